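test_that("angular velocity follows 2*pi*f with a guarded zero case", {
  expect_identical(angular_velocity(0), 0)
  expect_equal(angular_velocity(1), 2 * pi)
  expect_equal(angular_velocity(3), 18.8496, tolerance = 1e-5)
  expect_error(angular_velocity(-1), "frequency")
})

test_that("capillary pressure is the Young-Laplace closed form", {
  expect_equal(capillary_pressure(0.072, 20e-6), 7200)
  expect_identical(capillary_pressure(0, 20e-6), 0)
  expect_equal(capillary_pressure(0.036, 20e-6), 3600)
  expect_error(capillary_pressure(0.072, 0), "pore")
})

test_that("association rate converts per-molar to SI with factor 10", {
  expect_identical(si_association_rate(100), 1000)
  expect_identical(si_association_rate(0), 0)
  expect_identical(si_association_rate(700), 7000)
  expect_error(si_association_rate(-1), "N_Abs")
  expect_identical(per_molar_rate_to_si(1e4), 10)
})

test_that("microscale defaults reproduce the published parameter table", {
  p <- micro_params()
  expect_identical(p$L_chain, 1050e-9)
  expect_identical(p$W_chain, 150e-9)
  expect_identical(p$domain_size, 15e-6)
  expect_identical(p$C_bulk, 6.67e-8)
  expect_identical(p$mu_fluid, 1.8e-3)
  expect_identical(p$rho_fluid, 1000)
  expect_identical(p$k_on, 1)
  expect_identical(p$k_off, 0.1)
  expect_identical(p$freq, 0)
  expect_identical(p$Gamma_max, 1e-8)
  expect_identical(p$t_end, 360)
  expect_identical(p$spacing, 5e-6)   # domain_size / 3
  expect_identical(p$D_analyte, 1.1e-10)
  expect_identical(p$M_analyte, 15000)
  expect_identical(micro_derived(p)$K_D, 0.1)
})

test_that("membrane defaults reproduce the published parameter table", {
  p <- membrane_params()
  expect_identical(p$L_model, 3e-3)
  expect_identical(p$H_membrane, 2.5e-3)
  expect_identical(p$porosity, 0.75)
  expect_identical(p$k_perm, 1e-13)
  expect_identical(p$pore_size, 20e-6)
  expect_identical(p$eta_fluid, 1e-3)
  expect_identical(p$gamma_surface, 0.072)
  expect_identical(p$C0_mol, 7e-8)
  expect_identical(p$D0, 2e-13)
  expect_identical(p$delta_smooth, 1e-4)
  expect_identical(p$power_contrast, 2)
  expect_identical(p$P_inlet, 25000)
  expect_identical(p$k_min, 0.01)
  expect_identical(p$W_TL, 1e-3)
  expect_identical(p$H_TL, p$H_membrane)
  expect_identical(p$x_testline, p$L_model)
  expect_identical(p$w_testline, p$W_TL)
  expect_identical(p$C_Ab_init, 1e-5)
  expect_identical(p$koff, 1e-9)
  expect_identical(p$N_Abs, 100)
  expect_identical(p$k_recruit, 7e4)
  d <- membrane_derived(p)
  expect_equal(d$P_cap, 7200)
  expect_identical(d$kon, 1000)
})

test_that("parameter validation rejects bad values and unknown names", {
  expect_error(micro_params(L_chain = -1), "L_chain")
  expect_error(micro_params(bogus = 1), "bogus")
  expect_error(membrane_params(porosity = 1.2), "porosity")
  expect_error(membrane_params(k_min = 0), "k_min")
  expect_error(membrane_params(typo_key = 3), "typo_key")
  expect_warning(membrane_params(V_chain = 1e-20), "not consumed")
})

test_that("derived quantities track parameter updates with no stale cache", {
  p <- micro_params()
  expect_identical(micro_derived(update_params(p, k_off = 0.2))$K_D, 0.2)
  expect_equal(micro_derived(update_params(p, freq = 5))$omega, 10 * pi)
  mp <- membrane_params()
  expect_identical(membrane_derived(update_params(mp, N_Abs = 700))$kon, 7000)
  expect_equal(
    membrane_derived(update_params(mp, pore_size = 10e-6))$P_cap, 14400)
  ## geometry defaults re-derive when their anchor moves
  mp2 <- update_params(mp, L_model = 4e-3)
  expect_identical(mp2$x_testline, 4e-3)
})

test_that("config round trip reproduces every value bit-exactly", {
  p <- micro_params(freq = 3)
  mp <- membrane_params(N_Abs = 600)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(f, micro = p, membrane = mp)
  back <- load_config(f)
  expect_identical(unclass(back$micro), unclass(p))
  expect_identical(unclass(back$membrane), unclass(mp))
})

test_that("config loading is strict about keys and magnitudes", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)                     # empty file -> defaults
  expect_identical(unclass(cfg$micro), unclass(micro_params()))
  expect_identical(unclass(cfg$membrane), unclass(membrane_params()))

  writeLines("micro:\n  freq: 3", f)
  cfg <- load_config(f)                     # single override
  expect_identical(cfg$micro$freq, 3)
  others <- setdiff(names(unclass(cfg$micro)), "freq")
  expect_identical(unclass(cfg$micro)[others],
                   unclass(micro_params())[others])

  writeLines("micro:\n  frq: 3", f)
  expect_error(load_config(f), "frq")       # misspelt key named

  writeLines("micro:\n  domain_size: 15", f)  # metres instead of um
  expect_error(load_config(f), "units")

  writeLines("extras:\n  a: 1", f)
  expect_error(load_config(f), "section")
})
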