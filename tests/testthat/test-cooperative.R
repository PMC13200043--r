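test_that("reaction rates implement the cooperative network algebra", {
  r0 <- reaction_rates(0, 0, 0, 1000, 1e-9, 7e4)
  expect_identical(unlist(r0), c(R_c = 0, R_c2 = 0, R_c3 = 0))
  ## pairwise conservation without recruitment
  r <- reaction_rates(3e-8, 5e-6, 2e-7, 1000, 1e-9, 0)
  expect_identical(r$R_c, r$R_c2)
  expect_identical(r$R_c, -r$R_c3)
  ## worked arithmetic case
  r2 <- reaction_rates(7e-8, 1e-5, 0, 1000, 1e-9, 0)
  expect_equal(r2$R_c3, 7e-10)
  expect_error(reaction_rates(-1e-9, 0, 0, 1, 1, 0), "non-negative")
})

test_that("no association pathway means no complex ever forms", {
  p <- membrane_params()
  h <- simulate_membrane_assay(p, N_Abs = 0, k_recruit = 0,
                               output_times = c(0, 30, 60), t_end = 60)
  expect_true(all(h$c3 == 0))
  expect_true(all(h$c2[, 3] == h$c2[, 1]))
})

test_that("c2 + c3 is conserved pointwise when recruitment is off", {
  p <- membrane_params()
  h <- simulate_membrane_assay(p, N_Abs = 800, k_recruit = 0,
                               output_times = c(0, 180, 360))
  init <- h$c2[, 1] + h$c3[, 1]
  for (k in 2:3) {
    tot <- h$c2[, k] + h$c3[, k]
    expect_lt(max(abs(tot - init)) / p$C_Ab_init, 1e-6)
  }
})

test_that("the asymmetry index quantifies upstream-weighted capture", {
  p <- membrane_params()
  g <- membrane_grid(p, "coarse")
  tl <- rep(g$on_testline, g$ny)
  uniform <- ifelse(tl, 1, 0)
  expect_identical(asymmetry_index(uniform, grid = g, params = p), 0)
  upstream <- ifelse(tl & rep(g$xc <= 3.5e-3, g$ny), 1, 0)
  expect_identical(asymmetry_index(upstream, grid = g, params = p), 1)
  ## linear ramp 2a at the upstream edge to 0 downstream -> +0.5
  frac <- (g$xc - p$x_testline) / p$w_testline
  ramp <- ifelse(tl, rep(2 * (1 - frac), g$ny), 0)
  expect_equal(asymmetry_index(ramp, grid = g, params = p), 0.5)
  ## zero field: flagged undefined
  z <- asymmetry_index(numeric(g$nx * g$ny), grid = g, params = p)
  expect_true(is.na(z))
  expect_true(attr(z, "undefined"))
})

test_that("recruitment skews capture upstream at N_Abs = 600", {
  p <- membrane_params()
  h0 <- simulate_membrane_assay(p, N_Abs = 600, k_recruit = 0,
                                output_times = c(0, 360))
  h1 <- simulate_membrane_assay(p, N_Abs = 600, k_recruit = 7e4,
                                output_times = c(0, 360))
  expect_gt(asymmetry_index(h1), asymmetry_index(h0))
})

test_that("the nanochain mass audit closes over the full assay", {
  p <- membrane_params()
  h <- simulate_membrane_assay(p, N_Abs = 500, k_recruit = 7e4,
                               output_times = c(0, 360))
  expect_lt(h$audit$rel_error, 0.01)
})

test_that("the parametric sweep covers the 8 x 2 grid deterministically", {
  sw <- study_sweep()
  expect_identical(nrow(sw), 16L)
  expect_identical(sw$N_Abs, rep(seq(300, 1000, by = 100), each = 2))
  expect_identical(sw$k_recruit, rep(c(0, 7e4), times = 8))
  expect_true(all(sw$status == "ok"))
  ## total complex grows with binding efficiency at fixed recruitment
  for (kr in c(0, 7e4)) {
    tot <- sw$total_complex[sw$k_recruit == kr]
    expect_true(all(diff(tot) > 0))
  }
  ## recruitment raises the asymmetry at every N_Abs
  a0 <- sw$asymmetry[sw$k_recruit == 0]
  a1 <- sw$asymmetry[sw$k_recruit == 7e4]
  expect_true(all(a1 > a0))
})

test_that("complex totals scale near-linearly with N_Abs in the dilute regime", {
  ## premise of the linearity property: small consumption across the
  ## test line, arranged here by a 10x lower antibody load
  p <- membrane_params(C_Ab_init = 1e-6)
  tots <- vapply(c(300, 1000), function(na) {
    h <- simulate_membrane_assay(p, N_Abs = na, k_recruit = 0,
                                 output_times = c(0, 360))
    testline_complex(h)
  }, numeric(1))
  ratio <- tots[2] / tots[1]
  expect_gt(ratio, 3.0)
  expect_lt(ratio, 3.7)
})

test_that("frozen-coupling mode reproduces a fixed-wetness flow", {
  p <- membrane_params()
  h <- simulate_membrane_assay(p, N_Abs = 500, k_recruit = 0,
                               output_times = c(0, 60), t_end = 60,
                               coupling = "frozen", freeze_time = 360)
  ## frozen at full wetness: inflow velocity equals the wet closed form
  u_exact <- membrane_derived(p)$u_wet
  expect_equal(h$darcy$ux[1, 1], u_exact, tolerance = 1e-6)
})
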