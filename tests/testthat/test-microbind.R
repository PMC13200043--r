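test_that("no binding capacity means no uptake: c stays at C_bulk", {
  p <- micro_params(Gamma_max = 1e-300, t_end = 36)
  ## Gamma_max must be > 0 by validation; 1e-300 is numerically zero
  fl <- solve_flow(aligned_mesh_ci(), p, omega = 0)
  h <- simulate_binding(fl, p, dt = 4)
  expect_lt(max(abs(h$conc[, ncol(h$conc)] - p$C_bulk)) / p$C_bulk, 1e-9)
})

test_that("static uptake matches the well-mixed exponential oracle", {
  ## oracle: c(t) = C_bulk * exp(-k_on*Gamma_max*P_tot/A_fluid * t),
  ## computed independently of the PDE path
  p <- micro_params()
  h <- static_history()
  expect_equal(removal_percentage(h), well_mixed_removal(p, 360),
               tolerance = 0.05)
  ## and much tighter in practice: the static case is reaction-limited
  expect_equal(removal_percentage(h), well_mixed_removal(p, 360),
               tolerance = 2e-3)
})

test_that("removal percentage implements the full-square normalisation", {
  p <- micro_params()
  mesh <- coarse_mesh()
  nc <- length(mesh$fluid)
  ## c == 0 -> 100 %
  expect_identical(removal_percentage(fake_history(mesh, p, rep(0, nc))), 100)
  ## c == C_bulk -> ~0.63 % because the chains occupy 9*L*W of the square
  r0 <- removal_percentage(fake_history(mesh, p, rep(p$C_bulk, nc)))
  expect_equal(r0, 100 * 9 * p$L_chain * p$W_chain / p$domain_size^2,
               tolerance = 0.15)
  ## definition inverted: integral c dA = 0.323 * C_bulk * domain^2
  cval <- 0.323 * p$C_bulk * p$domain_size^2 / (nc * mesh$h^2)
  expect_equal(removal_percentage(fake_history(mesh, p, rep(cval, nc))),
               67.7)
  ## residual scale: C_bulk maps to ~1 ng/mL
  expect_equal(residual_ng_ml(fake_history(mesh, p, rep(p$C_bulk, nc))),
               1.0, tolerance = 0.01)
})

test_that("removal grows monotonically in time, capacity and rate", {
  p <- micro_params(t_end = 36)
  mesh <- aligned_mesh_ci()
  fl <- solve_flow(mesh, p, omega = 0)
  h <- simulate_binding(fl, p, dt = 2)
  expect_true(all(diff(removal_series(h)$removal_pct) >= 0))
  base <- removal_percentage(h)
  h_gam <- simulate_binding(fl, update_params(p, Gamma_max = 2e-8), dt = 2)
  expect_gt(removal_percentage(h_gam), base)
  h_kon <- simulate_binding(fl, update_params(p, k_on = 2), dt = 2)
  expect_gt(removal_percentage(h_kon), base)
})

test_that("the mass audit closes: concentration loss equals wall uptake", {
  au <- mass_audit(static_history())
  expect_lt(au$rel_error, 0.01)
  ## rotating, tangential walls: uptake is still the only species sink
  p <- micro_params(t_end = 36)
  flt <- solve_flow(aligned_mesh_ci(), p, omega = angular_velocity(3),
                    wall_mode = "tangential")
  ht <- simulate_binding(flt, p, flux_mode = "uptake", dt = 2)
  expect_lt(mass_audit(ht)$rel_error, 0.01)
  ## advective walls: the audit closes once the tracked leak is included
  flp <- solve_flow(aligned_mesh_ci(), p, omega = angular_velocity(3))
  ha <- simulate_binding(flp, p, flux_mode = "advective", dt = 2)
  expect_lt(mass_audit(ha)$rel_error, 0.01)
})

test_that("uptake flux mode refuses a penetrating advection field", {
  p <- micro_params(t_end = 36)
  flp <- solve_flow(aligned_mesh_ci(), p, omega = angular_velocity(3))
  expect_error(simulate_binding(flp, p, flux_mode = "uptake"),
               "tangential")
})

test_that("mesh convergence: static removal moves < 1 pp medium to fine", {
  p <- micro_params()
  g <- build_chain_grid(p, "seeded_random", 1)
  r <- vapply(c("medium", "fine"), function(res) {
    fl <- solve_flow(generate_mesh(g, res), p, omega = 0)
    removal_percentage(simulate_binding(fl, p, dt = 2))
  }, numeric(1))
  expect_lt(abs(diff(r)), 1)
})

test_that("a frequency sweep is consistent and tabulates every frequency", {
  p <- micro_params(t_end = 36)
  sw <- frequency_sweep(p, freqs = 0:20, seed = 1, resolution = 100L)
  expect_identical(nrow(sw), 21L)
  expect_identical(sw$freq_hz, 0:20)
  expect_true(all(sw$status == "ok"))
  expect_identical(names(sw)[1:6],
                   c("freq_hz", "removal_pct", "residual_ng_ml",
                     "wall_mode", "mesh", "seed"))
  ## the 0 Hz row equals a standalone static run bit-identically
  mesh <- generate_mesh(build_chain_grid(p, "seeded_random", 1), 100L)
  fl0 <- solve_flow(mesh, p, omega = 0, wall_mode = "tangential")
  h0 <- simulate_binding(fl0, p, flux_mode = "uptake", dt = 1)
  expect_identical(sw$removal_pct[1], removal_percentage(h0))
  ## removal is non-decreasing over 0-10 Hz up to solver roundoff
  r <- sw$removal_pct[sw$freq_hz <= 10]
  expect_true(all(diff(r) > -1e-6))
})

test_that("per-frequency failures are marked while the sweep continues", {
  p <- micro_params(t_end = 36)
  ## an impossible time step makes one run fail fast via output mismatch
  sw <- suppressWarnings(
    frequency_sweep(p, freqs = c(0, 1), seed = 1, resolution = 100L,
                    dt = -1))
  expect_true(all(sw$status == "failed"))
  expect_true(all(is.na(sw$removal_pct)))
})
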