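test_that("the wetting front follows the imbibition law", {
  p <- membrane_params()
  expect_identical(front_position(-0.1, p), 0)
  expect_error(front_position(-0.2, p), ">= -0.1")
  ## direct evaluation of sqrt(2*k*P_cap*(t+0.1)/(eta*porosity))
  expect_equal(front_position(0, p), 4.381780e-4, tolerance = 1e-6)
  expect_equal(front_position(0.9, p) / front_position(0.15, p), 2)
})

test_that("front position scales exactly as sqrt(t + 0.1)", {
  p <- membrane_params()
  t <- c(0, 0.5, 2, 10, 31, 100, 360)
  x <- front_position(t, p)
  expect_equal(x / sqrt(t + 0.1), rep(x[1] / sqrt(0.1), length(t)))
})

test_that("wetness is the smoothed front indicator", {
  p <- membrane_params()
  xf <- front_position(5, p)
  expect_identical(wetness(xf, 5, p), 0.5)
  expect_equal(wetness(xf + p$delta_smooth, 5, p), 0.11920, tolerance = 1e-4)
  expect_gt(wetness(xf - 10 * p$delta_smooth, 5, p), 0.999)
  ## monotone: non-increasing in x, non-decreasing in t
  xs <- seq(0, 7e-3, length.out = 200)
  expect_true(all(diff(wetness(xs, 3, p)) <= 0))
  expect_true(all(wetness(xs, 10, p) >= wetness(xs, 3, p)))
})

test_that("effective properties follow the printed wet/dry contrast maps", {
  p <- membrane_params()
  ep1 <- effective_properties(1, p)
  expect_equal(ep1$k_eff, 1e-13)
  expect_equal(ep1$D_eff, 2e-13)
  ep0 <- effective_properties(0, p)
  expect_equal(ep0$k_eff, 1e-15)
  expect_equal(ep0$D_eff, 2e-15)
  ep5 <- effective_properties(0.5, p)
  expect_equal(ep5$k_eff, p$k_perm * (0.01 + 0.99 * 0.25))
  expect_error(effective_properties(1.5, p), "wetness")
})

test_that("the test-line indicator is the closed interval [3, 4] mm", {
  p <- membrane_params()
  expect_identical(testline_indicator(3.5e-3, p), 1L)
  expect_identical(testline_indicator(2.9e-3, p), 0L)
  expect_identical(testline_indicator(3.0e-3, p), 1L)
  expect_identical(testline_indicator(4.0e-3, p), 1L)
  expect_identical(testline_indicator(4.1e-3, p), 0L)
})

test_that("a uniform membrane gives the 1D Darcy closed form", {
  p <- membrane_params()
  g <- membrane_grid(p, "coarse")
  d <- solve_darcy(rep(p$k_perm, g$nx), g, p)
  u_exact <- p$k_perm * p$P_inlet / (p$eta_fluid * g$Lx)
  expect_equal(max(abs(d$ux - u_exact)) / u_exact, 0, tolerance = 1e-9)
  ## pressure decays linearly from P_inlet to 0
  expect_equal(d$p[, 1], p$P_inlet * (1 - g$xc / g$Lx), tolerance = 1e-9)
  ## doubling the viscosity halves the velocity
  p2 <- update_params(p, eta_fluid = 2e-3)
  d2 <- solve_darcy(rep(p$k_perm, g$nx), g, p2)
  expect_equal(d2$ux[1, 1], d$ux[1, 1] / 2)
})

test_that("a two-block permeability field reproduces the harmonic mean", {
  p <- membrane_params()
  g <- membrane_grid(p, "coarse")
  k1 <- 1e-13; k2 <- 1e-14
  keff <- ifelse(g$xc < g$Lx / 2, k1, k2)
  d <- solve_darcy(keff, g, p)
  u_exact <- p$P_inlet /
    (p$eta_fluid * (g$Lx / 2 / k1 + g$Lx / 2 / k2))
  expect_equal(mean(d$flux) / (p$H_membrane), u_exact, tolerance = 5e-3)
  expect_lt(d$flux_rel_spread, 1e-3)
})

test_that("cross-section flux is uniform and conductance grows as the strip wets", {
  p <- membrane_params()
  g <- membrane_grid(p, "coarse")
  fluxes <- vapply(c(2, 5, 10, 20, 40), function(t) {
    keff <- effective_properties(wetness(g$xc, t, p), p)$k_eff
    d <- solve_darcy(keff, g, p)
    expect_lt(d$flux_rel_spread, 1e-3)
    mean(d$flux)
  }, numeric(1))
  expect_true(all(diff(fluxes) > 0))
})

test_that("the membrane grid marks exactly the test-line columns", {
  p <- membrane_params()
  g <- membrane_grid(p, "coarse")
  expect_identical(sum(g$on_testline), 20L)   # 1 mm / 50 um
  expect_true(all(g$xc[g$on_testline] >= 3e-3 &
                    g$xc[g$on_testline] <= 4e-3))
})
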