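test_that("chain centres form the 3x3 grid at +/- spacing", {
  g <- build_chain_grid(micro_params(), "aligned")
  pl <- g$placements
  s <- 5e-6
  expect_identical(nrow(pl), 9L)
  expect_equal(unlist(pl[5, c("center_x", "center_y")]),
               c(center_x = 0, center_y = 0))
  expect_equal(unlist(pl[1, c("center_x", "center_y")]),
               c(center_x = -s, center_y = -s))
  expect_equal(unlist(pl[9, c("center_x", "center_y")]),
               c(center_x = s, center_y = s))
  expect_setequal(pl$center_x, c(-s, 0, s))
  expect_setequal(pl$center_y, c(-s, 0, s))
  expect_true(all(pl$angle == 0))
})

test_that("seeded orientations are reproducible, in range, and seed-sensitive", {
  p <- micro_params()
  g1 <- build_chain_grid(p, "seeded_random", seed = 42)
  g2 <- build_chain_grid(p, "seeded_random", seed = 42)
  g3 <- build_chain_grid(p, "seeded_random", seed = 43)
  expect_identical(g1$placements, g2$placements)
  expect_false(identical(g1$placements$angle, g3$placements$angle))
  expect_true(all(g1$placements$angle >= 0 & g1$placements$angle < pi))
  ## drawing angles must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(build_chain_grid(p, "seeded_random", seed = 7))
  expect_identical(runif(1), before)
})

test_that("wall velocity is the rigid-rotation field", {
  pl <- build_chain_grid(micro_params(), "aligned")$placements[5, ]
  expect_equal(wall_velocity(pl, 10, c(pl$center_x, pl$center_y)),
               c(u = 0, v = 0))
  expect_equal(wall_velocity(pl, 0, c(1e-6, 2e-6)), c(u = 0, v = 0))
  v <- wall_velocity(pl, 18.8496, c(pl$center_x + 5.25e-7, pl$center_y))
  expect_equal(unname(v[1]), 0)
  expect_equal(unname(v[2]), 9.90e-6, tolerance = 1e-3)
  ## |u| = omega * r on random points around every chain
  set.seed(5)
  geom <- build_chain_grid(micro_params(), "seeded_random", 3)
  for (i in c(1, 5, 9)) {
    plc <- geom$placements[i, ]
    pts <- cbind(plc$center_x + runif(20, -2e-6, 2e-6),
                 plc$center_y + runif(20, -2e-6, 2e-6))
    vv <- wall_velocity(plc, 7.5, pts)
    r <- sqrt((pts[, 1] - plc$center_x)^2 + (pts[, 2] - plc$center_y)^2)
    expect_equal(sqrt(rowSums(vv^2)), 7.5 * r)
  }
})

test_that("fluid area matches the closed form", {
  p <- micro_params()
  expect_identical(fluid_area(p),
                   p$domain_size^2 - 9 * p$L_chain * p$W_chain)
  expect_equal(fluid_area(p), 2.235825e-10, tolerance = 1e-6)
})

test_that("invalid placements raise geometry errors", {
  ## chains longer than the grid spacing overlap their neighbours
  expect_error(build_chain_grid(micro_params(L_chain = 6e-6)),
               "overlap|outside")
  ## chains wider than the margin to the wall leave the domain
  expect_error(build_chain_grid(micro_params(domain_size = 10.2e-6,
                                             spacing = 5e-6), "aligned"),
               "outside")
})

test_that("polygon export and placement report describe all nine chains", {
  g <- build_chain_grid(micro_params(), "seeded_random", 11)
  poly <- geometry_polygons(g)
  expect_identical(length(poly$chains), 9L)
  expect_identical(dim(poly$outer), c(4L, 2L))
  expect_true(all(vapply(poly$chains, function(m) all(dim(m) == c(4, 2)),
                         logical(1))))
  ## corner distances reproduce the rectangle diagonal
  diag_half <- sqrt((1050e-9 / 2)^2 + (150e-9 / 2)^2)
  c1 <- poly$chains[[1]]
  ctr <- colMeans(c1)
  expect_equal(sqrt(rowSums(sweep(c1, 2, ctr)^2)), rep(diag_half, 4))

  rep_json <- placement_report(g)
  parsed <- jsonlite::fromJSON(rep_json)
  expect_identical(parsed$seed, 11L)
  expect_identical(nrow(parsed$placements), 9L)
  expect_equal(parsed$placements$angle, g$placements$angle)
})
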