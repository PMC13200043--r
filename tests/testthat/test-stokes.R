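test_that("zero rotation gives an identically quiescent field", {
  p <- micro_params()
  fl <- solve_flow(aligned_mesh_ci(), p, omega = 0)
  expect_true(all(fl$u == 0))
  expect_true(all(fl$v == 0))
  expect_true(all(fl$p[!is.na(fl$p)] == 0))
})

test_that("the Stokes solution is linear in omega on a fixed mesh", {
  p <- micro_params()
  mesh <- aligned_mesh_ci()
  f1 <- solve_flow(mesh, p, omega = 2 * pi)
  f2 <- solve_flow(mesh, p, omega = 4 * pi)
  scale_err <- max(abs(f2$u - 2 * f1$u), abs(f2$v - 2 * f1$v)) /
    max(abs(f1$u), abs(f1$v))
  expect_lt(scale_err, 1e-8)
  ## scale_flow reproduces a direct solve exactly
  f3 <- scale_flow(f1, 4 * pi)
  expect_equal(f3$u, f2$u, tolerance = 1e-12)
})

test_that("cell divergence is far below the incompressibility audit level", {
  p <- micro_params()
  fl <- cached("flow_ci_3hz",
               solve_flow(aligned_mesh_ci(), p, omega = angular_velocity(3)))
  expect_lt(fl$div_rel, 1e-3)
})

test_that("chain-wall faces carry the prescribed rigid-rotation velocity", {
  p <- micro_params()
  mesh <- aligned_mesh_ci()
  omega <- angular_velocity(3)
  fl <- cached("flow_ci_3hz", solve_flow(mesh, p, omega = omega))
  n <- mesh$n
  hw <- n * mesh$h / 2
  cid <- mesh$cell_chain
  pl <- mesh$geometry$placements
  ## u-faces adjacent to a solid cell must equal -omega*(y - y_c)
  iu <- rep(seq_len(n - 1L), times = n)
  ju <- rep(seq_len(n), each = n - 1L)
  k <- pmax(cid[cbind(iu, ju)], cid[cbind(iu + 1L, ju)])
  sel <- which(k > 0L)
  uy <- -hw + (ju[sel] - 0.5) * mesh$h
  expect_equal(fl$u[sel], -omega * (uy - pl$center_y[k[sel]]))
  ## tangential mode: wall-normal faces are zero (impermeable chain)
  flt <- solve_flow(mesh, p, omega = omega, wall_mode = "tangential")
  fs <- sel[xor(cid[cbind(iu, ju)][sel] > 0L,
                cid[cbind(iu + 1L, ju)][sel] > 0L)]
  expect_true(all(flt$u[fs] == 0))
})

test_that("wall speeds reach the chain tip speed and stay below it elsewhere", {
  p <- micro_params()
  fl <- cached("flow_ci_3hz",
               solve_flow(aligned_mesh_ci(), p, omega = angular_velocity(3)))
  tip <- micro_derived(update_params(p, freq = 3))$u_tip
  vmax <- max(abs(fl$v))
  expect_lt(vmax, tip * 1.001)
  expect_gt(vmax, tip * 0.8)   # staircase faces stop short of the tip
})

test_that("the creeping-flow assumption holds: Re ~ 1e-5 at 3 Hz", {
  re <- micro_derived(micro_params(freq = 3))$reynolds
  expect_gt(re, 1e-6)
  expect_lt(re, 1e-4)
})
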