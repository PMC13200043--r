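# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; the "ci" scale keeps each solve in the seconds
# range.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .cache, inherits = FALSE)) {
    assign(name, force(expr), .cache)
  }
  get(name, .cache, inherits = FALSE)
}

ci_fixture <- function() cached("ci", generate_fixtures("ci", seed = 1))

# coarse seeded mesh of the full microscale geometry (the study layout)
coarse_mesh <- function() {
  cached("coarse_mesh", {
    generate_mesh(build_chain_grid(micro_params(), "seeded_random", 1),
                  "coarse")
  })
}

aligned_mesh_ci <- function() {
  cached("aligned_mesh_ci", {
    generate_mesh(build_chain_grid(micro_params(), "aligned"), 100L)
  })
}

# static (0 Hz) full-length binding run on the coarse mesh
static_history <- function() {
  cached("static_history", {
    p <- micro_params()
    fl <- solve_flow(coarse_mesh(), p, omega = 0)
    simulate_binding(fl, p, dt = 2)
  })
}

# well-mixed exponential oracle for the static uptake (independent
# closed form: uniform concentration, first-order surface sink on the
# total chain perimeter)
well_mixed_removal <- function(p, t) {
  d <- micro_derived(p)
  rate <- d$uptake_velocity * d$chain_perimeter_total / d$fluid_area
  100 * (1 - exp(-rate * t) * d$fluid_area / p$domain_size^2)
}

# membrane study sweep (coarse grid), shared by the acceptance blocks
study_sweep <- function() {
  cached("study_sweep", parameter_sweep(membrane_params()))
}

# craft a binding_history around a given uniform concentration field
fake_history <- function(mesh, params, cvec, time = 360) {
  structure(list(times = time,
                 conc = matrix(cvec, ncol = 1),
                 mesh = mesh, params = params,
                 freq = 0, omega = 0, flux_mode = "uptake",
                 wall_mode = "prescribed", dt = 1,
                 mass = sum(cvec) * mesh$h^2,
                 uptake = 0, leak = 0),
            class = "binding_history")
}
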