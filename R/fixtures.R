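## Fixture bundles: pre-wired parameter/geometry/grid sets at two
## problem sizes.  "ci" is a short, coarse configuration whose solves
## all finish in seconds (shortened incubation, coarse grids) for use
## in invariant tests; "desk" is the full study configuration.

#' Generate a fixture bundle
#'
#' @param scale `"ci"` (coarse grids, `t_end = 36` s) or `"desk"` (the
#'   full configuration, `t_end = 360` s).
#' @param seed Seed used for the chain-orientation draw.
#' @return A list of class `fixture_bundle`: `micro` and `membrane`
#'   parameter objects, `geometry`, `mesh` and `membrane_grid`, plus the
#'   `scale` and `seed` used.
#' @examples
#' fx <- generate_fixtures("ci", seed = 7)
#' fx$micro$t_end  # 36
#' @export
generate_fixtures <- function(scale = c("ci", "desk"), seed = 1L) {
  scale <- match.arg(scale)
  micro <- if (scale == "ci") micro_params(t_end = 36) else micro_params()
  membrane <- membrane_params()
  geometry <- build_chain_grid(micro, "seeded_random", seed)
  mesh_res <- if (scale == "ci") 100L else "medium"
  grid_res <- if (scale == "ci") "coarse" else "medium"
  structure(list(
    micro = micro,
    membrane = membrane,
    geometry = geometry,
    mesh = generate_mesh(geometry, mesh_res),
    membrane_grid = membrane_grid(membrane, grid_res),
    scale = scale,
    seed = as.integer(seed)
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("Fixture bundle '%s' (seed %d): micro t_end %g s, mesh %d^2, membrane grid %d x %d\n",
              x$scale, x$seed, x$micro$t_end, x$mesh$n,
              x$membrane_grid$nx, x$membrane_grid$ny))
  invisible(x)
}
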