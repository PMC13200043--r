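## Porous-membrane strip model: analytical Lucas-Washburn wetting front,
## smoothed wetness indicator, wetness-dependent effective transport
## properties, and a Darcy pressure solve on a structured 2D grid over
## the 7 mm strip (3 mm + 1 mm test line + 3 mm, height 2.5 mm).

#' Lucas-Washburn wetting front position
#'
#' `x_front(t) = sqrt(2 * k_perm * P_cap * (t + 0.1) / (eta * porosity))`
#' - the classical square-root-of-time capillary imbibition law, with a
#' 0.1 s offset that regularises the t = 0 singularity.  With the model
#' defaults the front crosses the full 7 mm strip at about 25 s.
#'
#' @param t Time in s (vectorised); must be >= -0.1.
#' @param params A [membrane_params()] object.
#' @return Front position in m.
#' @examples
#' front_position(0, membrane_params())   # 4.3818e-4 m
#' @export
front_position <- function(t, params) {
  stopifnot(inherits(params, "membrane_params"))
  if (any(t < -0.1)) {
    stop("`t` must be >= -0.1 s (the imbibition-law offset)", call. = FALSE)
  }
  P_cap <- capillary_pressure(params$gamma_surface, params$pore_size)
  sqrt(2 * params$k_perm * P_cap * (t + 0.1) /
         (params$eta_fluid * params$porosity))
}

#' Smoothed wetness indicator
#'
#' `wetness(x, t) = 0.5 * (1 + tanh((x_front(t) - x) / delta_smooth))`,
#' ranging from 1 (fully wetted, behind the front) to 0 (dry, ahead of
#' it) over a smoothing width `delta_smooth`.
#'
#' @param x Position along the strip in m (vectorised).
#' @param t Time in s (scalar).
#' @param params A [membrane_params()] object.
#' @return Wetness fraction in `[0, 1]`.
#' @export
wetness <- function(x, t, params) {
  xf <- front_position(t, params)
  0.5 * (1 + tanh((xf - x) / params$delta_smooth))
}

#' Effective transport properties of a partially wetted membrane
#'
#' Elementwise maps of the wetness field:
#' `k_eff = k_perm * (k_min + (1 - k_min) * w^power_contrast)` and
#' `D_eff = D0 * max(w, 0.01)`.
#'
#' @param w Wetness values in `[0, 1]` (vectorised).
#' @param params A [membrane_params()] object.
#' @return A list with components `k_eff` (m^2) and `D_eff` (m^2/s).
#' @export
effective_properties <- function(w, params) {
  stopifnot(inherits(params, "membrane_params"))
  if (any(w < -1e-12 | w > 1 + 1e-12)) {
    stop("wetness must lie in [0, 1]", call. = FALSE)
  }
  list(
    k_eff = params$k_perm *
      (params$k_min + (1 - params$k_min) * w^params$power_contrast),
    D_eff = params$D0 * pmax(w, 0.01)
  )
}

#' Test-line indicator
#'
#' 1 on the closed interval `[x_testline, x_testline + w_testline]`
#' (3 to 4 mm with defaults), 0 elsewhere.  Both boundaries are
#' inclusive (a measure-zero convention).
#'
#' @param x Position along the strip in m (vectorised).
#' @param params A [membrane_params()] object.
#' @return Integer 0/1 vector.
#' @export
testline_indicator <- function(x, params) {
  stopifnot(inherits(params, "membrane_params"))
  as.integer(x >= params$x_testline &
               x <= params$x_testline + params$w_testline)
}

.membrane_resolutions <- list(
  coarse = list(nx = 140L, ny = 6L, dt = 1),
  medium = list(nx = 280L, ny = 8L, dt = 0.5),
  fine   = list(nx = 420L, ny = 10L, dt = 0.25)
)

#' Structured grid over the membrane strip
#'
#' Uniform `nx x ny` cell grid over the flattened 2D strip
#' (`2*L_model + W_TL` by `H_membrane`).  The named resolutions are
#' coarse (140 x 6), medium (280 x 8) and fine (420 x 10); the test line
#' spans an integer number of columns at all three.
#'
#' @param params A [membrane_params()] object.
#' @param resolution `"coarse"`, `"medium"`, `"fine"`, or `c(nx, ny)`.
#' @return An object of class `membrane_grid`.
#' @export
membrane_grid <- function(params, resolution = "coarse") {
  stopifnot(inherits(params, "membrane_params"))
  if (is.character(resolution)) {
    resolution <- match.arg(resolution, names(.membrane_resolutions))
    r <- .membrane_resolutions[[resolution]]
    nx <- r$nx; ny <- r$ny; dt <- r$dt; resname <- resolution
  } else {
    nx <- as.integer(resolution[1])
    ny <- as.integer(resolution[2])
    dt <- NULL; resname <- "custom"
  }
  Lx <- 2 * params$L_model + params$W_TL
  dx <- Lx / nx
  dy <- params$H_membrane / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  structure(list(
    nx = nx, ny = ny, dx = dx, dy = dy, Lx = Lx,
    xc = xc, yc = yc,
    on_testline = testline_indicator(xc, params) == 1L,
    resolution = resname, default_dt = dt
  ), class = "membrane_grid")
}

#' Solve the Darcy pressure problem on the strip
#'
#' Finite-volume solve of `div((k_eff / eta) grad p) = 0` with pressure
#' `P_inlet` at the inlet (x = 0), 0 at the outlet (x = strip end) and
#' no-flow lateral walls.  Face permeabilities are harmonic means, so a
#' piecewise-constant permeability reproduces the series-resistance
#' (harmonic) closed form exactly.
#'
#' @param keff Effective permeability field (m^2): an `nx x ny` matrix or
#'   a length-`nx` vector (uniform in y).
#' @param grid A [membrane_grid()].
#' @param params A [membrane_params()] object.
#' @return An object of class `darcy_field`: cell pressures `p`
#'   (`nx x ny`), superficial x-face velocities `ux` (`(nx+1) x ny`),
#'   the per-column flux profile `flux` and its relative spread
#'   `flux_rel_spread` (incompressibility audit).
#' @export
solve_darcy <- function(keff, grid, params) {
  stopifnot(inherits(grid, "membrane_grid"),
            inherits(params, "membrane_params"))
  nx <- grid$nx; ny <- grid$ny
  if (is.matrix(keff)) {
    stopifnot(nrow(keff) == nx, ncol(keff) == ny)
  } else {
    stopifnot(length(keff) == nx)
    keff <- matrix(keff, nx, ny)
  }
  if (any(keff <= 0)) stop("`keff` must be positive", call. = FALSE)
  eta <- params$eta_fluid
  dx <- grid$dx; dy <- grid$dy
  id <- function(i, j) i + (j - 1L) * nx

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(nx * ny)
  diag_acc <- numeric(nx * ny)
  add_off <- function(a, b, g) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); xx <<- c(xx, -g, -g)
    diag_acc[a] <<- diag_acc[a] + g
    diag_acc[b] <<- diag_acc[b] + g
  }
  ## interior x-faces (harmonic mean)
  for (j in seq_len(ny)) {
    kcol <- keff[, j]
    gx <- 2 * kcol[-nx] * kcol[-1] / (kcol[-nx] + kcol[-1]) / eta * dy / dx
    add_off(id(seq_len(nx - 1L), j), id(seq(2L, nx), j), gx)
  }
  ## interior y-faces
  if (ny > 1L) {
    for (j in seq_len(ny - 1L)) {
      g <- 2 * keff[, j] * keff[, j + 1] / (keff[, j] + keff[, j + 1]) /
        eta * dx / dy
      add_off(id(seq_len(nx), j), id(seq_len(nx), j + 1L), g)
    }
  }
  ## Dirichlet inlet/outlet through half-cell conductances
  gin <- keff[1, ] / eta * dy / (dx / 2)
  gout <- keff[nx, ] / eta * dy / (dx / 2)
  lin <- id(1L, seq_len(ny)); lout <- id(nx, seq_len(ny))
  diag_acc[lin] <- diag_acc[lin] + gin
  diag_acc[lout] <- diag_acc[lout] + gout
  rhs[lin] <- rhs[lin] + gin * params$P_inlet

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nx * ny)),
                            j = c(jj, seq_len(nx * ny)),
                            x = c(xx, diag_acc),
                            dims = c(nx * ny, nx * ny))
  p <- matrix(as.numeric(Matrix::solve(A, rhs)), nx, ny)

  ## superficial x-velocities on the nx+1 x-faces of each row
  ux <- matrix(0, nx + 1L, ny)
  for (j in seq_len(ny)) {
    kcol <- keff[, j]
    kh <- 2 * kcol[-nx] * kcol[-1] / (kcol[-nx] + kcol[-1])
    ux[2:nx, j] <- -(kh / eta) * (p[-1, j] - p[-nx, j]) / dx
    ux[1, j] <- -(kcol[1] / eta) * (p[1, j] - params$P_inlet) / (dx / 2)
    ux[nx + 1L, j] <- -(kcol[nx] / eta) * (0 - p[nx, j]) / (dx / 2)
  }
  flux <- rowSums(ux) * dy              # per x-face cross-section flux
  spread <- (max(flux) - min(flux)) / max(abs(flux))
  structure(list(p = p, ux = ux, flux = flux, flux_rel_spread = spread,
                 grid = grid),
            class = "darcy_field")
}

#' @export
print.darcy_field <- function(x, ...) {
  cat(sprintf(
    "Darcy field on %d x %d grid: mean u_x %.4g m/s, flux spread %.2g\n",
    x$grid$nx, x$grid$ny, mean(x$ux), x$flux_rel_spread))
  invisible(x)
}
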