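## Three-species capture network on the membrane strip:
##   c   mobile nanochains   (advected + diffusing)
##   c2  free antibody       (immobilised on the test line)
##   c3  captured complex    (immobilised)
## with rates
##   R_c  = -kon*c*c2 + koff*c3 - k_recruit*c*c3
##   R_c2 = -kon*c*c2 + koff*c3
##   R_c3 =  kon*c*c2 - koff*c3 + k_recruit*c*c3
## The k_recruit term is the phenomenological cooperative-recruitment
## channel: complexes already captured attract flowing nanochains.
## Note R_c2 + R_c3 = 0 when k_recruit = 0, so c2 + c3 is conserved
## pointwise; the implicit reaction step preserves this identically.

#' Reaction rates of the cooperative capture network
#'
#' @param c,c2,c3 Concentrations (mol/m^3), vectorised.
#' @param kon Association rate (m^3/(mol*s)).
#' @param koff Dissociation rate (1/s).
#' @param k_recruit Cooperative recruitment rate (m^3/(mol*s)).
#' @return A list with components `R_c`, `R_c2`, `R_c3` (mol/(m^3*s)).
#' @examples
#' reaction_rates(7e-8, 1e-5, 0, kon = 1000, koff = 1e-9, k_recruit = 0)
#' @export
reaction_rates <- function(c, c2, c3, kon, koff, k_recruit) {
  if (any(c < 0 | c2 < 0 | c3 < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  std <- kon * c * c2 - koff * c3
  rec <- k_recruit * c * c3
  list(R_c = -std - rec, R_c2 = -std, R_c3 = std + rec)
}

## implicit-Euler reaction step for all cells at once: 3x3 Newton with a
## closed-form solve (Cramer), vectorised over cells
.reaction_step <- function(c0, c20, c30, dt, kon, koff, krec, porosity) {
  cn <- c0; c2n <- c20; c3n <- c30
  s <- dt / porosity   # the mobile species carries the porosity storage
  for (it in 1:12) {
    std <- kon * cn * c2n - koff * c3n
    rec <- krec * cn * c3n
    F1 <- cn - c0 + s * (std + rec)
    F2 <- c2n - c20 + dt * std
    F3 <- c3n - c30 - dt * (std + rec)
    a11 <- 1 + s * (kon * c2n + krec * c3n)
    a12 <- s * kon * cn
    a13 <- s * (-koff + krec * cn)
    a21 <- dt * kon * c2n
    a22 <- 1 + dt * kon * cn
    a23 <- -dt * koff
    a31 <- -dt * (kon * c2n + krec * c3n)
    a32 <- -dt * kon * cn
    a33 <- 1 + dt * (koff - krec * cn)
    det <- a11 * (a22 * a33 - a23 * a32) -
      a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
    d1 <- (F1 * (a22 * a33 - a23 * a32) - a12 * (F2 * a33 - a23 * F3) +
             a13 * (F2 * a32 - a22 * F3)) / det
    d2 <- (a11 * (F2 * a33 - a23 * F3) - F1 * (a21 * a33 - a23 * a31) +
             a13 * (a21 * F3 - F2 * a31)) / det
    d3 <- (a11 * (a22 * F3 - F2 * a32) - a12 * (a21 * F3 - F2 * a31) +
             F1 * (a21 * a32 - a22 * a31)) / det
    cn <- cn - d1; c2n <- c2n - d2; c3n <- c3n - d3
    if (max(abs(d1), abs(d2), abs(d3)) < 1e-20) break
  }
  list(c = pmax(cn, 0), c2 = pmax(c2n, 0), c3 = pmax(c3n, 0),
       consumed = -(cn - c0) * porosity)  # mobile mass removed per bulk volume
}

#' Simulate the membrane assay
#'
#' Integrates the coupled wetting / Darcy-flow / three-species capture
#' model over the strip: the mobile nanochain concentration is advected
#' by the superficial Darcy velocity with porosity-weighted storage and
#' `D_eff` diffusion (implicit upwind finite volumes), enters at
#' `C0_mol` on the inlet edge and leaves by advection at the outlet;
#' antibodies and complexes are immobile and evolve by the reaction
#' rates only (operator splitting with an exact implicit 3x3 Newton
#' reaction step, which conserves `c2 + c3` identically when
#' `k_recruit = 0`).
#'
#' With the default `coupling = "quasistatic"`, the Darcy problem is
#' re-solved whenever the wetness field has changed appreciably (the
#' front crosses the strip in the first ~25 s); `"frozen"` reproduces
#' the stationary-then-transient study layout by freezing the flow at
#' the wetness of `freeze_time`.
#'
#' @param params A [membrane_params()] object.
#' @param N_Abs Binding-efficiency factor (default from `params`).
#' @param k_recruit Recruitment constant in m^3/(mol*s) (default from
#'   `params`).
#' @param output_times Times (s) at which fields are recorded; default
#'   every 1 s to `t_end`.
#' @param t_end Final time (s), default 360.
#' @param grid A [membrane_grid()]; built from `resolution` if omitted.
#' @param resolution Grid resolution if `grid` is omitted.
#' @param dt Transport/reaction time step (s); defaults to the grid's
#'   resolution-matched step.
#' @param coupling `"quasistatic"` (default) or `"frozen"`.
#' @param freeze_time Wetness time (s) used when `coupling = "frozen"`.
#' @return An object of class `membrane_history` with recorded fields
#'   (`c`, `c2`, `c3`: cell x time matrices), the recording `times`,
#'   per-output test-line summaries and a nanochain mass audit.
#' @examples
#' \donttest{
#' mp <- membrane_params()
#' h <- simulate_membrane_assay(mp, N_Abs = 500, k_recruit = 0,
#'                              output_times = c(0, 180, 360))
#' summary(h)
#' }
#' @export
simulate_membrane_assay <- function(params,
                                    N_Abs = params$N_Abs,
                                    k_recruit = params$k_recruit,
                                    output_times = NULL,
                                    t_end = 360,
                                    grid = NULL,
                                    resolution = "coarse",
                                    dt = NULL,
                                    coupling = c("quasistatic", "frozen"),
                                    freeze_time = 31) {
  stopifnot(inherits(params, "membrane_params"))
  coupling <- match.arg(coupling)
  if (is.null(grid)) grid <- membrane_grid(params, resolution)
  if (is.null(dt)) dt <- grid$default_dt %||% 1
  if (!is.numeric(dt) || dt <= 0) {
    stop("`dt` must be a positive time step in seconds", call. = FALSE)
  }
  if (is.null(output_times)) output_times <- seq(0, t_end, by = 1)
  output_times <- sort(unique(output_times))
  if (any(output_times < 0) || any(output_times > t_end + 1e-9)) {
    stop("`output_times` must lie in [0, t_end]", call. = FALSE)
  }
  kon <- si_association_rate(N_Abs)
  krec <- k_recruit
  eps <- params$porosity

  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy
  ncell <- nx * ny
  Vc <- dx * dy
  xcol <- grid$xc
  tl_col <- grid$on_testline
  tl_cell <- rep(tl_col, times = ny)

  cfield <- numeric(ncell)
  c2 <- rep(ifelse(tl_col, params$C_Ab_init, 0), times = ny)
  c3 <- numeric(ncell)

  nt <- max(1L, round(t_end / dt))
  out_steps <- unique(pmin(nt, round(output_times / dt)))
  rec_times <- out_steps * dt
  n_out <- length(out_steps)
  Cmat <- matrix(NA_real_, ncell, n_out)
  C2mat <- matrix(NA_real_, ncell, n_out)
  C3mat <- matrix(NA_real_, ncell, n_out)

  w_solved <- rep(-1, nx)
  LUf <- NULL
  darcy <- NULL
  qx <- NULL
  Dfx <- NULL
  inflow_int <- 0; outflow_int <- 0; consumed_int <- 0

  rebuild <- function(w) {
    ep <- effective_properties(w, params)
    dar <- solve_darcy(ep$k_eff, grid, params)
    Dx <- ep$D_eff
    ## x-face diffusive conductances (per row), harmonic means
    Df <- numeric(nx + 1L)
    Df[2:nx] <- 2 * Dx[-nx] * Dx[-1] / (Dx[-nx] + Dx[-1]) / dx
    Df[1] <- Dx[1] / (dx / 2)   # Dirichlet inlet
    Df[nx + 1L] <- 0            # pure outflow
    ## implicit upwind transport matrix for c over all cells
    q <- dar$ux                 # (nx+1) x ny superficial velocities
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    dg <- rep(eps * Vc / dt, ncell)
    id <- function(i, j) i + (j - 1L) * nx
    for (j in seq_len(ny)) {
      qf <- q[, j] * dy         # face volumetric fluxes (positive = +x)
      ## interior faces i = 2..nx between cells i-1 and i
      f <- 2:nx
      up <- ifelse(qf[f] >= 0, id(f - 1L, j), id(f, j))
      dn <- ifelse(qf[f] >= 0, id(f, j), id(f - 1L, j))
      ## advection: downwind row gains qf*c_up, upwind row loses
      ii <- c(ii, up, dn); jj <- c(jj, up, up)
      xx <- c(xx, abs(qf[f]), -abs(qf[f]))
      ## diffusion
      a <- id(f - 1L, j); b <- id(f, j)
      g <- Df[f] * dy
      ii <- c(ii, a, b, a, b); jj <- c(jj, a, b, b, a)
      xx <- c(xx, g, g, -g, -g)
      ## inlet face: Dirichlet c = C0 (advective inflow carries C0, so it
      ## contributes only to the right-hand side; diffusion exchanges with
      ## the boundary value through a half-cell conductance)
      gin <- Df[1] * dy
      dg[id(1L, j)] <- dg[id(1L, j)] + gin
      ## outlet face: advective outflow
      dg[id(nx, j)] <- dg[id(nx, j)] + max(qf[nx + 1L], 0)
    }
    M <- Matrix::sparseMatrix(i = c(ii, seq_len(ncell)),
                              j = c(jj, seq_len(ncell)),
                              x = c(xx, numeric(ncell)),
                              dims = c(ncell, ncell)) +
      Matrix::Diagonal(ncell, dg)
    list(LU = Matrix::lu(M), darcy = dar, Dfx = Df, qx = dar$ux)
  }

  w_frozen <- if (coupling == "frozen") wetness(xcol, freeze_time, params)

  rec <- 1L
  if (out_steps[1] == 0L) {
    Cmat[, 1] <- cfield; C2mat[, 1] <- c2; C3mat[, 1] <- c3
    rec <- 2L
  }
  for (s in seq_len(nt)) {
    t_now <- s * dt
    w <- if (coupling == "frozen") w_frozen else wetness(xcol, t_now, params)
    if (is.null(LUf) || max(abs(w - w_solved)) > 1e-4) {
      built <- rebuild(w)
      LUf <- built$LU; darcy <- built$darcy
      Dfx <- built$Dfx; qx <- built$qx
      w_solved <- w
    }
    ## transport step (implicit)
    b <- eps * Vc / dt * cfield
    for (j in seq_len(ny)) {
      i1 <- 1L + (j - 1L) * nx
      b[i1] <- b[i1] + (max(qx[1, j] * dy, 0) + Dfx[1] * dy) * params$C0_mol
    }
    cstar <- as.numeric(Matrix::solve(LUf, b))
    for (j in seq_len(ny)) {
      i1 <- 1L + (j - 1L) * nx
      ilast <- nx + (j - 1L) * nx
      inflow_int <- inflow_int +
        (max(qx[1, j] * dy, 0) * params$C0_mol +
           Dfx[1] * dy * (params$C0_mol - cstar[i1])) * dt
      outflow_int <- outflow_int + max(qx[nx + 1L, j] * dy, 0) *
        cstar[ilast] * dt
    }
    ## reaction step
    rs <- .reaction_step(cstar, c2, c3, dt, kon, params$koff, krec, eps)
    consumed_int <- consumed_int + sum(rs$consumed) * Vc
    cfield <- rs$c; c2 <- rs$c2; c3 <- rs$c3
    if (rec <= n_out && s == out_steps[rec]) {
      Cmat[, rec] <- cfield; C2mat[, rec] <- c2; C3mat[, rec] <- c3
      rec <- rec + 1L
    }
  }

  storage <- eps * sum(cfield) * Vc
  structure(list(
    times = rec_times,
    c = Cmat, c2 = C2mat, c3 = C3mat,
    grid = grid, params = params,
    N_Abs = N_Abs, k_recruit = k_recruit,
    dt = dt, coupling = coupling,
    darcy = darcy,
    audit = list(inflow = inflow_int, outflow = outflow_int,
                 consumed = consumed_int, storage = storage,
                 rel_error = abs(inflow_int - outflow_int - consumed_int -
                                   storage) /
                   max(inflow_int, 1e-300))
  ), class = "membrane_history")
}

#' Total captured complex on the test line
#'
#' @param x A `membrane_history`.
#' @param time Time (s); default the last recorded time.
#' @return The integral of `c3` over the test-line region (mol/m, per
#'   unit out-of-plane thickness).
#' @export
testline_complex <- function(x, time = NULL) {
  stopifnot(inherits(x, "membrane_history"))
  k <- if (is.null(time)) length(x$times) else which.min(abs(x$times - time))
  tl <- rep(x$grid$on_testline, times = x$grid$ny)
  sum(x$c3[tl, k]) * x$grid$dx * x$grid$dy
}

#' Minimum free antibody on the test line
#'
#' @inheritParams testline_complex
#' @return Minimum of the free-antibody field `c2` over the test line
#'   (mol/m^3).
#' @export
testline_min_antibody <- function(x, time = NULL) {
  stopifnot(inherits(x, "membrane_history"))
  k <- if (is.null(time)) length(x$times) else which.min(abs(x$times - time))
  tl <- rep(x$grid$on_testline, times = x$grid$ny)
  min(x$c2[tl, k])
}

#' Spatial asymmetry index of the captured complex
#'
#' Quantifies the upstream/downstream imbalance of the complex density
#' across the test line:
#' `A = (\int c3 upstream half - \int c3 downstream half) / \int c3`,
#' with the halves split at the test-line midline (3.5 mm with
#' defaults).  `A` is 0 for a uniform field, +1 if all complex sits in
#' the upstream half.  If the total complex is zero the index is
#' undefined and `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param x A `membrane_history`, or a numeric `c3` field (length
#'   `nx*ny`) if `grid` and `params` are given.
#' @param time Time (s) when `x` is a history; default last.
#' @param grid,params Required when `x` is a raw field.
#' @return The asymmetry index in `[-1, 1]`, or flagged `NA`.
#' @export
asymmetry_index <- function(x, time = NULL, grid = NULL, params = NULL) {
  if (inherits(x, "membrane_history")) {
    k <- if (is.null(time)) length(x$times) else
      which.min(abs(x$times - time))
    field <- x$c3[, k]
    grid <- x$grid
    params <- x$params
  } else {
    stopifnot(is.numeric(x), inherits(grid, "membrane_grid"),
              inherits(params, "membrane_params"))
    field <- x
  }
  mid <- params$x_testline + params$w_testline / 2
  tl <- grid$on_testline
  upcol <- tl & grid$xc <= mid
  dncol <- tl & grid$xc > mid
  up <- sum(field[rep(upcol, times = grid$ny)])
  dn <- sum(field[rep(dncol, times = grid$ny)])
  tot <- up + dn
  if (tot <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (up - dn) / tot
}

#' Parametric sweep over binding efficiency and recruitment
#'
#' Runs [simulate_membrane_assay()] over the full cross-product of
#' `N_Abs_list` and `k_recruit_list` (default the 8 x 2 = 16-point
#' study grid) and tabulates the test-line outcomes.  Row order is
#' deterministic (sorted by `N_Abs`, then `k_recruit`); per-row
#' failures are caught and marked in `status`.
#'
#' @param params A [membrane_params()] object.
#' @param N_Abs_list Binding-efficiency values (default 300...1000).
#' @param k_recruit_list Recruitment constants (default `c(0, 7e4)`).
#' @param t_end Final time (s), default 360.
#' @param ... Passed to [simulate_membrane_assay()] (`grid`,
#'   `resolution`, `dt`, `coupling`, ...).
#' @return A data frame of class `membrane_sweep` with one row per
#'   combination: `N_Abs`, `k_recruit`, `total_complex`,
#'   `min_c2_testline`, `asymmetry`, `status`.
#' @export
parameter_sweep <- function(params,
                            N_Abs_list = seq(300, 1000, by = 100),
                            k_recruit_list = c(0, 7e4),
                            t_end = 360, ...) {
  stopifnot(inherits(params, "membrane_params"))
  if (!length(N_Abs_list) || !length(k_recruit_list)) {
    stop("sweep lists must be non-empty", call. = FALSE)
  }
  combos <- expand.grid(k_recruit = sort(k_recruit_list),
                        N_Abs = sort(N_Abs_list),
                        KEEP.OUT.ATTRS = FALSE)[, c("N_Abs", "k_recruit")]
  rows <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    rows[[r]] <- tryCatch({
      h <- simulate_membrane_assay(params,
                                   N_Abs = combos$N_Abs[r],
                                   k_recruit = combos$k_recruit[r],
                                   output_times = c(0, t_end),
                                   t_end = t_end, ...)
      data.frame(N_Abs = combos$N_Abs[r],
                 k_recruit = combos$k_recruit[r],
                 total_complex = testline_complex(h),
                 min_c2_testline = testline_min_antibody(h),
                 asymmetry = as.numeric(asymmetry_index(h)),
                 status = "ok")
    }, error = function(e) {
      warning("sweep point (N_Abs = ", combos$N_Abs[r], ", k_recruit = ",
              combos$k_recruit[r], ") failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(N_Abs = combos$N_Abs[r], k_recruit = combos$k_recruit[r],
                 total_complex = NA_real_, min_c2_testline = NA_real_,
                 asymmetry = NA_real_, status = "failed")
    })
  }
  out <- do.call(rbind, rows)
  class(out) <- c("membrane_sweep", class(out))
  out
}

#' @export
print.membrane_history <- function(x, ...) {
  cat(sprintf(
    "Membrane assay: N_Abs %g, k_recruit %.3g, %s coupling, dt %g s\n",
    x$N_Abs, x$k_recruit, x$coupling, x$dt))
  cat(sprintf(
    "  t = %g s: test-line complex %.4g, min free antibody %.4g mol/m^3\n",
    max(x$times), testline_complex(x), testline_min_antibody(x)))
  invisible(x)
}

#' @export
summary.membrane_history <- function(object, ...) {
  print(object)
  a <- asymmetry_index(object)
  cat(sprintf("  asymmetry index %+.3f; nanochain mass audit error %.2g\n",
              as.numeric(a), object$audit$rel_error))
  invisible(object)
}
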