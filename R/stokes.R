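## Steady incompressible creeping flow on the staggered grid.
##
## At the micron scale and 0-20 Hz the Reynolds number is ~1e-5, so the
## quasi-steady Stokes equations apply and the solution is linear in the
## rotation rate.  The solver minimises the discrete energy
##    mu/2 * |grad u|^2 + kappa/2 * (div u)^2
## over the free velocity faces (a grad-div penalty formulation): the
## system is symmetric positive definite and is factorised once with
## CHOLMOD.  With kappa = 1e7 * mu the relative cell divergence comes out
## around 1e-8, far below the 1e-3 incompressibility audit.  Pressure is
## recovered from the penalty residual, p = -kappa * div u, and pinned to
## zero at the cell nearest the origin.

.face_index <- function(i, j, n, which) {
  if (which == "u") i + (j - 1L) * (n - 1L) else i + (j - 1L) * n
}

## accumulator for symmetric pair energies w/2*(a-b)^2 where a and/or b
## may be Dirichlet (g == 0 with value v)
.pair_acc <- function(ntot) {
  env <- new.env(parent = emptyenv())
  env$i <- vector("list", 64L)
  env$j <- vector("list", 64L)
  env$x <- vector("list", 64L)
  env$k <- 0L
  env$rhs <- numeric(ntot)
  env
}

.pair_add <- function(acc, ga, gb, va, vb, w) {
  freeA <- ga > 0L
  freeB <- gb > 0L
  push <- function(i, j, x) {
    acc$k <- acc$k + 1L
    acc$i[[acc$k]] <- i
    acc$j[[acc$k]] <- j
    acc$x[[acc$k]] <- x
  }
  bb <- freeA & freeB
  if (any(bb)) {
    a <- ga[bb]; b <- gb[bb]
    push(c(a, b), c(a, b), rep(w, 2 * sum(bb)))
    push(c(a, b), c(b, a), rep(-w, 2 * sum(bb)))
  }
  oa <- freeA & !freeB
  if (any(oa)) {
    a <- ga[oa]
    push(a, a, rep(w, sum(oa)))
    acc$rhs[a] <- acc$rhs[a] + w * vb[oa]
  }
  ob <- !freeA & freeB
  if (any(ob)) {
    b <- gb[ob]
    push(b, b, rep(w, sum(ob)))
    acc$rhs[b] <- acc$rhs[b] + w * va[ob]
  }
  invisible(NULL)
}

#' Solve the chain-stirred Stokes flow
#'
#' Computes the steady creeping-flow velocity and pressure in the
#' chain-perforated square domain, with no-slip outer walls and
#' rigid-rotation velocities on the chain boundaries.
#'
#' Two wall conventions are provided. `"prescribed"` imposes the full
#' rigid-rotation vector `(-omega*(y - y_c), omega*(x - x_c))` on every
#' chain-wall face, exactly as the model prescription states; on the flat
#' faces of a rectangle this vector has a non-zero wall-normal component,
#' so fluid formally penetrates the wall (the chain "paddles").
#' `"tangential"` zeroes the wall-normal face velocities and keeps the
#' rigid-rotation values as tangential wall data, giving an impermeable
#' rotating chain.  The choice matters for the species transport
#' bookkeeping; see the methods vignette.
#'
#' The solution is exactly linear in `omega`; [scale_flow()] rescales a
#' solved field to another frequency at no cost.
#'
#' @param mesh A `micro_mesh` from [generate_mesh()].
#' @param params A [micro_params()] object (viscosity is taken from it).
#' @param omega Angular velocity in rad/s (default: from `params$freq`).
#' @param wall_mode `"prescribed"` (default) or `"tangential"`.
#' @param kappa_factor Grad-div penalty coefficient as a multiple of the
#'   viscosity (default 1e7).
#' @return An object of class `flow_field`: face velocity vectors `u`,
#'   `v`, cell pressure `p` (NA inside chains), cell divergence, the
#'   relative divergence norm `div_rel`, `omega`, `wall_mode` and the
#'   mesh.
#' @examples
#' \donttest{
#' mesh <- generate_mesh(build_chain_grid(micro_params(), "aligned"), 60)
#' fl <- solve_flow(mesh, micro_params(), omega = angular_velocity(3))
#' summary(fl)
#' }
#' @export
solve_flow <- function(mesh, params, omega = NULL,
                       wall_mode = c("prescribed", "tangential"),
                       kappa_factor = 1e7) {
  stopifnot(inherits(mesh, "micro_mesh"), inherits(params, "micro_params"))
  wall_mode <- match.arg(wall_mode)
  if (is.null(omega)) omega <- angular_velocity(params$freq)
  if (omega < 0) stop("`omega` must be >= 0", call. = FALSE)

  n <- mesh$n
  h <- mesh$h
  cid <- mesh$cell_chain
  solid <- cid > 0L
  mu <- params$mu_fluid
  kappa <- kappa_factor * mu

  nu <- (n - 1L) * n
  nv <- n * (n - 1L)
  iu <- rep(seq_len(n - 1L), times = n)
  ju <- rep(seq_len(n), each = n - 1L)
  iv <- rep(seq_len(n), times = n - 1L)
  jv <- rep(seq_len(n - 1L), each = n)
  hw <- n * h / 2
  ux <- -hw + iu * h
  uy <- -hw + (ju - 0.5) * h
  vx <- -hw + (iv - 0.5) * h
  vy <- -hw + jv * h

  ## chain owning each face (0 = fluid-fluid); number of solid neighbours
  cu_L <- cid[cbind(iu, ju)];      cu_R <- cid[cbind(iu + 1L, ju)]
  cv_B <- cid[cbind(iv, jv)];      cv_T <- cid[cbind(iv, jv + 1L)]
  cidu <- pmax(cu_L, cu_R)
  cidv <- pmax(cv_B, cv_T)
  u_dir <- cidu > 0L
  v_dir <- cidv > 0L

  pl <- mesh$geometry$placements
  u_val <- numeric(nu)
  v_val <- numeric(nv)
  if (any(u_dir)) {
    u_val[u_dir] <- -omega * (uy[u_dir] - pl$center_y[cidu[u_dir]])
  }
  if (any(v_dir)) {
    v_val[v_dir] <- omega * (vx[v_dir] - pl$center_x[cidv[v_dir]])
  }
  if (wall_mode == "tangential") {
    ## faces between fluid and solid carry the wall-normal component:
    ## impermeable wall => zero; interior (solid-solid) faces keep the
    ## rigid-rotation value and act as tangential wall data for the
    ## viscous stencil of adjacent fluid faces.
    u_norm <- u_dir & xor(cu_L > 0L, cu_R > 0L)
    v_norm <- v_dir & xor(cv_B > 0L, cv_T > 0L)
    u_val[u_norm] <- 0
    v_val[v_norm] <- 0
  }

  ufree <- which(!u_dir)
  vfree <- which(!v_dir)
  nfu <- length(ufree)
  nfv <- length(vfree)
  gu <- integer(nu); gu[ufree] <- seq_len(nfu)
  gv <- integer(nv); gv[vfree] <- nfu + seq_len(nfv)
  ntot <- nfu + nfv

  acc <- .pair_acc(ntot)
  zero <- function(k) rep(0, k)

  ## --- viscous energy of u ---
  sel <- iu <= n - 2L   # horizontal neighbour pairs
  idx <- which(sel); nb <- .face_index(iu[sel] + 1L, ju[sel], n, "u")
  .pair_add(acc, gu[idx], gu[nb], u_val[idx], u_val[nb], mu)
  for (edge in list(which(iu == 1L), which(iu == n - 1L))) {
    .pair_add(acc, gu[edge], rep(0L, length(edge)),
              u_val[edge], zero(length(edge)), mu)   # normal deriv at side walls
  }
  sel <- ju <= n - 1L   # vertical neighbour pairs
  idx <- which(sel); nb <- .face_index(iu[sel], ju[sel] + 1L, n, "u")
  .pair_add(acc, gu[idx], gu[nb], u_val[idx], u_val[nb], mu)
  for (edge in list(which(ju == 1L), which(ju == n))) {
    .pair_add(acc, gu[edge], rep(0L, length(edge)),
              u_val[edge], zero(length(edge)), 2 * mu) # no-slip wall at h/2
  }

  ## --- viscous energy of v (mirror) ---
  sel <- jv <= n - 2L
  idx <- which(sel); nb <- .face_index(iv[sel], jv[sel] + 1L, n, "v")
  .pair_add(acc, gv[idx], gv[nb], v_val[idx], v_val[nb], mu)
  for (edge in list(which(jv == 1L), which(jv == n - 1L))) {
    .pair_add(acc, gv[edge], rep(0L, length(edge)),
              v_val[edge], zero(length(edge)), mu)
  }
  sel <- iv <= n - 1L
  idx <- which(sel); nb <- .face_index(iv[sel] + 1L, jv[sel], n, "v")
  .pair_add(acc, gv[idx], gv[nb], v_val[idx], v_val[nb], mu)
  for (edge in list(which(iv == 1L), which(iv == n))) {
    .pair_add(acc, gv[edge], rep(0L, length(edge)),
              v_val[edge], zero(length(edge)), 2 * mu)
  }

  ## --- grad-div penalty over fluid cells ---
  fluid <- mesh$fluid
  ci <- ((fluid - 1L) %% n) + 1L
  cj <- ((fluid - 1L) %/% n) + 1L
  nc <- length(fluid)
  fe <- ifelse(ci <= n - 1L, .face_index(ci, cj, n, "u"), 0L)
  fw <- ifelse(ci >= 2L, .face_index(ci - 1L, cj, n, "u"), 0L)
  fn <- ifelse(cj <= n - 1L, .face_index(ci, cj, n, "v"), 0L)
  fs <- ifelse(cj >= 2L, .face_index(ci, cj - 1L, n, "v"), 0L)
  rows <- rep(seq_len(nc), 4L)
  colsA <- c(fe, fw, ifelse(fn > 0L, fn + nu, 0L), ifelse(fs > 0L, fs + nu, 0L))
  sgn <- c(rep(1, nc), rep(-1, nc), rep(1, nc), rep(-1, nc))
  keep <- colsA > 0L
  B_all <- Matrix::sparseMatrix(i = rows[keep], j = colsA[keep],
                                x = sgn[keep], dims = c(nc, nu + nv))
  allmap <- c(gu, ifelse(gv > 0L, gv, 0L))
  fixedv <- c(u_val, v_val)
  isfree <- allmap > 0L
  Bf <- B_all[, which(isfree), drop = FALSE]
  Bf <- Bf[, order(allmap[isfree]), drop = FALSE]
  Bx <- B_all[, which(!isfree), drop = FALSE]
  A_pen <- kappa * Matrix::crossprod(Bf)
  rhs_pen <- -kappa *
    as.numeric(Matrix::crossprod(Bf, Bx %*% fixedv[!isfree]))

  A_vis <- Matrix::sparseMatrix(
    i = unlist(acc$i[seq_len(acc$k)]),
    j = unlist(acc$j[seq_len(acc$k)]),
    x = unlist(acc$x[seq_len(acc$k)]),
    dims = c(ntot, ntot))
  A <- Matrix::forceSymmetric((A_vis + Matrix::t(A_vis)) / 2, uplo = "U") +
    Matrix::forceSymmetric(A_pen, uplo = "U")
  b <- acc$rhs + rhs_pen

  sol <- if (omega == 0) numeric(ntot) else as.numeric(Matrix::solve(A, b))

  uu <- u_val; uu[ufree] <- sol[seq_len(nfu)]
  vv <- v_val; vv[vfree] <- sol[nfu + seq_len(nfv)]

  s <- as.numeric(B_all %*% c(uu, vv))     # per-cell net face imbalance
  div <- s / h
  umax <- max(abs(uu), abs(vv), .Machine$double.eps)
  p <- rep(NA_real_, n * n)
  p[fluid] <- -kappa * div
  ## pressure pin at the fluid cell nearest the origin
  ci0 <- abs(ci - (n + 1) / 2)
  cj0 <- abs(cj - (n + 1) / 2)
  pin <- fluid[which.min(ci0 + cj0)]
  p <- p - p[pin]

  structure(list(
    u = uu, v = vv, p = p,
    div = div,
    div_rel = max(abs(div)) * h / umax,
    omega = omega, wall_mode = wall_mode,
    kappa_factor = kappa_factor,
    mesh = mesh
  ), class = "flow_field")
}

#' Rescale a Stokes solution to another rotation rate
#'
#' The creeping-flow problem is linear and its boundary data scale with
#' `omega`, so the velocity and pressure fields at a new rotation rate
#' are an exact multiple of a solved field on the same mesh.
#'
#' @param flow A `flow_field`.
#' @param omega New angular velocity (rad/s).
#' @return A `flow_field` at the new `omega`.
#' @export
scale_flow <- function(flow, omega) {
  stopifnot(inherits(flow, "flow_field"))
  if (flow$omega == 0 && omega != 0) {
    stop("cannot rescale a zero-frequency field to omega > 0; solve at ",
         "a reference omega first", call. = FALSE)
  }
  fac <- if (omega == 0) 0 else omega / flow$omega
  out <- flow
  out$u <- flow$u * fac
  out$v <- flow$v * fac
  out$p <- flow$p * fac
  out$div <- flow$div * fac
  out$omega <- omega
  out
}

#' Cell-centred speed field
#'
#' @param flow A `flow_field`.
#' @return An n x n matrix of velocity magnitudes (NA inside chains).
#' @export
speed_field <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  n <- flow$mesh$n
  U <- matrix(flow$u, n - 1L, n)
  V <- matrix(flow$v, n, n - 1L)
  uc <- matrix(0, n, n)
  uc[2:(n - 1), ] <- (U[1:(n - 2), ] + U[2:(n - 1), ]) / 2
  uc[1, ] <- U[1, ] / 2
  uc[n, ] <- U[n - 1, ] / 2
  vc <- matrix(0, n, n)
  vc[, 2:(n - 1)] <- (V[, 1:(n - 2)] + V[, 2:(n - 1)]) / 2
  vc[, 1] <- V[, 1] / 2
  vc[, n] <- V[, n - 1] / 2
  sp <- sqrt(uc^2 + vc^2)
  sp[flow$mesh$cell_chain > 0L] <- NA_real_
  sp
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "Stokes flow at omega = %.4g rad/s (%.3g Hz), wall mode '%s'\n",
    x$omega, x$omega / (2 * pi), x$wall_mode))
  cat(sprintf("  max speed %.4g m/s, relative divergence %.2g\n",
              max(abs(x$u), abs(x$v)), x$div_rel))
  invisible(x)
}

#' @export
summary.flow_field <- function(object, ...) {
  p <- object$mesh$geometry
  cat(sprintf("Creeping flow summary (mesh %d^2, wall mode '%s')\n",
              object$mesh$n, object$wall_mode))
  cat(sprintf("  omega %.4g rad/s; max |u| %.4g m/s; divergence (rel) %.2g\n",
              object$omega, max(abs(object$u), abs(object$v)),
              object$div_rel))
  invisible(object)
}
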