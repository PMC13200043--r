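## Microscale computational domain: a square of side `domain_size`
## centred on the origin, minus nine oriented rectangular nanochains on a
## 3x3 grid with spacing `spacing` (default domain_size/3).  Chains are
## numbered row-wise from the bottom-left: 1 = (-s,-s) ... 9 = (+s,+s).

## evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random-number stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.chain_grid_centers <- function(spacing) {
  s <- spacing
  g <- expand.grid(x = c(-s, 0, s), y = c(-s, 0, s),
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$y, g$x), , drop = FALSE]
}

## corners of an oriented rectangle, counter-clockwise
.rect_corners <- function(cx, cy, ang, L, W) {
  dx <- c(-L, L, L, -L) / 2
  dy <- c(-W, -W, W, W) / 2
  cbind(x = cx + dx * cos(ang) - dy * sin(ang),
        y = cy + dx * sin(ang) + dy * cos(ang))
}

## separating-axis test for two oriented rectangles (TRUE if disjoint)
.rects_disjoint <- function(a, b) {
  for (r in list(a, b)) {
    axes <- rbind(c(cos(r$angle), sin(r$angle)),
                  c(-sin(r$angle), cos(r$angle)))
    ca <- .rect_corners(a$center_x, a$center_y, a$angle, a$length, a$width)
    cb <- .rect_corners(b$center_x, b$center_y, b$angle, b$length, b$width)
    for (k in 1:2) {
      pa <- ca %*% axes[k, ]
      pb <- cb %*% axes[k, ]
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
    }
  }
  FALSE
}

#' Build the 3x3 nanochain grid
#'
#' Places nine oriented rectangular nanochains at the grid positions
#' `(±spacing, ±spacing, 0)` inside the square fluid domain.  `aligned`
#' mode sets every rotation angle to zero (useful for closed-form
#' oracles); `seeded_random` draws the nine angles independently and
#' uniformly on `[0, pi)` from a reproducible seed, emulating the random
#' in-solution orientations of real nanochains.  Placements are validated
#' to lie strictly inside the domain and to be pairwise disjoint after
#' rotation.
#'
#' @param params A [micro_params()] object.
#' @param orientation_mode `"seeded_random"` (default) or `"aligned"`.
#' @param seed Integer seed for the angle draw (default 1).
#' @return An object of class `micro_geometry` with fields `half_width`,
#'   `placements` (data frame: `index`, `center_x`, `center_y`, `angle`,
#'   `length`, `width`), `orientation_mode` and `seed`.
#' @examples
#' g <- build_chain_grid(micro_params(), "aligned")
#' g$placements[5, c("center_x", "center_y")]  # chain 5 at the origin
#' @export
build_chain_grid <- function(params,
                             orientation_mode = c("seeded_random", "aligned"),
                             seed = 1L) {
  stopifnot(inherits(params, "micro_params"))
  orientation_mode <- match.arg(orientation_mode)
  centers <- .chain_grid_centers(params$spacing)
  angles <- if (orientation_mode == "aligned") {
    rep(0, 9)
  } else {
    .with_seed(seed, stats::runif(9, 0, pi))
  }
  pl <- data.frame(index = 1:9,
                   center_x = centers$x, center_y = centers$y,
                   angle = angles,
                   length = params$L_chain, width = params$W_chain)
  geom <- structure(list(half_width = params$domain_size / 2,
                         placements = pl,
                         orientation_mode = orientation_mode,
                         seed = as.integer(seed)),
                    class = "micro_geometry")
  validate_geometry(geom)
  geom
}

#' Validate a chain placement layout
#'
#' Checks that every rotated rectangle lies strictly inside the square
#' domain and that the nine rectangles are pairwise disjoint; violations
#' raise a geometry error naming the offending chain(s).
#'
#' @param geom A `micro_geometry` object.
#' @return `geom`, invisibly.
#' @export
validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "micro_geometry"))
  pl <- geom$placements
  hw <- geom$half_width
  for (i in seq_len(nrow(pl))) {
    co <- .rect_corners(pl$center_x[i], pl$center_y[i], pl$angle[i],
                        pl$length[i], pl$width[i])
    if (any(abs(co) >= hw)) {
      stop("geometry error: chain ", pl$index[i],
           " extends outside the fluid domain after rotation",
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(pl) - 1L)) {
    for (j in seq(i + 1L, nrow(pl))) {
      a <- list(center_x = pl$center_x[i], center_y = pl$center_y[i],
                angle = pl$angle[i], length = pl$length[i],
                width = pl$width[i])
      b <- list(center_x = pl$center_x[j], center_y = pl$center_y[j],
                angle = pl$angle[j], length = pl$length[j],
                width = pl$width[j])
      if (!.rects_disjoint(a, b)) {
        stop("geometry error: chains ", pl$index[i], " and ", pl$index[j],
             " overlap", call. = FALSE)
      }
    }
  }
  invisible(geom)
}

#' Rigid-rotation wall velocity
#'
#' Velocity of a point on (or rigidly co-rotating with) a nanochain
#' rotating at angular velocity `omega` about its centre:
#' `u = -omega * (y - y_c)`, `v = omega * (x - x_c)`.
#'
#' @param placement A single-row placement (row of
#'   `micro_geometry$placements`, or any list with `center_x`,
#'   `center_y`).
#' @param omega Angular velocity in rad/s.
#' @param point Numeric vector `c(x, y)` or an n x 2 matrix of points (m).
#' @return A vector `c(u, v)` or an n x 2 matrix of velocities (m/s).
#' @examples
#' pl <- build_chain_grid(micro_params(), "aligned")$placements[5, ]
#' wall_velocity(pl, angular_velocity(3), c(5.25e-7, 0))
#' @export
wall_velocity <- function(placement, omega, point) {
  pt <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  u <- -omega * (pt[, 2] - placement$center_y)
  v <- omega * (pt[, 1] - placement$center_x)
  out <- cbind(u = u, v = v)
  if (!is.matrix(point)) out[1, ] else out
}

#' Fluid area of the perforated domain
#'
#' Closed form `domain_size^2 - 9 * L_chain * W_chain` (rotation does not
#' change a rectangle's area).
#'
#' @param params A [micro_params()] object.
#' @return Fluid area in m^2.
#' @export
fluid_area <- function(params) {
  stopifnot(inherits(params, "micro_params"))
  params$domain_size^2 - 9 * params$L_chain * params$W_chain
}

#' Export the geometry as polygons
#'
#' @param geom A `micro_geometry` object.
#' @return A list with `outer` (4 x 2 corner matrix of the domain square)
#'   and `chains` (list of nine 4 x 2 corner matrices, counter-clockwise).
#' @export
geometry_polygons <- function(geom) {
  stopifnot(inherits(geom, "micro_geometry"))
  hw <- geom$half_width
  outer <- cbind(x = c(-hw, hw, hw, -hw), y = c(-hw, -hw, hw, hw))
  chains <- lapply(seq_len(nrow(geom$placements)), function(i) {
    p <- geom$placements[i, ]
    .rect_corners(p$center_x, p$center_y, p$angle, p$length, p$width)
  })
  list(outer = outer, chains = chains)
}

#' JSON placement report
#'
#' @param geom A `micro_geometry` object.
#' @return A JSON string describing the placements, mode and seed.
#' @export
placement_report <- function(geom) {
  stopifnot(inherits(geom, "micro_geometry"))
  jsonlite::toJSON(list(orientation_mode = geom$orientation_mode,
                        seed = geom$seed,
                        half_width = geom$half_width,
                        placements = geom$placements),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
print.micro_geometry <- function(x, ...) {
  cat(sprintf("Microscale geometry: %g m square, 9 chains (%s, seed %d)\n",
              2 * x$half_width, x$orientation_mode, x$seed))
  print(x$placements, digits = 4)
  invisible(x)
}
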