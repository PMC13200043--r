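## Base-graphics views of the simulation objects.

#' @export
plot.flow_field <- function(x, ...) {
  sp <- speed_field(x)
  n <- x$mesh$n
  hw <- n * x$mesh$h / 2
  ax <- seq(-hw, hw, length.out = n)
  graphics::image(ax * 1e6, ax * 1e6, sp, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("Speed (m/s) at %.3g Hz", x$omega / (2 * pi)),
                  ...)
  invisible(x)
}

#' @export
plot.binding_history <- function(x, ...) {
  s <- removal_series(x)
  graphics::plot(s$time, s$removal_pct, type = "b", pch = 16,
                 xlab = "time (s)", ylab = "antigen removal (%)",
                 main = sprintf("Removal at %.3g Hz (%s flux)",
                                x$freq, x$flux_mode), ...)
  invisible(x)
}

#' @export
plot.removal_sweep <- function(x, ...) {
  ok <- x$status == "ok"
  graphics::plot(x$freq_hz[ok], x$removal_pct[ok], type = "b", pch = 16,
                 xlab = "rotation frequency (Hz)",
                 ylab = "antigen removal at t_end (%)",
                 main = "Frequency sweep", ...)
  invisible(x)
}

#' @export
plot.membrane_history <- function(x, time = NULL, ...) {
  g <- x$grid
  k <- if (is.null(time)) length(x$times) else which.min(abs(x$times - time))
  ## fields are stored cell-major with x fastest: reshape to nx x ny
  pr <- function(m) rowMeans(matrix(m[, k], g$nx, g$ny))
  graphics::matplot(g$xc * 1e3, cbind(pr(x$c) / max(pr(x$c), 1e-300),
                                      pr(x$c2) / x$params$C_Ab_init,
                                      pr(x$c3) / max(pr(x$c3), 1e-300)),
                    type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "darkgreen", "firebrick"),
                    xlab = "x (mm)", ylab = "normalised concentration",
                    main = sprintf("Membrane profiles at t = %g s",
                                   x$times[k]), ...)
  graphics::abline(v = c(x$params$x_testline,
                         x$params$x_testline + x$params$w_testline) * 1e3,
                   lty = 3)
  graphics::legend("topright", c("nanochain c", "antibody c2", "complex c3"),
                   col = c("steelblue", "darkgreen", "firebrick"), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' @export
plot.membrane_sweep <- function(x, ...) {
  ok <- x$status == "ok"
  krs <- sort(unique(x$k_recruit))
  cols <- c("steelblue", "firebrick")[seq_along(krs)]
  graphics::plot(range(x$N_Abs), range(x$total_complex[ok]), type = "n",
                 xlab = "N_Abs", ylab = "test-line complex (integrated c3)",
                 main = "Binding-efficiency sweep", ...)
  for (i in seq_along(krs)) {
    sel <- ok & x$k_recruit == krs[i]
    graphics::lines(x$N_Abs[sel], x$total_complex[sel], type = "b",
                    pch = 16, col = cols[i])
  }
  graphics::legend("topleft", sprintf("k_recruit = %g", krs), col = cols,
                   lwd = 1, pch = 16, bty = "n")
  invisible(x)
}
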