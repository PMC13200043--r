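## Capture-efficiency data analysis for the supernatant-depletion
## measurement: antigen is incubated with functionalised nanochains
## (with or without magnetic rotation), the chains are pulled down with
## a permanent magnet, and the residual antigen in the supernatant is
## quantified against a calibration curve.

#' Antigen capture efficiency
#'
#' `efficiency = (C0 - Cs) / C0 * 100`, the percentage of antigen
#' removed from solution.  Noisy measurements with `Cs > C0` yield
#' negative efficiencies; such out-of-range values are returned as-is
#' and flagged with a warning rather than clipped.
#'
#' @param C0 Initial antigen concentration (ng/mL), > 0. Vectorised.
#' @param Cs Supernatant concentration after capture (ng/mL), >= 0.
#' @return Capture efficiency in percent.
#' @examples
#' capture_efficiency(1.0, 0.48)  # 52 %
#' @export
capture_efficiency <- function(C0, Cs) {
  if (any(C0 <= 0)) {
    stop("`C0` must be > 0 (efficiency undefined at zero initial ",
         "concentration)", call. = FALSE)
  }
  if (any(Cs < 0)) stop("`Cs` must be >= 0", call. = FALSE)
  eff <- (C0 - Cs) / C0 * 100
  if (any(eff < 0 | eff > 100)) {
    warning("capture efficiency outside [0, 100] % (noisy measurement?); ",
            "returned unclipped", call. = FALSE)
  }
  eff
}

#' Fold improvement of rotating over static capture
#'
#' Plain ratio of the two capture efficiencies.
#'
#' @param eff_rot Capture efficiency with rotation (percent).
#' @param eff_static Capture efficiency without rotation (percent);
#'   must be non-zero.
#' @return The fold improvement (dimensionless).
#' @examples
#' fold_improvement(67.7, 27.9)  # ~2.43
#' @export
fold_improvement <- function(eff_rot, eff_static) {
  if (any(eff_static == 0)) {
    stop("fold improvement undefined: static efficiency is zero",
         call. = FALSE)
  }
  eff_rot / eff_static
}

#' Summarise replicated capture measurements
#'
#' Aggregates per-replicate measurements as mean plus/minus the sample
#' standard deviation per condition (the convention of the validation
#' data, e.g. 52 +/- 11 % over n = 3), and tabulates fold improvements
#' of every condition over a reference (static) condition.
#'
#' @param data A data frame with columns `condition`, `replicate`,
#'   `C0_ng_ml`, `Cs_ng_ml`.
#' @param static Name of the reference condition for the fold table
#'   (default `"static"`); skipped if absent.
#' @return A list with `efficiency` (per-measurement values), `summary`
#'   (condition, mean_eff, sd, n) and `fold` (condition,
#'   fold_vs_static), of class `capture_table`.
#' @export
capture_summary <- function(data, static = "static") {
  need <- c("condition", "replicate", "C0_ng_ml", "Cs_ng_ml")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("`data` lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data$efficiency <- capture_efficiency(data$C0_ng_ml, data$Cs_ng_ml)
  agg <- do.call(rbind, lapply(split(data, data$condition), function(d) {
    data.frame(condition = d$condition[1],
               mean_eff = mean(d$efficiency),
               sd = stats::sd(d$efficiency),
               n = nrow(d))
  }))
  rownames(agg) <- NULL
  fold <- NULL
  if (static %in% agg$condition) {
    ref <- agg$mean_eff[agg$condition == static]
    others <- agg[agg$condition != static, , drop = FALSE]
    if (nrow(others) && ref != 0) {
      fold <- data.frame(condition = others$condition,
                         fold_vs_static = fold_improvement(others$mean_eff,
                                                           ref))
    }
  }
  structure(list(efficiency = data, summary = agg, fold = fold),
            class = "capture_table")
}

#' @export
print.capture_table <- function(x, ...) {
  cat("Capture efficiency by condition (mean +/- sd over replicates):\n")
  for (r in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %5.1f +/- %4.1f %%  (n = %d)\n",
                x$summary$condition[r], x$summary$mean_eff[r],
                x$summary$sd[r], x$summary$n[r]))
  }
  if (!is.null(x$fold)) {
    for (r in seq_len(nrow(x$fold))) {
      cat(sprintf("  fold improvement %s vs static: %.2f\n",
                  x$fold$condition[r], x$fold$fold_vs_static[r]))
    }
  }
  invisible(x)
}
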