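## Structured configuration files: a YAML document with optional `micro`
## and `membrane` sections whose keys are exactly the model parameter
## names.  Unknown keys are an error; a handful of magnitude sanity bounds
## catch the common unit slips (mm typed as m, per-molar rates typed as
## SI) with a descriptive message.

.sanity_bounds <- list(
  micro = list(
    L_chain     = c(1e-8, 1e-4),
    W_chain     = c(1e-9, 1e-4),
    domain_size = c(1e-7, 1e-2),
    mu_fluid    = c(1e-5, 10),
    D_analyte   = c(1e-14, 1e-7),
    t_end       = c(1e-3, 1e6)
  ),
  membrane = list(
    L_model    = c(1e-5, 1),
    H_membrane = c(1e-5, 1),
    pore_size  = c(1e-8, 1e-3),
    k_perm     = c(1e-18, 1e-8),
    eta_fluid  = c(1e-5, 10),
    porosity   = c(1e-3, 1 - 1e-6)
  )
)

.check_sanity <- function(vals, section) {
  bounds <- .sanity_bounds[[section]]
  for (key in intersect(names(vals), names(bounds))) {
    v <- vals[[key]]
    b <- bounds[[key]]
    if (is.numeric(v) && length(v) == 1L && (v < b[1] || v > b[2])) {
      stop("config key `", section, ":", key, "` = ", v,
           " is outside the plausible range [", b[1], ", ", b[2],
           "] - check the units", call. = FALSE)
    }
  }
}

#' Load a model configuration file
#'
#' Reads a YAML configuration with optional `micro` and `membrane`
#' sections and returns fully validated parameter objects.  An empty or
#' absent section yields the model defaults.  Keys must match the
#' parameter names exactly; misspelt or unknown keys raise an error
#' naming the key, and magnitude sanity bounds reject values that look
#' like unit mistakes.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `micro` ([micro_params()]) and
#'   `membrane` ([membrane_params()]).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("micro:\n  freq: 3", cfg)
#' load_config(cfg)$micro$freq
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  extra <- setdiff(names(raw), c("micro", "membrane"))
  if (length(extra)) {
    stop("unknown config section(s): ",
         paste0("`", extra, "`", collapse = ", "),
         " (expected `micro` and/or `membrane`)", call. = FALSE)
  }
  micro_vals <- raw$micro %||% list()
  memb_vals <- raw$membrane %||% list()
  .check_sanity(micro_vals, "micro")
  .check_sanity(memb_vals, "membrane")
  list(
    micro = do.call(micro_params, micro_vals),
    membrane = do.call(membrane_params, memb_vals)
  )
}

#' Write a model configuration file
#'
#' Serialises parameter objects to YAML such that [load_config()]
#' reproduces every stored value bit-exactly (numbers are written with
#' full precision).
#'
#' @param path Output path.
#' @param micro A [micro_params()] object (optional).
#' @param membrane A [membrane_params()] object (optional).
#' @return `path`, invisibly.
#' @export
write_config <- function(path, micro = NULL, membrane = NULL) {
  doc <- list()
  if (!is.null(micro)) {
    stopifnot(inherits(micro, "micro_params"))
    doc$micro <- unclass(micro)
  }
  if (!is.null(membrane)) {
    stopifnot(inherits(membrane, "membrane_params"))
    doc$membrane <- unclass(membrane)
  }
  ## 17 significant digits: doubles survive the round trip bit-exactly
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
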