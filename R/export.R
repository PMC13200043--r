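## Output plumbing: CSV sweep tables, legacy-VTK field snapshots and
## JSON run manifests.  Sweep CSVs are written with deterministic row
## order (the sweep functions already sort by their sweep keys) so a
## rerun from the same manifest is byte-identical.

#' Write a sweep table to CSV
#'
#' Writes exactly the tabular columns of a [frequency_sweep()] or
#' [parameter_sweep()] result (attributes and the `status` bookkeeping
#' column are dropped for the microscale sweep, whose column contract is
#' `freq_hz, removal_pct, residual_ng_ml, wall_mode, mesh, seed`).
#'
#' @param x A `removal_sweep` or `membrane_sweep` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "removal_sweep")) {
    df <- df[, c("freq_hz", "removal_pct", "residual_ng_ml", "wall_mode",
                 "mesh", "seed")]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.vtk_header <- function(con, title, nx, ny, dx, dy, ox, oy) {
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
               sprintf("ORIGIN %.9g %.9g 0", ox, oy),
               sprintf("SPACING %.9g %.9g 1", dx, dy),
               sprintf("CELL_DATA %d", nx * ny)), con)
}

.vtk_scalar <- function(con, name, values) {
  writeLines(c(sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(values, digits = 9, trim = TRUE, scientific = TRUE),
             con)
}

#' Export microscale fields as a legacy VTK file
#'
#' Writes the cell-centred speed, pressure and chain-id fields of a flow
#' solution - and optionally a recorded concentration field - as an
#' ASCII `STRUCTURED_POINTS` legacy VTK file readable by ParaView and
#' friends.
#'
#' @param flow A `flow_field`.
#' @param path Output `.vtk` path.
#' @param history Optional `binding_history` on the same mesh; its field
#'   at `time` is added as a `concentration` array.
#' @param time Time (s) of the concentration snapshot (default last).
#' @return `path`, invisibly.
#' @export
write_micro_vtk <- function(flow, path, history = NULL, time = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  mesh <- flow$mesh
  n <- mesh$n
  con <- file(path, "w")
  on.exit(close(con))
  hw <- n * mesh$h / 2
  .vtk_header(con, "chainflow microscale fields", n, n,
              mesh$h, mesh$h, -hw, -hw)
  sp <- speed_field(flow)
  sp[is.na(sp)] <- 0
  .vtk_scalar(con, "speed", as.numeric(sp))
  pp <- flow$p
  pp[is.na(pp)] <- 0
  .vtk_scalar(con, "pressure", pp)
  .vtk_scalar(con, "chain_id", as.numeric(mesh$cell_chain))
  if (!is.null(history)) {
    stopifnot(inherits(history, "binding_history"))
    k <- if (is.null(time)) length(history$times) else
      which.min(abs(history$times - time))
    cc <- numeric(n * n)
    cc[mesh$fluid] <- history$conc[, k]
    .vtk_scalar(con, "concentration", cc)
  }
  invisible(path)
}

#' Export membrane fields as a legacy VTK file
#'
#' @param history A `membrane_history`.
#' @param path Output `.vtk` path.
#' @param time Snapshot time (s), default last.
#' @return `path`, invisibly.
#' @export
write_membrane_vtk <- function(history, path, time = NULL) {
  stopifnot(inherits(history, "membrane_history"))
  g <- history$grid
  k <- if (is.null(time)) length(history$times) else
    which.min(abs(history$times - time))
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, "chainflow membrane fields", g$nx, g$ny, g$dx, g$dy, 0, 0)
  .vtk_scalar(con, "nanochain", history$c[, k])
  .vtk_scalar(con, "antibody", history$c2[, k])
  .vtk_scalar(con, "complex", history$c3[, k])
  invisible(path)
}

#' Build a run manifest
#'
#' Collects the configuration snapshot, seeds and solver modes that
#' produced a set of outputs, so a rerun reproduces them bit-exactly.
#'
#' @param micro,membrane Parameter objects included in the snapshot
#'   (optional).
#' @param seed Seed(s) used.
#' @param modes Named list of solver modes (wall/flux/coupling, grid
#'   resolutions, time steps).
#' @param outputs Character vector of output files the manifest covers.
#' @param timings Optional named numeric vector of per-stage timings (s).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(micro = NULL, membrane = NULL, seed = NULL,
                         modes = list(), outputs = character(),
                         timings = NULL) {
  structure(list(
    package = "chainflow",
    version = as.character(utils::packageVersion("chainflow")),
    r_version = R.version.string,
    seed = seed,
    modes = modes,
    outputs = outputs,
    timings = as.list(timings),
    config = list(micro = if (!is.null(micro)) unclass(micro),
                  membrane = if (!is.null(membrane)) unclass(membrane))
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A `run_manifest`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
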