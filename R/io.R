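fmt_num_cols <- function(df, digits = 9) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.*g", digits, df[[nm]])
  df
}

#' Write a snapshot CSV (and optional VTK point cloud)
#'
#' Fixed header, numeric fields at 9 significant digits for cross-platform
#' diffs. The optional legacy-VTK POLYDATA file carries the points with the
#' radius and an integer state class as point data, viewable in standard VTK
#' viewers.
#'
#' @param snapshot a [snapshot_df()] table.
#' @param path output CSV path.
#' @param vtk also write `<path stem>.vtk`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path, vtk = FALSE) {
  write.csv(fmt_num_cols(snapshot), path, row.names = FALSE, quote = FALSE)
  if (vtk)
    write_vtk_points(snapshot, sub("\\.csv$", ".vtk", path))
  invisible(path)
}

#' Write a legacy-VTK point cloud of a snapshot
#'
#' @param snapshot a [snapshot_df()] table.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(snapshot, path) {
  n <- nrow(snapshot)
  class_code <- match(snapshot$class,
                      c("proliferative", "meiotic", "sperm", "oocyte")) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("germsim snapshot t=%.9g hph", snapshot$t_hph[1L]),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", snapshot$x, snapshot$y, snapshot$z),
             con)
  writeLines(c(sprintf("VERTICES %d %d", n, 2L * n)), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", snapshot$radius), con)
  writeLines(c("SCALARS state_class int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", class_code), con)
  invisible(path)
}

#' Write all outputs of a finished run
#'
#' Creates `snap_<t>.csv` per snapshot (plus `.vtk` when requested),
#' `events.csv`, `metrics.csv`, `lineage.csv`, `trajectories.csv` (when
#' tracking was enabled) and `config_resolved.cfg` in `dir`.
#'
#' @param sim a finished `germ_sim`.
#' @param dir output directory (created if missing).
#' @param vtk also write VTK point clouds.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(sim, dir, vtk = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sn in sim$snapshots)
    write_snapshot(sn, file.path(dir,
                                 sprintf("snap_%07.2f.csv", sn$t_hph[1L])),
                   vtk = vtk)
  write.csv(fmt_num_cols(event_log(sim)), file.path(dir, "events.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(fmt_num_cols(compute_metrics(sim)),
            file.path(dir, "metrics.csv"), row.names = FALSE, quote = FALSE)
  write.csv(fmt_num_cols(lineage_records(sim)),
            file.path(dir, "lineage.csv"), row.names = FALSE, quote = FALSE)
  if (length(sim$traj))
    write.csv(fmt_num_cols(trajectory_export(sim)),
              file.path(dir, "trajectories.csv"), row.names = FALSE,
              quote = FALSE)
  write_config(sim$config, file.path(dir, "config_resolved.cfg"))
  invisible(dir)
}
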