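#' Assign distal-proximal rows
#'
#' Row index = floor(distance-from-DTC / CD); row 0 abuts the DTC. Rows are
#' arclength bins of width one cell diameter, matching the CD axis used for
#' zone-length measurements.
#'
#' @param snapshot a [snapshot_df()] table (needs `dtc_dist`).
#' @param cd cell diameter (um, > 0).
#' @return integer row index per cell.
#' @export
assign_rows <- function(snapshot, cd) {
  stopifnot(cd > 0)
  as.integer(floor(snapshot$dtc_dist / cd))
}

is_meiotic_class <- function(class) class != "proliferative"

#' Proliferative zone length in rows (CD)
#'
#' The proliferative zone (mitotic region) is the area distal to the first
#' row containing two or more meiotic cells; its length is that row's index.
#' With no such row the convention is last occupied row + 1.
#'
#' @param rows integer row indices (from [assign_rows()]).
#' @param class cell classes (from [cell_classes()] / `snapshot$class`);
#'   everything not proliferative counts as meiotic here (committed cells,
#'   including sperm-fated ones, gametes).
#' @return zone length in rows.
#' @export
prolif_zone_length <- function(rows, class) {
  mei <- rows[is_meiotic_class(class)]
  if (length(mei)) {
    tab <- table(mei)
    hit <- as.integer(names(tab))[tab >= 2L]
    if (length(hit)) return(min(hit))
  }
  max(rows) + 1L
}

#' Proximal-most row containing a proliferative cell
#'
#' @inheritParams prolif_zone_length
#' @return largest row index holding at least one proliferative cell.
#' @export
proximal_most_prolif_row <- function(rows, class) {
  pr <- rows[class == "proliferative"]
  if (!length(pr))
    stop("no proliferative cells: zone lost", call. = FALSE)
  max(pr)
}

#' Mitotic index of the proliferative zone
#'
#' Fraction of cells within the zone (rows distal to the first two-meiotic
#' row) that are in M phase.
#'
#' @param snapshot a [snapshot_df()] table.
#' @param cd cell diameter (um).
#' @return fraction in [0, 1].
#' @export
mitotic_index <- function(snapshot, cd) {
  rows <- assign_rows(snapshot, cd)
  zone <- prolif_zone_length(rows, snapshot$class)
  inz <- rows < zone
  if (!any(inz)) stop("empty proliferative zone", call. = FALSE)
  sum(snapshot$CellCycle[inz] == "M") / sum(inz)
}

#' Internuclear distance index
#'
#' The distance from the distal tip to meiotic entry in microns divided by
#' the same distance in cell rows. The micron distance is read from the
#' actual position of the first row containing two or more meiotic cells;
#' the row count is obtained by clustering the zone cells' sorted
#' distances at gaps larger than the mean gap, which makes the count
#' invariant under a uniform axial compression while the micron distance
#' scales with it — so the index falls when cells pack tighter.
#'
#' @param snapshot a [snapshot_df()] table.
#' @param cd cell diameter (um), used only to locate the boundary row.
#' @return microns per cell row.
#' @export
internuclear_distance_index <- function(snapshot, cd) {
  rows <- assign_rows(snapshot, cd)
  mei <- is_meiotic_class(snapshot$class)
  b <- prolif_zone_length(rows, snapshot$class)
  if (!any(mei & rows == b))
    stop("no meiotic entry boundary", call. = FALSE)
  if (b == 0L)
    stop("meiotic boundary at row 0: index undefined", call. = FALSE)
  d_um <- min(snapshot$dtc_dist[mei & rows == b])
  zone_d <- sort(snapshot$dtc_dist[snapshot$dtc_dist < d_um])
  if (length(zone_d) < 2L)
    stop("too few cells distal to the boundary", call. = FALSE)
  gaps <- diff(zone_d)
  n_rows <- 1L + sum(gaps > mean(gaps))
  d_um / n_rows
}

#' Metrics report for one snapshot
#'
#' @param snapshot a [snapshot_df()] table.
#' @param cd cell diameter (um).
#' @param gonad_length_um total path length at snapshot time.
#' @return one-row data.frame with the census counts, zone lengths (CD and
#'   um), proximal-most proliferative row, mitotic index and internuclear
#'   distance index (NA where undefined).
#' @export
metrics_report <- function(snapshot, cd, gonad_length_um = NA_real_) {
  rows <- assign_rows(snapshot, cd)
  cls <- snapshot$class
  zone <- prolif_zone_length(rows, cls)
  mei <- is_meiotic_class(cls)
  zone_um <- if (any(mei & rows == zone))
    min(snapshot$dtc_dist[mei & rows == zone]) else NA_real_
  pmp <- tryCatch(proximal_most_prolif_row(rows, cls),
                  error = function(e) NA_integer_)
  mi <- tryCatch(mitotic_index(snapshot, cd), error = function(e) NA_real_)
  idi <- tryCatch(internuclear_distance_index(snapshot, cd),
                  error = function(e) NA_real_)
  data.frame(time_hph = snapshot$t_hph[1L],
             total = nrow(snapshot),
             proliferative = sum(cls == "proliferative"),
             meiotic = sum(cls == "meiotic"),
             sperm = sum(cls == "sperm"),
             oocyte = sum(cls == "oocyte"),
             gonad_length_um = gonad_length_um,
             prolif_zone_rows_CD = zone,
             prolif_zone_um = zone_um,
             proximal_most_prolif_row_CD = pmp,
             mitotic_index = mi,
             internuclear_distance_index = idi)
}

#' Metrics time-series of a run
#'
#' One [metrics_report()] row per recorded snapshot.
#'
#' @param sim a finished `germ_sim`.
#' @return data.frame, one row per snapshot.
#' @export
compute_metrics <- function(sim) {
  cd <- sim$config$path$cell_diameter_um
  out <- lapply(sim$snapshots, function(sn)
    metrics_report(sn, cd, gonad_length_um = NA_real_))
  res <- do.call(rbind, out)
  # gonad length is only known for the live geometry at the final snapshot;
  # reconstruct earlier lengths from the DTC's recorded maximum arclength
  lens <- vapply(sim$snapshots, function(sn)
    max(sn$s + sn$dtc_dist), 0)
  res$gonad_length_um <- lens
  res
}
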