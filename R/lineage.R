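#' Label cells for clonal tracking
#'
#' Selected cells receive distinct positive labels; all other cells keep (or
#' are reset to) the background label 0. Labels are inherited by daughter
#' cells at division, so each label marks the clone of one ancestor.
#' Relabeling at the same time with the same selection is idempotent.
#'
#' @param sim a `germ_sim`.
#' @param selection `"all"` to give every live cell its own label, or a
#'   numeric vector of fractions of the current gonad length (0 = proximal
#'   end, 1 = DTC); for each fraction the cell nearest that arclength is
#'   labeled (e.g. `c(0.9, 0.5, 0.1)` marks one distal, one mid and one
#'   proximal cell).
#' @return the simulation, invisibly; labels are updated in place.
#' @export
label_cells_at <- function(sim, selection = "all") {
  n <- length(sim$id)
  if (identical(selection, "all")) {
    labs <- seq_len(n)
    idx <- seq_len(n)
  } else {
    stopifnot(is.numeric(selection), all(selection >= 0 & selection <= 1))
    proj <- project_to_path(sim$geom, sim$pos)
    tgt <- selection * sim$geom$dtc_arclength
    idx <- vapply(tgt, function(s) which.min(abs(proj$s - s)), 0L)
    if (anyDuplicated(idx))
      stop("selection positions resolve to the same cell", call. = FALSE)
    labs <- seq_along(idx)
  }
  sim$label <- rep(0L, n)
  sim$label[idx] <- labs
  sim$lin$label[sim$id] <- sim$label
  invisible(sim)
}

#' Flat lineage records
#'
#' @param sim a `germ_sim`.
#' @return data.frame: one row per cell that ever existed, with id, parent id
#'   (NA for founders), clonal label, birth and end times (end NA while
#'   alive) and end cause (alive, division, apoptosis, ovulation,
#'   sperm_consumed).
#' @export
lineage_records <- function(sim) {
  n <- length(sim$lin$parent)
  data.frame(id = seq_len(n), parent = sim$lin$parent,
             label = sim$lin$label, birth_time = sim$lin$birth,
             end_time = sim$lin$end, end_cause = sim$lin$cause)
}

#' Clonality summary
#'
#' Counts the distinct ancestor labels surviving among live cells. The
#' monoclonal flag is true when exactly one non-background label remains
#' among the maintained germ line; sperm are excluded by default since the
#' neutral-drift question concerns the maintained (non-gamete) population.
#'
#' @param sim a `germ_sim`.
#' @param include_sperm count sperm in the surviving-label census.
#' @return list: `surviving_labels` (count of distinct non-background
#'   labels), `monoclonal` (logical), `per_label` (table of live cells per
#'   label, background included).
#' @export
clonality_summary <- function(sim, include_sperm = FALSE) {
  cls <- cell_classes(sim)
  keep <- if (include_sperm) rep(TRUE, length(cls)) else cls != "sperm"
  labs <- sim$label[keep]
  nz <- unique(labs[labs > 0L])
  list(surviving_labels = length(nz),
       monoclonal = length(nz) == 1L,
       per_label = table(factor(sim$label, levels = sort(unique(sim$label)))))
}

#' Export sampled trajectories
#'
#' Long-format table of the positions recorded while tracking was enabled.
#' Tracks of removed cells end at their removal time; a divided cell's track
#' ends at division and two new tracks begin.
#'
#' @param sim a `germ_sim` run with `track = TRUE`.
#' @return data.frame with columns t_hph, id, label, x, y, z, s.
#' @export
trajectory_export <- function(sim) {
  if (!length(sim$traj))
    stop("tracking was not enabled for this run", call. = FALSE)
  do.call(rbind, sim$traj)
}
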