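#' DTC path and migration specification
#'
#' The distal tip cell starts at the distal end of a short initial straight
#' path anchored at the proximal origin (the center of the animal) and
#' migrates along `distal_axis`. At the prescribed `turn_time_hph` it executes
#' a semicircular U-turn of radius `turn_radius_um` (wherever it happens to be
#' at that time) and then migrates back antiparallel to `distal_axis`. The
#' gonad boundary is the tube of radius r(t) around the path traced so far.
#'
#' @param turn_radius_um U-turn radius (um).
#' @param turn_time_hph prescribed turn time (hours post-hatch).
#' @param migration_rates named vector of stage rates (um/h) with entries
#'   `L3`, `L4`, `lateL4`, `adult`.
#' @param stage_times named vector with entries `t_L4`, `t_lateL4`, `t_adult`
#'   (hph) bounding the stages.
#' @param stretch_window numeric length-2, the late-L4 window (hph) during
#'   which the turn is displaced away from the center of the animal;
#'   `c(0, 0)` disables stretching.
#' @param stretch_rate_um_per_h turn displacement rate (um/h).
#' @param radius_times,radius_values piecewise-linear gonad radius schedule
#'   r(t) (hph, um).
#' @param initial_length_um path length already present at simulation start.
#' @param cell_diameter_um one cell diameter (um); the DTC pauses when its
#'   lead over the distal-most germ cell reaches this gap.
#' @return a `dtc_path_spec` list.
#' @export
dtc_path_spec <- function(turn_radius_um = 14,
                          turn_time_hph = 26,
                          migration_rates = c(L3 = 7, L4 = 9, lateL4 = 11,
                                              adult = 0),
                          stage_times = c(t_L4 = 25, t_lateL4 = 29.75,
                                          t_adult = 34.5),
                          stretch_window = c(29.75, 34.5),
                          stretch_rate_um_per_h = 22,
                          radius_times = c(15, 25, 34.5),
                          radius_values = c(5, 6, 11.5),
                          initial_length_um = 20,
                          cell_diameter_um = 70 / 13) {
  stopifnot(turn_radius_um > 0, all(migration_rates >= 0),
            length(stretch_window) == 2L,
            stretch_window[1] <= stretch_window[2],
            stretch_rate_um_per_h >= 0,
            length(radius_times) == length(radius_values),
            all(diff(radius_times) > 0), all(radius_values > 0),
            initial_length_um > 0, cell_diameter_um > 0)
  structure(as.list(environment()), class = "dtc_path_spec")
}

#' Time-dependent gonad geometry state
#'
#' @param spec a [dtc_path_spec()].
#' @return a `gonad_geometry` list: the path spec plus the mutable fields
#'   `dtc_arclength` (current DTC progress, um), `L1` (origin-to-turn length,
#'   `NA` until the turn begins), `turn_started`, and `stretch_total` (um of
#'   accumulated turn displacement).
#' @export
gonad_geometry <- function(spec = dtc_path_spec()) {
  stopifnot(inherits(spec, "dtc_path_spec"))
  structure(list(spec = spec,
                 dtc_arclength = spec$initial_length_um,
                 L1 = NA_real_, turn_started = FALSE,
                 stretch_total = 0),
            class = "gonad_geometry")
}

#' Gonad tube radius r(t)
#'
#' @param geom a `gonad_geometry`.
#' @param t time (hph).
#' @return radius (um), piecewise linear, constant beyond the schedule ends.
#' @export
gonad_radius <- function(geom, t) {
  stats::approx(geom$spec$radius_times, geom$spec$radius_values, t,
                rule = 2)$y
}

#' Stage migration rate of the DTC at time t
#'
#' @param geom a `gonad_geometry`.
#' @param t time (hph).
#' @return rate (um/h).
#' @export
dtc_migration_rate <- function(geom, t) {
  st <- geom$spec$stage_times
  r <- geom$spec$migration_rates
  if (t < st[["t_L4"]]) r[["L3"]]
  else if (t < st[["t_lateL4"]]) r[["L4"]]
  else if (t < st[["t_adult"]]) r[["lateL4"]]
  else r[["adult"]]
}

#' Total path length traced so far
#'
#' The boundary forms along the path of the DTC, so the domain ends at the
#' DTC's current arclength.
#'
#' @param geom a `gonad_geometry`.
#' @return length (um).
#' @export
path_total_length <- function(geom) geom$dtc_arclength

# arc helpers: the path runs from the origin along +x to x = L1, turns through
# a semicircle of radius Rt in the xy-plane (center (L1, Rt, 0)), then returns
# along -x at y = 2 Rt.

#' Point on the DTC path at a given arclength
#'
#' @param geom a `gonad_geometry`.
#' @param s arclength from the proximal origin (um); vectorized.
#' @return matrix of 3D points (um).
#' @export
path_point <- function(geom, s) {
  s <- pmax(0, s)
  n <- length(s)
  out <- matrix(0, n, 3L)
  if (!geom$turn_started) {
    out[, 1L] <- s
    return(out)
  }
  L1 <- geom$L1
  Rt <- geom$spec$turn_radius_um
  arc_end <- L1 + pi * Rt
  i1 <- s <= L1
  i2 <- s > L1 & s <= arc_end
  i3 <- s > arc_end
  out[i1, 1L] <- s[i1]
  th <- (s[i2] - L1) / Rt
  out[i2, 1L] <- L1 + Rt * sin(th)
  out[i2, 2L] <- Rt - Rt * cos(th)
  out[i3, 1L] <- L1 - (s[i3] - arc_end)
  out[i3, 2L] <- 2 * Rt
  out
}

#' Current DTC position
#'
#' @param geom a `gonad_geometry`.
#' @return 3D point (um).
#' @export
dtc_position <- function(geom) {
  drop(path_point(geom, geom$dtc_arclength))
}

#' Project points onto the DTC path
#'
#' Returns the arclength of the closest path point and the radial distance to
#' it. Only the path traced so far (s <= DTC arclength) exists, so points
#' beyond the tip project onto the tip. Ties at the turn resolve to the
#' smaller arclength.
#'
#' @param geom a `gonad_geometry`.
#' @param x n x 3 matrix (or 3-vector) of positions (um).
#' @return list with numeric vectors `s` (um) and `rho` (um).
#' @export
project_to_path <- function(geom, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, 3L)
  sd_ <- geom$dtc_arclength
  if (!geom$turn_started) {
    s <- pmin(pmax(x[, 1L], 0), sd_)
    rho <- sqrt((x[, 1L] - s)^2 + x[, 2L]^2 + x[, 3L]^2)
    return(list(s = s, rho = rho))
  }
  L1 <- geom$L1
  Rt <- geom$spec$turn_radius_um
  arc_end <- L1 + pi * Rt
  # candidate 1: proximal limb [0, min(L1, sd_)]
  s1 <- pmin(pmax(x[, 1L], 0), min(L1, sd_))
  d1 <- sqrt((x[, 1L] - s1)^2 + x[, 2L]^2 + x[, 3L]^2)
  best_s <- s1; best_d <- d1
  # candidate 2: the arc, up to the DTC if it is still inside the turn
  if (sd_ > L1) {
    th_max <- (min(sd_, arc_end) - L1) / Rt
    th <- atan2(x[, 1L] - L1, Rt - x[, 2L])
    th <- pmin(pmax(th, 0), th_max)
    px <- L1 + Rt * sin(th)
    py <- Rt - Rt * cos(th)
    d2 <- sqrt((x[, 1L] - px)^2 + (x[, 2L] - py)^2 + x[, 3L]^2)
    s2 <- L1 + Rt * th
    upd <- d2 < best_d - 1e-12
    best_s[upd] <- s2[upd]; best_d[upd] <- d2[upd]
  }
  # candidate 3: return limb
  if (sd_ > arc_end) {
    v <- pmin(pmax(L1 - x[, 1L], 0), sd_ - arc_end)
    px <- L1 - v
    d3 <- sqrt((x[, 1L] - px)^2 + (x[, 2L] - 2 * Rt)^2 + x[, 3L]^2)
    s3 <- arc_end + v
    upd <- d3 < best_d - 1e-12
    best_s[upd] <- s3[upd]; best_d[upd] <- d3[upd]
  }
  list(s = best_s, rho = best_d)
}

# radial rescale helper: move x to radial distance rho_new from its path point
radial_place <- function(geom, x, proj, idx, rho_new) {
  if (!length(idx)) return(x)
  p <- path_point(geom, proj$s[idx])
  d <- x[idx, , drop = FALSE] - p
  rho <- proj$rho[idx]
  deg <- rho < 1e-9
  if (any(deg)) {
    # degenerate on-axis point: push along a fixed perpendicular; for path
    # tangents in the xy-plane, z is always perpendicular
    d[deg, ] <- matrix(c(0, 0, 1), sum(deg), 3L, byrow = TRUE)
    rho[deg] <- 1
  }
  x[idx, ] <- p + d * (rho_new[seq_along(idx)] / rho)
  x
}

#' Confine cells to the gonad tube
#'
#' Cells whose surface would cross the boundary (radial distance + radius
#' beyond r(t)) are moved radially inward so they touch it from inside;
#' points beyond the DTC tip are handled by projection onto the tip.
#'
#' @param geom a `gonad_geometry`.
#' @param pos n x 3 position matrix.
#' @param radius cell radii (um).
#' @param t time (hph).
#' @return updated position matrix.
#' @export
enforce_tube <- function(geom, pos, radius, t) {
  if (!nrow(pos)) return(pos)
  rt <- gonad_radius(geom, t)
  if (any(rt < radius))
    stop("gonad radius smaller than a cell radius; invalid configuration",
         call. = FALSE)
  proj <- project_to_path(geom, pos)
  viol <- which(proj$rho + radius > rt)
  radial_place(geom, pos, proj, viol, rt - radius[viol])
}

#' Enforce the rachis annulus
#'
#' Cells distal to and within the turn are kept to a single layer lining the
#' tube wall, leaving a hollow core (the rachis) of radius r(t) - 2 radius:
#' cells closer to the axis are moved radially outward. Cells proximal to the
#' turn are unaffected; before the turn exists the whole (distal) arm is
#' constrained. Where the tube is thinner than two cell radii the constraint
#' is skipped for that cell.
#'
#' @inheritParams enforce_tube
#' @return updated position matrix.
#' @export
enforce_rachis <- function(geom, pos, radius, t) {
  if (!nrow(pos)) return(pos)
  rt <- gonad_radius(geom, t)
  proj <- project_to_path(geom, pos)
  in_region <- if (geom$turn_started) proj$s >= geom$L1 else rep(TRUE, nrow(pos))
  target <- rt - 2 * radius
  viol <- which(in_region & target > 0 & proj$rho < target)
  radial_place(geom, pos, proj, viol, target[viol])
}

#' Advance the DTC along its path
#'
#' The DTC attempts `rate * dt` of migratory progress but only advances while
#' germ cells abut it: if its lead over the distal-most cell would reach one
#' cell diameter, the advance is truncated (the DTC pauses) for the remainder
#' of the step. The prescribed turn time fixes when the turn occurs, so a
#' frequently paused DTC turns closer to the center of the animal.
#'
#' @param geom a `gonad_geometry`.
#' @param t time (hph).
#' @param dt step (hours).
#' @param cell_s cell arclengths (um); `numeric(0)` blocks all progress.
#' @param pausing logical; `FALSE` disables the pause rule.
#' @return updated `gonad_geometry`.
#' @export
update_dtc <- function(geom, t, dt, cell_s, pausing = TRUE) {
  if (!geom$turn_started && t >= geom$spec$turn_time_hph) {
    geom$L1 <- geom$dtc_arclength
    geom$turn_started <- TRUE
  }
  target <- dtc_migration_rate(geom, t) * dt
  if (pausing) {
    gap <- if (length(cell_s)) geom$dtc_arclength - max(cell_s) else Inf
    target <- min(target, max(0, geom$spec$cell_diameter_um - gap))
  }
  geom$dtc_arclength <- geom$dtc_arclength + target
  geom
}

#' Apply late-L4 gonadal stretching
#'
#' Within the stretch window the boundary turn is displaced along the distal
#' axis at the stretch rate, lengthening both the proximal limb and the return
#' limb: the total path grows by twice the displacement per step. Cells move
#' with the stretching frame: the proximal limb is stretched affinely, cells
#' in the turn translate rigidly with it, and cells in the return limb keep
#' their physical position (the path lengthens behind them). The DTC
#' arclength is remapped to the same material point.
#'
#' @param geom a `gonad_geometry`.
#' @param t time (hph).
#' @param dt step (hours).
#' @param pos n x 3 cell position matrix (may have zero rows).
#' @return list with updated `geom` and `pos`.
#' @export
apply_stretch <- function(geom, t, dt, pos) {
  w <- geom$spec$stretch_window
  if (t < w[1] || t >= w[2] || !geom$turn_started ||
      geom$spec$stretch_rate_um_per_h <= 0)
    return(list(geom = geom, pos = pos))
  delta <- geom$spec$stretch_rate_um_per_h * dt
  L1 <- geom$L1
  Rt <- geom$spec$turn_radius_um
  arc_end <- L1 + pi * Rt
  if (nrow(pos)) {
    proj <- project_to_path(geom, pos)
    limb1 <- proj$s < L1 & pos[, 1L] > 0
    turn <- proj$s >= L1 & proj$s <= arc_end
    sc <- (L1 + delta) / L1
    pos[limb1, 1L] <- pos[limb1, 1L] * sc
    pos[turn, 1L] <- pos[turn, 1L] + delta
  }
  geom$L1 <- L1 + delta
  geom$dtc_arclength <- geom$dtc_arclength +
    if (geom$dtc_arclength > arc_end) 2 * delta else delta
  geom$stretch_total <- geom$stretch_total + delta
  list(geom = geom, pos = pos)
}
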