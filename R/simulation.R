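#' Simulation configuration
#'
#' Bundles every module's parameters with the stage schedule and numerical
#' settings. Simulations begin immediately after the establishment of the two
#' gonad arms at the end of L2 and cover larval development and adult
#' homeostasis of a single arm.
#'
#' @param seed RNG seed; a single stream drives every stochastic element.
#' @param t_start_hph,t_L4_hph,t_adult_hph,t_end_hph stage boundaries (hours
#'   post-hatch), strictly increasing.
#' @param dt simulation step (hours); statecharts and mechanics share it.
#' @param output_every_h snapshot cadence (hours).
#' @param n_founders number of germ cells at t_start.
#' @param base_radius_um base mitotic cell radius (um); one cell diameter
#'   (CD) is twice this.
#' @param cc,sig,fate,force,path module parameter objects; see
#'   [cell_cycle_params()], [signaling_params()], [fate_params()],
#'   [force_params()], [dtc_path_spec()].
#' @param contact_inhibition logical; compression arrest of the adult G2.
#' @param dtc_pausing logical; DTC pauses when it outpaces germ cells.
#' @param track logical; record trajectories.
#' @param traj_every_h trajectory sampling cadence (hours).
#' @param death_sweep candidate per-hour apoptosis probabilities explored by
#'   the no-feedback scenario.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              t_start_hph = 15, t_L4_hph = 25,
                              t_adult_hph = 34.5, t_end_hph = 120,
                              dt = 0.01,
                              output_every_h = 1,
                              n_founders = 16L,
                              base_radius_um = 2.7,
                              cc = NULL, sig = signaling_params(),
                              fate = fate_params(),
                              force = NULL, path = NULL,
                              contact_inhibition = TRUE,
                              dtc_pausing = TRUE,
                              track = FALSE, traj_every_h = 0.5,
                              death_sweep = c(0.05, 0.1, 0.2)) {
  stopifnot(t_start_hph < t_L4_hph, t_L4_hph < t_adult_hph,
            t_adult_hph < t_end_hph, dt > 0, n_founders >= 1L,
            base_radius_um > 0)
  mid_L4 <- t_L4_hph + (t_adult_hph - t_L4_hph) / 2
  if (is.null(cc))
    cc <- cell_cycle_params(ramp_start_hph = mid_L4,
                            ramp_end_hph = t_adult_hph)
  if (is.null(force)) force <- force_params(dt_mech = dt)
  if (is.null(path))
    path <- dtc_path_spec(stage_times = c(t_L4 = t_L4_hph,
                                          t_lateL4 = mid_L4,
                                          t_adult = t_adult_hph),
                          stretch_window = c(mid_L4, t_adult_hph),
                          radius_times = c(t_start_hph, t_L4_hph,
                                           t_adult_hph))
  structure(list(seed = as.integer(seed), t_start_hph = t_start_hph,
                 t_L4_hph = t_L4_hph, t_adult_hph = t_adult_hph,
                 t_end_hph = t_end_hph, dt = dt,
                 output_every_h = output_every_h,
                 n_founders = as.integer(n_founders),
                 base_radius_um = base_radius_um,
                 cc = cc, sig = sig, fate = fate, force = force, path = path,
                 contact_inhibition = contact_inhibition,
                 dtc_pausing = dtc_pausing, track = track,
                 traj_every_h = traj_every_h, death_sweep = death_sweep),
            class = "simulation_config")
}

new_event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

log_event <- function(sim, ids, kind, pos, s, dist) {
  if (!length(ids)) return(invisible())
  sim$evlog$rows[[length(sim$evlog$rows) + 1L]] <-
    data.frame(time = sim$t, cell = ids, event = kind,
               x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
               s = s, dtc_dist = dist)
  invisible()
}

#' Ordered event log of a simulation
#'
#' @param sim a `germ_sim`.
#' @return data.frame with columns time, cell, event, x, y, z, s (arclength),
#'   dtc_dist; rows in emission order.
#' @export
event_log <- function(sim) {
  if (!length(sim$evlog$rows))
    return(data.frame(time = numeric(), cell = integer(),
                      event = character(), x = numeric(), y = numeric(),
                      z = numeric(), s = numeric(), dtc_dist = numeric()))
  do.call(rbind, sim$evlog$rows)
}

sample_cycle_durations <- function(n, t, cc) {
  mu <- cycle_phase_means(t, cc)
  list(G1 = sample_phase_duration(mu[["G1"]], cc$s, n),
       S = rep_len(mu[["S"]], n),
       G2 = sample_phase_duration(mu[["G2"]], cc$s, n),
       M = rep_len(mu[["M"]], n))
}

#' Initialize a germline simulation
#'
#' Seeds the RNG, builds the germline chart and geometry, and packs
#' `n_founders` germ cells at the distal end of the initial path. Each
#' founder's cell-cycle region starts at a uniformly random point of the
#' cycle: the phase is chosen with probability proportional to its expected
#' duration and the elapsed time is uniform within the phase. All other
#' regions start in their initial states (receptor Unbound, LAG-1 Active,
#' GLD Inactive, sex Precursor).
#'
#' @param config a [simulation_config()].
#' @return a `germ_sim` environment.
#' @export
initialize_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_founders
  chart <- germline_chart(config$cc, config$sig, config$fate,
                          contact_inhibition = config$contact_inhibition)
  geom <- gonad_geometry(config$path)
  t0 <- config$t_start_hph
  r0 <- gonad_radius(geom, t0)
  cd <- config$path$cell_diameter_um
  s0 <- geom$dtc_arclength

  # pack the founders into the distal-most few cell diameters of the tube
  s_init <- runif(n, max(0, s0 - 3 * cd), s0)
  phi <- runif(n, 0, 2 * pi)
  rho <- runif(n, 0, max(0, r0 - config$base_radius_um))
  pos <- cbind(s_init, rho * cos(phi), rho * sin(phi))
  dimnames(pos) <- NULL

  # duration-weighted random cycle phase
  mu <- cycle_phase_means(t0, config$cc)
  dur <- sample_cycle_durations(n, t0, config$cc)
  phase <- sample(c("G1", "S", "G2", "M"), n, replace = TRUE,
                  prob = mu / sum(mu))
  elapsed <- runif(n) * mapply(function(p, i) dur[[p]][i], phase, seq_len(n))

  sc <- sc_init(chart, n, active = list(CellCycle = phase))
  sc$timers$CellCycle <- as.numeric(elapsed)

  sim <- new.env(parent = emptyenv())
  class(sim) <- c("germ_sim", "environment")
  sim$config <- config
  sim$chart <- chart
  sim$geom <- geom
  sim$t <- t0
  sim$pos <- pos
  sim$radius <- rep(config$base_radius_um, n)
  sim$id <- seq_len(n)
  sim$label <- rep(0L, n)
  sim$next_id <- n + 1L
  sim$sc <- sc
  sim$dur <- c(dur, list(meiG1 = rep(config$cc$fixed_meiotic_G1, n),
                         meiS = rep(config$cc$fixed_meiotic_S, n)))
  sim$sperm_divisions_remaining <- rep(2L, n)
  sim$evlog <- new_event_log()
  sim$snapshots <- list()
  sim$traj <- list()
  sim$lin <- list(parent = rep(NA_integer_, n),
                  label = rep(0L, n),
                  birth = rep(t0, n),
                  end = rep(NA_real_, n),
                  cause = rep("alive", n))
  # settle the founders inside the boundary
  sim$pos <- enforce_tube(geom, sim$pos, sim$radius, t0)
  sim$pos <- enforce_rachis(geom, sim$pos, sim$radius, t0)
  sim
}

#' @export
print.germ_sim <- function(x, ...) {
  cn <- census(x)
  cat(sprintf(
    "germline simulation at %.2f hph: %d cells (%d proliferative, %d meiotic, %d sperm, %d oocyte); gonad %.1f um\n",
    x$t, cn[["total"]], cn[["proliferative"]], cn[["meiotic"]],
    cn[["sperm"]], cn[["oocyte"]], path_total_length(x$geom)))
  invisible(x)
}

#' Classify each live cell
#'
#' Mutually exclusive classes: `sperm`, `oocyte` (oocyte-fated or mature),
#' `proliferative` (mitotic cycle phases), `meiotic` (committed meiotic
#' pathway, including sperm-fated cells that have not yet produced sperm).
#'
#' @param sim a `germ_sim`.
#' @return character vector, one class per cell.
#' @export
cell_classes <- function(sim) {
  sex <- sc_active(sim$sc, sim$chart, "SexDetermination")
  cyc <- sc_active(sim$sc, sim$chart, "CellCycle")
  out <- rep("meiotic", length(sex))
  out[cyc %in% c("G1", "S", "G2", "M")] <- "proliferative"
  out[sex %in% c("OocyteFated", "MatureOocyte")] <- "oocyte"
  out[sex == "Sperm"] <- "sperm"
  out
}

#' Census of a simulation state
#'
#' @param sim a `germ_sim`.
#' @return named integer vector: total, proliferative, meiotic, sperm, oocyte.
#' @export
census <- function(sim) {
  cls <- cell_classes(sim)
  c(total = length(cls),
    proliferative = sum(cls == "proliferative"),
    meiotic = sum(cls == "meiotic"),
    sperm = sum(cls == "sperm"),
    oocyte = sum(cls == "oocyte"))
}

# append daughters for dividing parents; returns daughter indices
divide_cells <- function(sim, parents) {
  if (!length(parents)) return(invisible())
  parents <- sort(unique(parents))
  cfg <- sim$config
  m <- length(parents)
  # uniformly random division axes, one per parent in index order
  v <- matrix(rnorm(3L * m), m, 3L)
  v <- v / sqrt(rowSums(v^2))
  br <- cfg$base_radius_um
  ppos <- sim$pos[parents, , drop = FALSE]
  pid <- sim$id[parents]
  proj <- project_to_path(sim$geom, ppos)
  log_event(sim, pid, "division", ppos, proj$s,
            sim$geom$dtc_arclength - proj$s)

  d1_pos <- ppos + 0.5 * br * v
  d2_pos <- ppos - 0.5 * br * v
  ids <- sim$next_id + seq_len(2L * m) - 1L
  d1_id <- ids[seq_len(m)]
  d2_id <- ids[m + seq_len(m)]
  sim$next_id <- sim$next_id + 2L * m

  # daughter 1 reuses the parent's row, daughter 2 is appended
  sim$pos[parents, ] <- d1_pos
  sim$pos <- rbind(sim$pos, d2_pos)
  sim$radius[parents] <- br
  sim$radius <- c(sim$radius, rep(br, m))
  lab <- sim$label[parents]
  sim$id[parents] <- d1_id
  sim$id <- c(sim$id, d2_id)
  sim$label <- c(sim$label, lab)

  fk <- sc_fork(sim$sc, parents)
  sim$sc <- fk$state
  # both daughters resample every phase duration
  for (rows in list(parents, fk$daughters)) {
    dur <- sample_cycle_durations(m, sim$t, cfg$cc)
    sim$dur$G1[rows] <- dur$G1; sim$dur$S[rows] <- dur$S
    sim$dur$G2[rows] <- dur$G2; sim$dur$M[rows] <- dur$M
  }
  sim$dur$meiG1 <- c(sim$dur$meiG1, rep(cfg$cc$fixed_meiotic_G1, m))
  sim$dur$meiS <- c(sim$dur$meiS, rep(cfg$cc$fixed_meiotic_S, m))
  rem <- sim$sperm_divisions_remaining[parents]
  sim$sperm_divisions_remaining <- c(sim$sperm_divisions_remaining, rem)

  # lineage: the parent's record closes, two new records open
  sim$lin$end[pid] <- sim$t
  sim$lin$cause[pid] <- "division"
  grow <- function(x, val) { x[ids] <- val; x }
  sim$lin$parent <- grow(sim$lin$parent, rep(pid, 2L))
  sim$lin$label <- grow(sim$lin$label, rep(lab, 2L))
  sim$lin$birth <- grow(sim$lin$birth, sim$t)
  sim$lin$end <- grow(sim$lin$end, NA_real_)
  sim$lin$cause <- grow(sim$lin$cause, "alive")

  log_event(sim, c(d1_id, d2_id), "birth", rbind(d1_pos, d2_pos),
            rep(proj$s, 2L), rep(sim$geom$dtc_arclength - proj$s, 2L))
  invisible()
}

remove_cells <- function(sim, idx, cause) {
  if (!length(idx)) return(invisible())
  ids <- sim$id[idx]
  sim$lin$end[ids] <- sim$t
  sim$lin$cause[ids] <- cause
  keep <- setdiff(seq_along(sim$id), idx)
  sim$pos <- sim$pos[keep, , drop = FALSE]
  sim$radius <- sim$radius[keep]
  sim$id <- sim$id[keep]
  sim$label <- sim$label[keep]
  for (f in names(sim$dur)) sim$dur[[f]] <- sim$dur[[f]][keep]
  sim$sperm_divisions_remaining <- sim$sperm_divisions_remaining[keep]
  sim$sc <- sc_remove(sim$sc, idx)
  invisible()
}

#' Process ovulation
#'
#' A mature oocyte within one oocyte diameter of the proximal path end is
#' removed together with exactly one sperm (the proximal-most); with no sperm
#' remaining, no ovulation occurs and oocytes accumulate.
#'
#' @param sim a `germ_sim`.
#' @return integer vector of removed cell row indices (oocytes and sperm).
#' @export
ovulate <- function(sim) {
  sex <- sc_active(sim$sc, sim$chart, "SexDetermination")
  proj <- project_to_path(sim$geom, sim$pos)
  lim <- 2 * sim$config$fate$oocyte_mature_radius_um
  ooc <- which(sex == "MatureOocyte" & proj$s < lim)
  if (!length(ooc)) return(integer())
  sperm <- which(sex == "Sperm")
  k <- min(length(ooc), length(sperm))
  if (k == 0L) return(integer())
  ooc <- ooc[order(proj$s[ooc])][seq_len(k)]
  sperm <- sperm[order(proj$s[sperm])][seq_len(k)]
  log_event(sim, sim$id[ooc], "ovulation_oocyte",
            sim$pos[ooc, , drop = FALSE], proj$s[ooc],
            sim$geom$dtc_arclength - proj$s[ooc])
  log_event(sim, sim$id[sperm], "ovulation_sperm",
            sim$pos[sperm, , drop = FALSE], proj$s[sperm],
            sim$geom$dtc_arclength - proj$s[sperm])
  c(ooc, sperm)
}

#' Advance the simulation by one step
#'
#' Fixed sub-step order: (1) build the per-cell context (arclength distance
#' to the DTC, compressed-volume fraction, stage); (2) step all statecharts
#' against that frozen context; (3) process emitted events: growth, phase
#' resampling, divisions, apoptosis and ovulation removals; (4) compute
#' repulsion forces and integrate positions; (5) enforce the tube and rachis
#' constraints; (6) advance the DTC and apply stretching; (7) advance the
#' clock.
#'
#' @param sim a `germ_sim` (modified in place).
#' @return the simulation, invisibly.
#' @export
step_simulation <- function(sim) {
  cfg <- sim$config
  dt <- cfg$dt
  t <- sim$t
  n <- length(sim$id)
  geom <- sim$geom

  # (1) context
  proj <- project_to_path(geom, sim$pos)
  dist <- geom$dtc_arclength - proj$s
  split_r <- cfg$fate$max_meiotic_radius_um + 0.1
  pairs <- if (is.null(cfg$force$neighbor_cutoff))
    contact_pairs(sim$pos, sim$radius, split_r)
  else find_neighbors(sim$pos, cfg$force$neighbor_cutoff)
  vf <- compressed_fractions(sim$pos, sim$radius, pairs)
  ctx <- list(time_hph = t, dtc_distance_um = dist, volume_fraction = vf,
              radius_um = sim$radius,
              life_stage = life_stage_at(t, cfg$cc),
              dur_G1 = sim$dur$G1, dur_S = sim$dur$S, dur_G2 = sim$dur$G2,
              dur_M = sim$dur$M, dur_meiG1 = sim$dur$meiG1,
              dur_meiS = sim$dur$meiS,
              sperm_divisions_remaining = sim$sperm_divisions_remaining)

  # (2) statecharts
  res <- sc_step(sim$sc, sim$chart, ctx, dt)
  sim$sc <- res$state
  ev <- res$events

  # (3) events
  if (!is.null(ev$resample_G1)) {
    i <- ev$resample_G1
    mu <- cycle_phase_means(t, cfg$cc)
    sim$dur$G1[i] <- sample_phase_duration(mu[["G1"]], cfg$cc$s, length(i))
  }
  if (!is.null(ev$resample_G2)) {
    i <- ev$resample_G2
    mu <- cycle_phase_means(t, cfg$cc)
    sim$dur$G2[i] <- sample_phase_duration(mu[["G2"]], cfg$cc$s, length(i))
  }
  for (kind in c("meiotic_entry", "commit_sperm", "commit_oocyte",
                 "oocyte_mature", "sperm_division"))
    if (!is.null(ev[[kind]]))
      log_event(sim, sim$id[ev[[kind]]], kind,
                sim$pos[ev[[kind]], , drop = FALSE], proj$s[ev[[kind]]],
                dist[ev[[kind]]])

  if (!is.null(ev$become_sperm))
    sim$radius[ev$become_sperm] <- cfg$fate$sperm_radius_um

  # growth: oocyte-fated cells follow the oocyte rule, other meiotic cells
  # (sperm excluded, they are terminal) the meiotic cap
  sex <- sc_active(sim$sc, sim$chart, "SexDetermination")
  if (!is.null(ev$grow_meiotic)) {
    i <- setdiff(ev$grow_meiotic,
                 which(sex %in% c("OocyteFated", "MatureOocyte", "Sperm")))
    if (length(i))
      sim$radius[i] <- grow_cell(sim$radius[i], "meiotic", cfg$fate, dt)
  }
  if (!is.null(ev$grow_oocyte))
    sim$radius[ev$grow_oocyte] <-
      grow_cell(sim$radius[ev$grow_oocyte], "oocyte", cfg$fate, dt)

  # apoptosis draw for immature oocyte-fated cells
  dead <- integer()
  if (!is.null(ev$apoptosis_check) && length(ev$apoptosis_check)) {
    i <- sort(ev$apoptosis_check)
    die <- apoptosis_draw(list(dtc_distance_um = dist[i],
                               life_stage = ctx$life_stage),
                          cfg$fate, dt)
    dead <- i[die]
    if (length(dead))
      log_event(sim, sim$id[dead], "apoptosis",
                sim$pos[dead, , drop = FALSE], proj$s[dead], dist[dead])
  }

  # sperm divisions decrement the remaining count before the fork copies it
  if (!is.null(ev$sperm_division)) {
    i <- ev$sperm_division
    sim$sperm_divisions_remaining[i] <-
      sim$sperm_divisions_remaining[i] - 1L
  }
  divide_cells(sim, c(ev$divide, ev$sperm_division))

  remove_cells(sim, dead, "apoptosis")
  ovu <- ovulate(sim)
  if (length(ovu)) {
    half <- length(ovu) / 2L
    remove_cells(sim, ovu,
                 rep(c("ovulation", "sperm_consumed"), each = half))
  }

  # (4) mechanics: adaptively substep so no update moves a cell further
  # than the displacement limit (transient force spikes at divisions)
  n2 <- length(sim$id)
  if (n2) {
    remaining <- dt
    for (it in seq_len(64L)) {
      pairs2 <- if (is.null(cfg$force$neighbor_cutoff))
        contact_pairs(sim$pos, sim$radius, split_r)
      else find_neighbors(sim$pos, cfg$force$neighbor_cutoff)
      f <- repulsion_forces(sim$pos, sim$radius, pairs2, cfg$force, sim$id)
      # per-cell safety: no cell may move further than 0.45 x its own
      # radius in one update, so fast (large) cells do not force tiny
      # global substeps
      vscaled <- max(sqrt(rowSums(f^2)) / (0.45 * sim$radius)) /
        cfg$force$drag
      h <- if (vscaled * remaining > 1) 1 / vscaled else remaining
      sim$pos <- sim$pos + f * (h / cfg$force$drag)
      remaining <- remaining - h
      if (remaining <= 1e-12) break
    }
    # (5) boundary
    sim$pos <- enforce_tube(sim$geom, sim$pos, sim$radius, t)
    sim$pos <- enforce_rachis(sim$geom, sim$pos, sim$radius, t)
  }

  # (6) DTC migration and stretching
  proj3 <- project_to_path(sim$geom, sim$pos)
  sim$geom <- update_dtc(sim$geom, t, dt, proj3$s,
                         pausing = cfg$dtc_pausing)
  st <- apply_stretch(sim$geom, t, dt, sim$pos)
  sim$geom <- st$geom
  sim$pos <- st$pos

  # (7) clock
  sim$t <- t + dt
  invisible(sim)
}

#' Per-cell snapshot table
#'
#' @param sim a `germ_sim`.
#' @return data.frame: one row per live cell with time, id, position, radius,
#'   active state of every region, lineage label, arclength `s`, distance to
#'   the DTC and cell class.
#' @export
snapshot_df <- function(sim) {
  proj <- project_to_path(sim$geom, sim$pos)
  df <- data.frame(t_hph = sim$t, id = sim$id,
                   x = sim$pos[, 1L], y = sim$pos[, 2L], z = sim$pos[, 3L],
                   radius = sim$radius)
  for (rn in names(sim$chart))
    df[[rn]] <- sc_active(sim$sc, sim$chart, rn)
  df$label <- sim$label
  df$s <- proj$s
  df$dtc_dist <- sim$geom$dtc_arclength - proj$s
  df$class <- cell_classes(sim)
  df
}

#' Run (or continue) a simulation up to a time
#'
#' Steps the simulation until the clock reaches `until`, recording a snapshot
#' every `output_every_h` hours (and trajectory samples every `traj_every_h`
#' when tracking is enabled). May be called repeatedly on the same simulation
#' to run it in stages.
#'
#' @param sim a `germ_sim` from [initialize_simulation()].
#' @param until stop time (hph).
#' @param progress print a census line every simulated hour.
#' @return the simulation, invisibly.
#' @export
simulate_until <- function(sim, until, progress = FALSE) {
  cfg <- sim$config
  eps <- 1e-9
  if (is.null(sim$next_snap)) {
    sim$snapshots[[length(sim$snapshots) + 1L]] <- snapshot_df(sim)
    sim$next_snap <- sim$t + cfg$output_every_h
    sim$next_traj <- sim$t
  }
  while (sim$t < until - eps) {
    if (cfg$track && sim$t >= sim$next_traj - eps) {
      proj <- project_to_path(sim$geom, sim$pos)
      sim$traj[[length(sim$traj) + 1L]] <-
        data.frame(t_hph = sim$t, id = sim$id, label = sim$label,
                   x = sim$pos[, 1L], y = sim$pos[, 2L],
                   z = sim$pos[, 3L], s = proj$s)
      sim$next_traj <- sim$next_traj + cfg$traj_every_h
    }
    step_simulation(sim)
    if (sim$t >= sim$next_snap - eps) {
      sim$snapshots[[length(sim$snapshots) + 1L]] <- snapshot_df(sim)
      sim$next_snap <- sim$next_snap + cfg$output_every_h
      if (progress) print(sim)
    }
  }
  invisible(sim)
}

#' Initialize and run a simulation
#'
#' @param config a [simulation_config()].
#' @param until stop time (hph); defaults to the configured end time.
#' @param progress print a census line every simulated hour.
#' @return the finished `germ_sim`.
#' @export
run_simulation <- function(config = simulation_config(), until = NULL,
                           progress = FALSE) {
  sim <- initialize_simulation(config)
  simulate_until(sim, if (is.null(until)) config$t_end_hph else until,
                 progress = progress)
  sim
}
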