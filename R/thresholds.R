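# Single-cell statechart probes. These drive the germline chart with an
# imposed context, independent of any tissue simulation, and recover its
# decision boundaries by bisection; used for verification and reporting.

default_probe_ctx <- function(n = 1L) {
  list(time_hph = 25, dtc_distance_um = 10, volume_fraction = 1,
       radius_um = 2.7, life_stage = "larval",
       dur_G1 = rep(Inf, n), dur_S = rep(Inf, n), dur_G2 = rep(Inf, n),
       dur_M = rep(Inf, n), dur_meiG1 = rep(Inf, n),
       dur_meiS = rep(Inf, n),
       sperm_divisions_remaining = rep(2L, n))
}

step_single <- function(chart, active, ctx_over = list(), dt = 0.01) {
  st <- sc_init(chart, 1L, active = active)
  ctx <- default_probe_ctx(1L)
  ctx[names(ctx_over)] <- ctx_over
  sc_step(st, chart, ctx, dt)
}

#' Locate a decision boundary by bisection
#'
#' `pred` must be a deterministic logical function of a scalar, taking one
#' value on `[lo, boundary)` and the other on `(boundary, hi]`. Returns the
#' boundary to within `tol`.
#'
#' @param pred function(x) -> logical.
#' @param lo,hi bracketing values with `pred(lo) != pred(hi)`.
#' @param tol absolute tolerance.
#' @return the located boundary (midpoint of the final bracket).
#' @export
bisect_boundary <- function(pred, lo, hi, tol = 0.005) {
  plo <- pred(lo)
  if (pred(hi) == plo) stop("pred does not change over [lo, hi]",
                            call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid) == plo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Recover the germline chart's printed thresholds by bisection
#'
#' Probes a single cell's statechart with an imposed context and locates
#' every decision boundary: GLP-1 receptor binding distance, GLP-1 signal
#' loss distance, sex-determination distance, the sperm/oocyte time boundary,
#' the G2 compression-arrest volume fraction, the apoptosis protection
#' distance (probed with the death probability forced to certainty over one
#' hour), the meiotic growth cap and the oocyte maturity radius.
#'
#' @param cc,sig,fate parameter objects (defaults as configured).
#' @param tol bisection tolerance for distances/times (um or hours).
#' @return named numeric vector: `glp1_bound_um`, `glp1_absent_um`,
#'   `sex_decision_um`, `sperm_time_hph`, `g2_arrest_percent`,
#'   `apoptosis_protect_um`, `meiotic_radius_cap_um`, `oocyte_mature_um`.
#' @export
germline_thresholds <- function(cc = cell_cycle_params(),
                                sig = signaling_params(),
                                fate = fate_params(),
                                tol = 0.005) {
  chart <- germline_chart(cc, sig, fate)

  binds <- function(d)
    sc_active(step_single(chart, list(CellCycle = "G1"),
                          list(dtc_distance_um = d))$state,
              chart, "GLP1Receptor") == "Bound"
  glp1_bound <- bisect_boundary(binds, 0, 1000, tol)

  absent <- function(d)
    sc_active(step_single(chart,
                          list(CellCycle = "G1", GLP1Receptor = "Bound"),
                          list(dtc_distance_um = d))$state,
              chart, "GLP1Receptor") == "Absent"
  glp1_absent <- bisect_boundary(absent, 36, 1000, tol)

  commits <- function(d)
    sc_active(step_single(chart, list(CellCycle = "MeioticProphase"),
                          list(dtc_distance_um = d))$state,
              chart, "SexDetermination") != "Precursor"
  sex_um <- bisect_boundary(commits, 71, 1000, tol)

  sperm <- function(t)
    sc_active(step_single(chart, list(CellCycle = "MeioticProphase"),
                          list(dtc_distance_um = sex_um + 10,
                               time_hph = t))$state,
              chart, "SexDetermination") == "SpermFated"
  sperm_t <- bisect_boundary(sperm, 0, 100, tol)

  arrested <- function(vf) {
    res <- step_single(chart, list(CellCycle = "G2"),
                       list(volume_fraction = vf, life_stage = "adult",
                            dtc_distance_um = 10), dt = 0.1)
    res$state$timers$CellCycle[1L] == 0
  }
  arrest_frac <- bisect_boundary(arrested, 0.01, 0.999, tol / 10)

  fate1 <- fate
  fate1$apoptosis_prob_per_h <- 1
  dies <- function(d)
    apoptosis_draw(list(dtc_distance_um = d, life_stage = "adult"),
                   fate1, dt = 1)
  protect_um <- bisect_boundary(dies, 0, 1000, tol)

  cap_um <- grow_cell(2.7, "meiotic", fate, dt = 1e6)

  mature_um <- oocyte_maturity_radius(chart, fate)

  c(glp1_bound_um = glp1_bound, glp1_absent_um = glp1_absent,
    sex_decision_um = sex_um, sperm_time_hph = sperm_t,
    g2_arrest_percent = 100 * arrest_frac,
    apoptosis_protect_um = protect_um,
    meiotic_radius_cap_um = cap_um, oocyte_mature_um = mature_um)
}

# grow an isolated oocyte-fated cell and report its radius at the step the
# maturity event is emitted
oocyte_maturity_radius <- function(chart, fate, dt = 0.01) {
  st <- sc_init(chart, 1L,
                active = list(CellCycle = "MeioticProphase",
                              SexDetermination = "OocyteFated"))
  ctx <- default_probe_ctx(1L)
  ctx$dtc_distance_um <- 260
  ctx$time_hph <- 50
  r <- 4
  for (i in seq_len(200000L)) {
    ctx$radius_um <- r
    res <- sc_step(st, chart, ctx, dt)
    st <- res$state
    if (!is.null(res$events$oocyte_mature)) return(r)
    if (!is.null(res$events$grow_oocyte))
      r <- grow_cell(r, "oocyte", fate, dt)
  }
  stop("oocyte never matured", call. = FALSE)
}

#' Sperm yield of isolated sperm-fated cells
#'
#' Steps `n0` freshly sperm-fated cells (already in the meiotic pathway)
#' through the chart with division events applied, until all descendants are
#' terminal sperm.
#'
#' @param n0 number of starting sperm-fated cells.
#' @param fate a [fate_params()].
#' @param dt step (hours).
#' @param hours simulated duration (must exceed twice the division delay).
#' @return number of sperm produced.
#' @export
spermatogenesis_count <- function(n0 = 1L, fate = fate_params(), dt = 0.05,
                                  hours = 10) {
  chart <- germline_chart(fate = fate)
  st <- sc_init(chart, n0,
                active = list(CellCycle = "MeioticProphase",
                              SexDetermination = "SpermFated"))
  rem <- rep(2L, n0)
  steps <- ceiling(hours / dt)
  for (i in seq_len(steps)) {
    ctx <- default_probe_ctx(st$n)
    ctx$dtc_distance_um <- 210
    ctx$time_hph <- 40
    ctx$sperm_divisions_remaining <- rem
    res <- sc_step(st, chart, ctx, dt)
    st <- res$state
    div <- res$events$sperm_division
    if (length(div)) {
      rem[div] <- rem[div] - 1L
      fk <- sc_fork(st, div)
      st <- fk$state
      rem <- c(rem, rem[div])
    }
  }
  sum(sc_active(st, chart, "SexDetermination") == "Sperm")
}

#' Completed cycle lengths of isolated uncompressed cells
#'
#' Steps `n_cells` proliferative cells near the DTC (volume fraction fixed at
#' 1) through the chart without forking, and measures the intervals between
#' their successive division events (M entries). Phase durations are
#' resampled on each G1/G2 entry with the configured stochasticity.
#'
#' @param n_cells number of independent cells.
#' @param cc a [cell_cycle_params()].
#' @param t_hph imposed clock (fixes the stage; 50 hph = adult).
#' @param dt step (hours).
#' @param hours simulated duration.
#' @return numeric vector of completed cycle lengths (hours).
#' @export
isolated_cycle_lengths <- function(n_cells = 1000L,
                                   cc = cell_cycle_params(),
                                   t_hph = 50, dt = 0.01, hours = 18) {
  chart <- germline_chart(cc = cc)
  mu <- cycle_phase_means(t_hph, cc)
  st <- sc_init(chart, n_cells, active = list(CellCycle = "G1"))
  dur <- list(G1 = sample_phase_duration(mu[["G1"]], cc$s, n_cells),
              S = rep(mu[["S"]], n_cells),
              G2 = sample_phase_duration(mu[["G2"]], cc$s, n_cells),
              M = rep(mu[["M"]], n_cells))
  ctx0 <- default_probe_ctx(n_cells)
  ctx0$time_hph <- t_hph
  last_div <- rep(NA_real_, n_cells)
  lengths <- list()
  t <- 0
  steps <- ceiling(hours / dt)
  for (i in seq_len(steps)) {
    ctx <- ctx0
    ctx$dur_G1 <- dur$G1; ctx$dur_S <- dur$S
    ctx$dur_G2 <- dur$G2; ctx$dur_M <- dur$M
    res <- sc_step(st, chart, ctx, dt)
    st <- res$state
    if (!is.null(res$events$resample_G1)) {
      k <- res$events$resample_G1
      dur$G1[k] <- sample_phase_duration(mu[["G1"]], cc$s, length(k))
    }
    if (!is.null(res$events$resample_G2)) {
      k <- res$events$resample_G2
      dur$G2[k] <- sample_phase_duration(mu[["G2"]], cc$s, length(k))
    }
    d <- res$events$divide
    if (length(d)) {
      done <- d[!is.na(last_div[d])]
      if (length(done))
        lengths[[length(lengths) + 1L]] <- t - last_div[done]
      last_div[d] <- t
    }
    t <- t + dt
  }
  unlist(lengths)
}
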