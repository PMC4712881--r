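#' Cell-cycle parameters
#'
#' Phase means are derived from the stage's total cycle length (3 h in larvae,
#' 8 h in adults) and a phase split. G1 and G2 durations are sampled per phase
#' entry from N(mu, (s*mu)^2) with stochasticity `s`; S and M are fixed at
#' their means. Between `ramp_start_hph` and `ramp_end_hph` (mid-L4 to
#' adulthood) the phase means ramp linearly from larval to adult values.
#' Compression below `arrest_volume_fraction` of rest volume transiently
#' freezes the G2 timer of adult cells.
#'
#' @param total_cycle_larval,total_cycle_adult total cycle lengths (hours).
#' @param split fractions of the total assigned to G1, S, G2, M (sums to 1).
#'   G1 is very short in this system.
#' @param s phase-length coefficient of variation (dimensionless).
#' @param fixed_meiotic_G1,fixed_meiotic_S fixed durations (hours) of the
#'   post-commitment G1 and meiotic S preceding meiotic prophase.
#' @param arrest_volume_fraction compression threshold (fraction of rest
#'   volume) for cell-cycle arrest in adults.
#' @param ramp_start_hph,ramp_end_hph larval-to-adult parameter ramp window.
#' @return a `cell_cycle_params` list.
#' @export
cell_cycle_params <- function(total_cycle_larval = 3,
                              total_cycle_adult = 8,
                              split = c(G1 = 0.05, S = 0.50, G2 = 0.35,
                                        M = 0.10),
                              s = 0.1,
                              fixed_meiotic_G1 = 0.5,
                              fixed_meiotic_S = 3,
                              arrest_volume_fraction = 0.70,
                              ramp_start_hph = 29.75,
                              ramp_end_hph = 34.5) {
  stopifnot(total_cycle_larval > 0, total_cycle_adult > 0,
            length(split) == 4L, abs(sum(split) - 1) < 1e-9, all(split > 0),
            s >= 0, fixed_meiotic_G1 > 0, fixed_meiotic_S > 0,
            arrest_volume_fraction > 0, arrest_volume_fraction < 1,
            ramp_start_hph < ramp_end_hph)
  names(split) <- c("G1", "S", "G2", "M")
  structure(list(total_cycle_larval = total_cycle_larval,
                 total_cycle_adult = total_cycle_adult,
                 split = split, s = s,
                 mean_larval = split * total_cycle_larval,
                 mean_adult = split * total_cycle_adult,
                 fixed_meiotic_G1 = fixed_meiotic_G1,
                 fixed_meiotic_S = fixed_meiotic_S,
                 arrest_volume_fraction = arrest_volume_fraction,
                 ramp_start_hph = ramp_start_hph,
                 ramp_end_hph = ramp_end_hph),
            class = "cell_cycle_params")
}

#' GLP-1 signalling thresholds
#'
#' @param bound_threshold_um distance from the DTC below which the GLP-1
#'   receptor becomes Bound (um).
#' @param absent_threshold_um distance at and beyond which the GLP-1 signal
#'   becomes Absent (um). Between the two the receptor keeps its state
#'   (hysteresis).
#' @return a `signaling_params` list.
#' @export
signaling_params <- function(bound_threshold_um = 35,
                             absent_threshold_um = 70) {
  stopifnot(bound_threshold_um > 0,
            bound_threshold_um < absent_threshold_um)
  structure(list(bound_threshold_um = bound_threshold_um,
                 absent_threshold_um = absent_threshold_um),
            class = "signaling_params")
}

#' Sex-determination, growth and apoptosis parameters
#'
#' @param sex_decision_distance_um distance from the DTC at which a Precursor
#'   commits to a sperm or oocyte fate (um).
#' @param sperm_time_threshold_hph commitments strictly before this clock time
#'   are sperm-fated; at or after it, oocyte-fated (hours post-hatch).
#' @param sperm_division_delay_h delay between sperm-fate commitment (or a
#'   spermatogenic division) and the next division (hours).
#' @param max_meiotic_radius_um growth cap for meiotic, non-oocyte-fated cells.
#' @param oocyte_mature_radius_um radius at which an oocyte-fated cell is
#'   flagged mature.
#' @param meiotic_growth_rate_um_per_h,oocyte_growth_rate_um_per_h steady
#'   growth rates (um/h).
#' @param apoptosis_prob_per_h per-hour death probability P of an immature
#'   oocyte-fated adult cell outside the proximal gonad, i.e. while closer
#'   than `proximal_protect_distance_um` to the DTC. Cells that reach the
#'   proximal gonad are committed to becoming mature gametes.
#' @param proximal_protect_distance_um see above (um).
#' @param sperm_radius_um radius of a terminal sperm (um); spermatids are far
#'   smaller than germ cells.
#' @return a `fate_params` list.
#' @export
fate_params <- function(sex_decision_distance_um = 200,
                        sperm_time_threshold_hph = 32.5,
                        sperm_division_delay_h = 1,
                        max_meiotic_radius_um = 4,
                        oocyte_mature_radius_um = 10,
                        meiotic_growth_rate_um_per_h = 0.05,
                        oocyte_growth_rate_um_per_h = 0.5,
                        apoptosis_prob_per_h = 0.03,
                        proximal_protect_distance_um = 250,
                        sperm_radius_um = 1.5) {
  stopifnot(sex_decision_distance_um > 0, sperm_time_threshold_hph > 0,
            sperm_division_delay_h > 0,
            max_meiotic_radius_um > 0,
            oocyte_mature_radius_um > max_meiotic_radius_um,
            meiotic_growth_rate_um_per_h > 0,
            oocyte_growth_rate_um_per_h > 0,
            apoptosis_prob_per_h >= 0, apoptosis_prob_per_h <= 1,
            proximal_protect_distance_um > 0, sperm_radius_um > 0)
  structure(as.list(environment()), class = "fate_params")
}

#' Sample a stochastic phase duration
#'
#' Durations of G1 and G2 are drawn from a normal distribution with mean `mean`
#' and standard deviation `s * mean`, clamped below at 1% of the mean so a
#' draw can never be non-positive. With `s = 0` the mean is returned exactly
#' (as used for S and M phases, which are not sampled).
#'
#' @param mean expected phase length (hours, > 0).
#' @param s stochasticity parameter (>= 0).
#' @param n number of draws.
#' @return numeric vector of durations (hours).
#' @export
sample_phase_duration <- function(mean, s = 0.1, n = 1L) {
  stopifnot(all(mean > 0), s >= 0)
  if (s == 0) return(rep_len(mean, n))
  pmax(0.01 * mean, rnorm(n, mean = mean, sd = s * mean))
}

#' Interpolated cell-cycle phase means at a given time
#'
#' Larval means before the ramp window, adult means after it, linear in
#' between.
#'
#' @param t_hph hours post-hatch.
#' @param cc a [cell_cycle_params()] object.
#' @return named numeric vector (G1, S, G2, M) of phase means (hours).
#' @export
cycle_phase_means <- function(t_hph, cc) {
  w <- (t_hph - cc$ramp_start_hph) / (cc$ramp_end_hph - cc$ramp_start_hph)
  w <- min(1, max(0, w))
  (1 - w) * cc$mean_larval + w * cc$mean_adult
}

#' Life stage at a given time
#'
#' @param t_hph hours post-hatch.
#' @param cc a [cell_cycle_params()] object; its ramp window separates the
#'   stages.
#' @return `"larval"`, `"transition"` or `"adult"`.
#' @export
life_stage_at <- function(t_hph, cc) {
  if (t_hph < cc$ramp_start_hph) "larval"
  else if (t_hph < cc$ramp_end_hph) "transition"
  else "adult"
}

#' Contact-inhibition arrest guard
#'
#' True (arrest) when an adult cell is compressed below the arrest fraction of
#' its rest volume. Applied to adult germ cells only; the arrest freezes the
#' G2 timer.
#'
#' @param ctx context list with `life_stage` and `volume_fraction`.
#' @param cc a [cell_cycle_params()] object.
#' @return logical vector.
#' @export
contact_inhibition_guard <- function(ctx, cc) {
  (ctx$life_stage == "adult") & (ctx$volume_fraction < cc$arrest_volume_fraction)
}

#' Sperm/oocyte fate decision
#'
#' Cells commit on reaching the sex-determination distance from the DTC:
#' sperm-fated if the decision occurs strictly before the time threshold,
#' oocyte-fated otherwise (a tie at exactly the threshold is an oocyte).
#' The decision is irreversible.
#'
#' @param ctx context list with `time_hph`.
#' @param fate a [fate_params()] object.
#' @return `"sperm_fated"` or `"oocyte_fated"` (vectorized over `time_hph`).
#' @export
decide_sex_fate <- function(ctx, fate) {
  ifelse(ctx$time_hph < fate$sperm_time_threshold_hph,
         "sperm_fated", "oocyte_fated")
}

#' Grow meiotic and oocyte-fated cells
#'
#' Meiotic non-oocyte cells grow steadily up to a maximum radius of
#' `max_meiotic_radius_um`; oocyte-fated cells grow up to
#' `oocyte_mature_radius_um`. Mitotic cells keep the base radius.
#'
#' @param radius current radii (um).
#' @param state one of `"mitotic"`, `"meiotic"`, `"oocyte"` (vectorized).
#' @param fate a [fate_params()] object.
#' @param dt time step (hours, > 0).
#' @return updated radii (um).
#' @export
grow_cell <- function(radius, state, fate, dt) {
  stopifnot(dt > 0)
  state <- rep_len(state, length(radius))
  mei <- state == "meiotic"
  oo <- state == "oocyte"
  radius[mei] <- pmin(fate$max_meiotic_radius_um,
                      radius[mei] + fate$meiotic_growth_rate_um_per_h * dt)
  radius[oo] <- pmin(fate$oocyte_mature_radius_um,
                     radius[oo] + fate$oocyte_growth_rate_um_per_h * dt)
  radius
}

#' Apoptosis draw for immature oocyte-fated cells
#'
#' Death occurs with probability P per hour spent outside the adult proximal
#' gonad, i.e. while an adult oocyte-fated cell is still within
#' `proximal_protect_distance_um` of the DTC. The per-hour probability is
#' converted to the step length by the geometric hazard
#' 1 - (1 - P)^dt, making the outcome invariant to step size. Cells that have
#' reached the proximal gonad (at or beyond the protect distance) never die:
#' they are committed to becoming mature gametes.
#'
#' @param ctx context list with `dtc_distance_um` and `life_stage`.
#' @param fate a [fate_params()] object.
#' @param dt step length (hours).
#' @return logical vector: death this step.
#' @export
apoptosis_draw <- function(ctx, fate, dt) {
  p_step <- 1 - (1 - fate$apoptosis_prob_per_h)^dt
  eligible <- (ctx$life_stage == "adult") &
    (ctx$dtc_distance_um < fate$proximal_protect_distance_um)
  n <- length(ctx$dtc_distance_um)
  eligible & (runif(n) < p_step)
}

#' Build the germline statechart
#'
#' Assembles the orthogonal regions governing one germ cell:
#' \describe{
#'   \item{GLP1Receptor}{Unbound -> Bound below 35 um from the DTC; Bound (or
#'     Unbound) -> Absent at and beyond 70 um. No transition fires between the
#'     two thresholds, so the receptor state is hysteretic there, and Absent
#'     is terminal (meiotic entry is irreversible).}
#'   \item{LAG1}{Active while the receptor is Bound, switches off when the
#'     signal becomes Absent.}
#'   \item{GLD}{The GLD-1/GLD-2 pathways: active exactly when LAG-1 is off;
#'     active GLD promotes meiotic entry.}
#'   \item{CellCycle}{G1 -> S -> G2 -> M; a division event is emitted on entry
#'     into M. Cells exit mitosis only when they are in G1 within an active
#'     GLD region at >= 70 um from the DTC (so cells in S or G2 at signal loss
#'     divide once more before committing), then a fixed-length G1
#'     (NonProliferative) and meiotic S precede meiotic prophase. The G2 timer
#'     of adult cells is frozen while compressed below the arrest fraction.}
#'   \item{SexDetermination}{Precursors commit at the sex-determination
#'     distance (sperm-fated strictly before the time threshold, oocyte-fated
#'     otherwise). Sperm-fated cells divide twice, after a short delay each,
#'     producing four sperm; sperm never divide again. Oocyte-fated cells grow
#'     and become mature oocytes at the maturity radius; while immature they
#'     are subject to the apoptosis draw.}
#' }
#'
#' Guards read only the frozen per-step context. Actions are emitted as named
#' events (`divide`, `sperm_division`, `meiotic_entry`, `commit_sperm`,
#' `commit_oocyte`, `oocyte_mature`, `resample_G1`, `resample_G2`,
#' `grow_meiotic`, `grow_oocyte`, `apoptosis_check`) and are interpreted by the
#' simulation loop.
#'
#' @param cc a [cell_cycle_params()] object.
#' @param sig a [signaling_params()] object.
#' @param fate a [fate_params()] object.
#' @param contact_inhibition disable to remove the G2 compression arrest
#'   (the no-mechanical-feedback scenario).
#' @return an [sc_chart()].
#' @export
germline_chart <- function(cc = cell_cycle_params(),
                           sig = signaling_params(),
                           fate = fate_params(),
                           contact_inhibition = TRUE) {
  stopifnot(inherits(cc, "cell_cycle_params"),
            inherits(sig, "signaling_params"),
            inherits(fate, "fate_params"))
  b <- sig$bound_threshold_um
  a <- sig$absent_threshold_um

  receptor <- sc_region(
    "GLP1Receptor",
    states = c("Unbound", "Bound", "Absent"),
    transitions = list(
      sc_transition("Unbound", "Bound",
                    function(ctx) ctx$dtc_distance_um < b),
      sc_transition("Unbound", "Absent",
                    function(ctx) ctx$dtc_distance_um >= a),
      sc_transition("Bound", "Absent",
                    function(ctx) ctx$dtc_distance_um >= a)
    ),
    initial = "Unbound"
  )

  lag1 <- sc_region(
    "LAG1",
    states = c("Active", "Inactive"),
    transitions = list(
      sc_transition("Inactive", "Active",
                    function(ctx) ctx$active$GLP1Receptor == "Bound"),
      sc_transition("Active", "Inactive",
                    function(ctx) ctx$active$GLP1Receptor == "Absent")
    ),
    initial = "Active"
  )

  gld <- sc_region(
    "GLD",
    states = c("Inactive", "Active"),
    transitions = list(
      sc_transition("Inactive", "Active",
                    function(ctx) ctx$active$LAG1 == "Inactive"),
      sc_transition("Active", "Inactive",
                    function(ctx) ctx$active$LAG1 == "Active")
    ),
    initial = "Inactive"
  )

  cycle <- sc_region(
    "CellCycle",
    states = c("G1", "S", "G2", "M",
               "NonProliferative", "MeioticS", "MeioticProphase"),
    transitions = list(
      # meiotic commitment takes priority over cycling on, and is only
      # permitted at >= 70 um from the DTC
      sc_transition("G1", "NonProliferative",
                    function(ctx) ctx$active$GLD == "Active" &
                      ctx$dtc_distance_um >= a,
                    actions = "meiotic_entry"),
      sc_transition("G1", "S", function(ctx) ctx$timer >= ctx$dur_G1),
      sc_transition("S", "G2", function(ctx) ctx$timer >= ctx$dur_S),
      sc_transition("G2", "M", function(ctx) ctx$timer >= ctx$dur_G2),
      sc_transition("M", "G1", function(ctx) ctx$timer >= ctx$dur_M),
      sc_transition("NonProliferative", "MeioticS",
                    function(ctx) ctx$timer >= ctx$dur_meiG1),
      sc_transition("MeioticS", "MeioticProphase",
                    function(ctx) ctx$timer >= ctx$dur_meiS)
    ),
    initial = NA,
    entry_actions = list(G1 = "resample_G1", G2 = "resample_G2",
                         M = "divide"),
    during_actions = list(NonProliferative = "grow_meiotic",
                          MeioticS = "grow_meiotic",
                          MeioticProphase = "grow_meiotic"),
    timer_hold = if (contact_inhibition)
      list(G2 = function(ctx) contact_inhibition_guard(ctx, cc))
    else list()
  )

  sexdet <- sc_region(
    "SexDetermination",
    states = c("Precursor", "SpermFated", "Sperm",
               "OocyteFated", "MatureOocyte"),
    transitions = list(
      sc_transition("Precursor", "SpermFated",
                    function(ctx)
                      ctx$dtc_distance_um >= fate$sex_decision_distance_um &
                      ctx$time_hph < fate$sperm_time_threshold_hph,
                    actions = "commit_sperm"),
      sc_transition("Precursor", "OocyteFated",
                    function(ctx)
                      ctx$dtc_distance_um >= fate$sex_decision_distance_um &
                      ctx$time_hph >= fate$sperm_time_threshold_hph,
                    actions = "commit_oocyte"),
      sc_transition("SpermFated", "Sperm",
                    function(ctx) ctx$sperm_divisions_remaining <= 0L),
      sc_transition("SpermFated", "SpermFated",
                    function(ctx) ctx$timer >= fate$sperm_division_delay_h &
                      ctx$sperm_divisions_remaining > 0L,
                    actions = "sperm_division"),
      sc_transition("OocyteFated", "MatureOocyte",
                    function(ctx)
                      ctx$radius_um >= fate$oocyte_mature_radius_um,
                    actions = "oocyte_mature")
    ),
    initial = "Precursor",
    entry_actions = list(Sperm = "become_sperm"),
    during_actions = list(OocyteFated = c("grow_oocyte", "apoptosis_check"))
  )

  sc_chart(receptor, lag1, gld, cycle, sexdet)
}
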