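# drive the germline chart for isolated cells, applying forks and growth
chart_drive <- function(chart, active, ctx_over = list(), hours = 10,
                        dt = 0.05, fate = fate_params()) {
  st <- sc_init(chart, 1L, active = active)
  rem <- 2L
  radius <- 2.7
  events <- character()
  base <- list(time_hph = 25, dtc_distance_um = 10, volume_fraction = 1,
               life_stage = "larval",
               dur_G1 = 0.15, dur_S = 1.5, dur_G2 = 1.05, dur_M = 0.3,
               dur_meiG1 = 0.5, dur_meiS = 3)
  base[names(ctx_over)] <- ctx_over
  for (i in seq_len(ceiling(hours / dt))) {
    n <- st$n
    ctx <- lapply(base, function(v) rep_len(v, n))
    ctx$time_hph <- base$time_hph
    ctx$life_stage <- base$life_stage
    ctx$radius_um <- rep_len(radius, n)
    ctx$sperm_divisions_remaining <- rem
    res <- sc_step(st, chart, ctx, dt)
    st <- res$state
    events <- c(events, rep(names(res$events),
                            lengths(res$events)))
    div <- sort(unique(c(res$events$divide, res$events$sperm_division)))
    if (!is.null(res$events$sperm_division))
      rem[res$events$sperm_division] <-
        rem[res$events$sperm_division] - 1L
    if (length(div)) {
      fk <- sc_fork(st, div)
      st <- fk$state
      rem <- c(rem, rem[div])
      radius <- c(radius, radius[div])
    }
  }
  list(state = st, events = events, chart = chart)
}

test_that("phase durations are normal with sd = s * mean, clamped positive", {
  set.seed(101)
  expect_equal(sample_phase_duration(2, s = 0), 2)
  x <- sample_phase_duration(1, s = 0.1, n = 1e5)
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(sd(x), 0.1, tolerance = 0.05)
  # draws that would be non-positive are clamped at 1% of the mean
  y <- sample_phase_duration(1, s = 5, n = 1e4)
  expect_gte(min(y), 0.01)
})

test_that("contact inhibition arrests adults below 70% rest volume only", {
  cc <- cell_cycle_params()
  expect_true(contact_inhibition_guard(
    list(life_stage = "adult", volume_fraction = 0.69), cc))
  expect_false(contact_inhibition_guard(
    list(life_stage = "adult", volume_fraction = 0.71), cc))
  expect_false(contact_inhibition_guard(
    list(life_stage = "larval", volume_fraction = 0.5), cc))
})

test_that("the sperm/oocyte decision is a strict-before time threshold", {
  fate <- fate_params()
  expect_equal(decide_sex_fate(list(time_hph = 32.4), fate), "sperm_fated")
  expect_equal(decide_sex_fate(list(time_hph = 32.6), fate), "oocyte_fated")
  expect_equal(decide_sex_fate(list(time_hph = 32.5), fate), "oocyte_fated")
})

test_that("growth saturates at the meiotic and oocyte caps", {
  fate <- fate_params()
  expect_equal(grow_cell(4, "meiotic", fate, 100), 4)
  expect_equal(grow_cell(2.7, "meiotic", fate, 1),
               2.7 + fate$meiotic_growth_rate_um_per_h)
  expect_equal(grow_cell(9.99, "oocyte", fate, 1), 10)
  expect_equal(grow_cell(5, "mitotic", fate, 50), 5)
})

test_that("apoptosis hazard converts per-hour probability by step length", {
  set.seed(7)
  fate0 <- fate_params(apoptosis_prob_per_h = 0)
  expect_false(any(apoptosis_draw(
    list(dtc_distance_um = rep(220, 100), life_stage = "adult"),
    fate0, dt = 1)))
  fate1 <- fate_params(apoptosis_prob_per_h = 1)
  expect_true(apoptosis_draw(
    list(dtc_distance_um = 220, life_stage = "adult"), fate1, dt = 1))
  # committed once inside the proximal gonad, and larvae are never eligible
  expect_false(apoptosis_draw(
    list(dtc_distance_um = 300, life_stage = "adult"), fate1, dt = 1))
  expect_false(apoptosis_draw(
    list(dtc_distance_um = 220, life_stage = "larval"), fate1, dt = 1))
  # geometric hazard: fraction over half an hour at P = 0.1
  fateP <- fate_params(apoptosis_prob_per_h = 0.1)
  hit <- apoptosis_draw(list(dtc_distance_um = rep(220, 1e5),
                             life_stage = "adult"), fateP, dt = 0.5)
  expect_equal(mean(hit), 1 - 0.9^0.5, tolerance = 0.02)
})

test_that("a G1 cell in an active GLD region commits that step", {
  chart <- germline_chart()
  out <- chart_drive(chart, list(CellCycle = "G1", GLP1Receptor = "Absent",
                                 LAG1 = "Inactive", GLD = "Active"),
                     ctx_over = list(dtc_distance_um = 80),
                     hours = 0.05, dt = 0.05)
  expect_equal(sc_active(out$state, chart, "CellCycle"), "NonProliferative")
  expect_true("meiotic_entry" %in% out$events)
})

test_that("cells past G1 at signal loss divide once and only once", {
  chart <- germline_chart()
  out <- chart_drive(chart, list(CellCycle = "S", GLP1Receptor = "Absent",
                                 LAG1 = "Inactive", GLD = "Active"),
                     ctx_over = list(dtc_distance_um = 80), hours = 12)
  expect_equal(sum(out$events == "divide"), 1L)
  expect_equal(out$state$n, 2L)
  expect_equal(sc_active(out$state, chart, "CellCycle"),
               rep("MeioticProphase", 2))
})

test_that("the receptor is hysteretic between the two thresholds", {
  chart <- germline_chart()
  st <- sc_init(chart, 1L, active = list(CellCycle = "G1",
                                         GLP1Receptor = "Bound"))
  ctx <- list(time_hph = 25, dtc_distance_um = 50, volume_fraction = 1,
              radius_um = 2.7, life_stage = "larval",
              dur_G1 = Inf, dur_S = Inf, dur_G2 = Inf, dur_M = Inf,
              dur_meiG1 = Inf, dur_meiS = Inf,
              sperm_divisions_remaining = 2L)
  for (k in 1:50) st <- sc_step(st, chart, ctx, 0.1)$state
  expect_equal(sc_active(st, chart, "GLP1Receptor"), "Bound")
})

test_that("meiotic entry is blocked distal of the signal-loss distance", {
  chart <- germline_chart()
  # even with GLD active (history), a cell pushed back under 70 um stays out
  out <- chart_drive(chart, list(CellCycle = "G1", GLP1Receptor = "Absent",
                                 LAG1 = "Inactive", GLD = "Active"),
                     ctx_over = list(dtc_distance_um = 50),
                     hours = 0.05, dt = 0.05)
  expect_false(sc_active(out$state, chart, "CellCycle") ==
                 "NonProliferative")
})

test_that("sperm-fated cells make exactly four terminal sperm", {
  expect_equal(spermatogenesis_count(1), 4L)
  expect_equal(spermatogenesis_count(10), 40L)
  # long after completion no further divisions occur
  expect_equal(spermatogenesis_count(1, hours = 100), 4L)
})

test_that("every printed threshold is recovered by bisection", {
  th <- germline_thresholds()
  expect_equal(th[["glp1_bound_um"]], 35, tolerance = 0.01)
  expect_equal(th[["glp1_absent_um"]], 70, tolerance = 0.01)
  expect_equal(th[["sex_decision_um"]], 200, tolerance = 0.01)
  expect_equal(th[["sperm_time_hph"]], 32.5, tolerance = 0.01)
  expect_equal(th[["g2_arrest_percent"]], 70, tolerance = 0.1)
  expect_equal(th[["apoptosis_protect_um"]], 250, tolerance = 0.01)
  expect_equal(th[["meiotic_radius_cap_um"]], 4)
  expect_equal(th[["oocyte_mature_um"]], 10)
})

test_that("realized cycle lengths track the stage totals", {
  set.seed(55)
  adult <- isolated_cycle_lengths(n_cells = 150, t_hph = 50, hours = 18)
  expect_gt(length(adult), 100)
  expect_equal(mean(adult), 8, tolerance = 0.02)
  larval <- isolated_cycle_lengths(n_cells = 150, t_hph = 20, hours = 7.5)
  expect_equal(mean(larval), 3, tolerance = 0.02)
})
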