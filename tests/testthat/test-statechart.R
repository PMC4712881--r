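test_that("a true guard forces the transition and resets the timer", {
  chart <- sc_chart(two_state_region())
  st <- sc_init(chart, 1L)
  st$timers$R <- 5
  res <- sc_step(st, chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R"), "B")
  expect_equal(res$state$timers$R, 0)
})

test_that("a quiescent step only advances the timer", {
  chart <- sc_chart(two_state_region(guard = function(ctx) FALSE))
  st <- sc_init(chart, 1L)
  res <- sc_step(st, chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R"), "A")
  expect_equal(res$state$timers$R, 0.1)
})

test_that("orthogonal regions fire independently in the same step", {
  chart <- sc_chart(two_state_region("R1"), two_state_region("R2"))
  st <- sc_init(chart, 3L)
  res <- sc_step(st, chart, probe_ctx(3L), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R1"), rep("B", 3))
  expect_equal(sc_active(res$state, chart, "R2"), rep("B", 3))
})

test_that("cross-region guards read the frozen pre-step snapshot", {
  # R2 copies R1's state; within one step it must see R1's old state
  r1 <- two_state_region("R1")
  r2 <- sc_region("R2", states = c("A", "B"),
                  transitions = list(
                    sc_transition("A", "B",
                                  function(ctx) ctx$active$R1 == "B")),
                  initial = "A")
  chart <- sc_chart(r1, r2)
  st <- sc_init(chart, 1L)
  res <- sc_step(st, chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R1"), "B")
  expect_equal(sc_active(res$state, chart, "R2"), "A")  # lags one step
  res2 <- sc_step(res$state, chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res2$state, chart, "R2"), "B")
})

test_that("document order resolves simultaneously true guards", {
  r <- sc_region("R", states = c("A", "B", "C"),
                 transitions = list(
                   sc_transition("A", "B", function(ctx) TRUE),
                   sc_transition("A", "C", function(ctx) TRUE)),
                 initial = "A")
  chart <- sc_chart(r)
  res <- sc_step(sc_init(chart, 1L), chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R"), "B")
})

test_that("chained transitions run to quiescence within one step", {
  r <- sc_region("R", states = c("A", "B", "C"),
                 transitions = list(
                   sc_transition("A", "B", function(ctx) TRUE),
                   sc_transition("B", "C", function(ctx) TRUE)),
                 initial = "A")
  chart <- sc_chart(r)
  res <- sc_step(sc_init(chart, 1L), chart, probe_ctx(), dt = 0.1)
  expect_equal(sc_active(res$state, chart, "R"), "C")
})

test_that("a guard cycle hits the chain limit and errors", {
  r <- sc_region("R", states = c("A", "B"),
                 transitions = list(
                   sc_transition("A", "B", function(ctx) TRUE),
                   sc_transition("B", "A", function(ctx) TRUE)),
                 initial = "A")
  chart <- sc_chart(r)
  expect_error(sc_step(sc_init(chart, 1L), chart, probe_ctx(), dt = 0.1),
               "chain")
})

test_that("malformed charts are rejected", {
  expect_error(sc_region("R", states = c("A", "B"),
                         transitions = list(
                           sc_transition("A", "Z", function(ctx) TRUE)),
                         initial = "A"),
               "unknown state")
  expect_error(sc_init(sc_chart(two_state_region()), 1L,
                       active = list(R = "Z")), "unknown state")
  expect_error(sc_chart(two_state_region("R"), two_state_region("R")),
               "duplicate")
})

test_that("entry and transition actions are emitted for firing cells only", {
  r <- sc_region("R", states = c("A", "B"),
                 transitions = list(
                   sc_transition("A", "B",
                                 function(ctx) ctx$dtc_distance_um > 1,
                                 actions = "went")),
                 initial = "A", entry_actions = list(B = "arrived"),
                 during_actions = list(B = "staying"))
  chart <- sc_chart(r)
  st <- sc_init(chart, 3L)
  ctx <- probe_ctx(3L, dtc_distance_um = c(0, 2, 5))
  res <- sc_step(st, chart, ctx, dt = 0.1)
  expect_equal(res$events$went, c(2L, 3L))
  expect_equal(res$events$arrived, c(2L, 3L))
  expect_equal(res$events$staying, c(2L, 3L))
})

test_that("timer_hold freezes the timer while its guard is true", {
  r <- sc_region("R", states = c("A", "B"),
                 transitions = list(
                   sc_transition("A", "B", function(ctx) FALSE)),
                 initial = "A",
                 timer_hold = list(A = function(ctx) ctx$volume_fraction < 0.5))
  chart <- sc_chart(r)
  st <- sc_init(chart, 2L)
  ctx <- probe_ctx(2L, volume_fraction = c(0.4, 0.9))
  res <- sc_step(st, chart, ctx, dt = 0.2)
  expect_equal(res$state$timers$R, c(0, 0.2))
})

test_that("fork copies the active configuration and zeroes timers", {
  chart <- sc_chart(two_state_region(guard = function(ctx) FALSE),
                    two_state_region("S", guard = function(ctx) FALSE))
  st <- sc_init(chart, 2L, active = list(R = c("A", "B"), S = "B"))
  st$timers$R <- c(1, 2); st$timers$S <- c(3, 4)
  fk <- sc_fork(st, 2L)
  expect_equal(fk$state$n, 3L)
  expect_equal(fk$daughters, 3L)
  expect_equal(sc_active(fk$state, chart, "R"), c("A", "B", "B"))
  expect_equal(sc_active(fk$state, chart, "S"), c("B", "B", "B"))
  expect_equal(fk$state$timers$R, c(1, 0, 0))
  expect_equal(fk$state$timers$S, c(3, 0, 0))
})

test_that("stepping never mutates the caller's context (guard purity)", {
  chart <- sc_chart(two_state_region())
  ctx <- probe_ctx(2L, dtc_distance_um = c(1, 2))
  ctx_copy <- ctx
  invisible(sc_step(sc_init(chart, 2L), chart, ctx, dt = 0.1))
  expect_identical(ctx, ctx_copy)
})

test_that("exactly one state per region stays active over random charts", {
  set.seed(71)
  for (rep in 1:20) {
    ns <- sample(2:5, 1)
    states <- paste0("S", seq_len(ns))
    trs <- lapply(seq_len(sample(1:6, 1)), function(i) {
      ft <- sort(sample(states, 2))  # acyclic by construction
      thr <- runif(1, 0, 100)
      sc_transition(ft[1], ft[2],
                    local({ th <- thr
                            function(ctx) ctx$dtc_distance_um > th }))
    })
    chart <- sc_chart(sc_region("R", states, trs, initial = states[1]))
    st <- sc_init(chart, 10L)
    for (k in 1:30) {
      ctx <- probe_ctx(10L, dtc_distance_um = runif(10, 0, 120))
      st <- sc_step(st, chart, ctx, dt = 0.05)$state
      expect_true(all(st$active$R %in% seq_along(states)))
      expect_length(st$active$R, 10L)
      expect_true(all(st$timers$R >= 0))
    }
  }
})
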