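#' @useDynLib germsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.csv read.csv
NULL

#' Define a statechart transition
#'
#' A guarded transition between two states of the same region. Guards are pure
#' predicates over the cell context: they receive the frozen context list and
#' must return a logical vector (length 1 or one value per cell) without side
#' effects. When several guards out of a state are true simultaneously, the
#' first transition in definition order wins.
#'
#' @param source,target state names within the owning region.
#' @param guard function(ctx) -> logical. The context carries at least
#'   `time_hph`, `dtc_distance_um`, `volume_fraction`, `radius_um`,
#'   `life_stage`, plus `timer` (elapsed hours in the active state of the
#'   region being evaluated) and `active` (named list of the frozen active
#'   state names of every region, as of the start of the step).
#' @param actions character vector of action identifiers emitted when the
#'   transition fires (before the target state's entry actions).
#' @return an `sc_transition` object.
#' @export
sc_transition <- function(source, target, guard, actions = character()) {
  stopifnot(is.character(source), length(source) == 1L,
            is.character(target), length(target) == 1L,
            is.function(guard), is.character(actions))
  structure(list(source = source, target = target, guard = guard,
                 actions = actions),
            class = "sc_transition")
}

#' Define an orthogonal statechart region
#'
#' A region holds a set of mutually exclusive states; exactly one is active per
#' cell at all times. Regions of a chart update independently within a step,
#' each reading the same frozen context snapshot, so the update order across
#' regions cannot matter.
#'
#' @param name region identifier.
#' @param states character vector of state names (unique within the region).
#' @param transitions list of [sc_transition()] objects; document order defines
#'   priority.
#' @param initial initial state name, or `NA` when instances are initialized
#'   externally (e.g. a randomly chosen cell-cycle phase).
#' @param entry_actions named list: state name -> character vector of action
#'   identifiers emitted on entry into that state.
#' @param during_actions named list: state name -> character vector of action
#'   identifiers emitted every step the state is active.
#' @param timer_hold named list: state name -> guard function; while the guard
#'   is true the state's timer is frozen (used for compression arrest of G2).
#' @return an `sc_region` object.
#' @export
sc_region <- function(name, states, transitions = list(), initial = NA,
                      entry_actions = list(), during_actions = list(),
                      timer_hold = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(states), !anyDuplicated(states))
  for (tr in transitions) {
    if (!inherits(tr, "sc_transition"))
      stop("transitions must be sc_transition objects", call. = FALSE)
    if (!(tr$source %in% states) || !(tr$target %in% states))
      stop(sprintf("region '%s': transition %s -> %s references unknown state",
                   name, tr$source, tr$target), call. = FALSE)
  }
  bad <- setdiff(c(names(entry_actions), names(during_actions),
                   names(timer_hold)), states)
  if (length(bad))
    stop(sprintf("region '%s': actions reference unknown states: %s",
                 name, paste(bad, collapse = ", ")), call. = FALSE)
  if (!is.na(initial) && !(initial %in% states))
    stop(sprintf("region '%s': initial state '%s' not in states", name,
                 initial), call. = FALSE)
  structure(list(name = name, states = states, transitions = transitions,
                 initial = initial, entry_actions = entry_actions,
                 during_actions = during_actions, timer_hold = timer_hold),
            class = "sc_region")
}

#' Assemble a statechart from orthogonal regions
#'
#' @param ... [sc_region()] objects.
#' @return an `sc_chart` object (named list of regions).
#' @export
sc_chart <- function(...) {
  regions <- list(...)
  if (length(regions) == 1L && is.list(regions[[1L]]) &&
      !inherits(regions[[1L]], "sc_region"))
    regions <- regions[[1L]]
  for (r in regions)
    if (!inherits(r, "sc_region"))
      stop("sc_chart() takes sc_region objects", call. = FALSE)
  nm <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate region names", call. = FALSE)
  names(regions) <- nm
  structure(regions, class = "sc_chart")
}

#' @export
print.sc_chart <- function(x, ...) {
  cat(sc_dump(x), sep = "\n")
  invisible(x)
}

#' Human-readable chart dump
#'
#' One line per region listing its states and transitions, for documentation
#' and diffing of chart variants.
#'
#' @param chart an `sc_chart`.
#' @return character vector of lines.
#' @export
sc_dump <- function(chart) {
  vapply(chart, function(r) {
    trs <- vapply(r$transitions, function(tr)
      sprintf("%s->%s", tr$source, tr$target), "")
    sprintf("%s [init %s]: {%s} %s", r$name,
            ifelse(is.na(r$initial), "-", r$initial),
            paste(r$states, collapse = ","),
            paste(trs, collapse = " "))
  }, "")
}

#' Initialize statechart instances
#'
#' Creates the active-state configuration and zeroed timers for `n` cells.
#'
#' @param chart an `sc_chart`.
#' @param n number of instances.
#' @param active optional named list of per-region overrides (a single state
#'   name or one per cell); required for regions whose `initial` is `NA`.
#' @return an `sc_state`: list with `n`, `active` (region -> integer state
#'   codes) and `timers` (region -> numeric hours).
#' @export
sc_init <- function(chart, n, active = list()) {
  act <- list(); tim <- list()
  for (r in chart) {
    if (!is.null(active[[r$name]])) {
      a <- active[[r$name]]
      code <- match(a, r$states)
      if (anyNA(code))
        stop(sprintf("unknown state for region '%s'", r$name), call. = FALSE)
      act[[r$name]] <- rep_len(code, n)
    } else if (!is.na(r$initial)) {
      act[[r$name]] <- rep.int(match(r$initial, r$states), n)
    } else {
      stop(sprintf("region '%s' has no initial state and no override",
                   r$name), call. = FALSE)
    }
    tim[[r$name]] <- numeric(n)
  }
  structure(list(n = n, active = act, timers = tim), class = "sc_state")
}

#' Active state names of one region
#'
#' @param state an `sc_state`.
#' @param chart the owning `sc_chart`.
#' @param region region name.
#' @return character vector, one state name per cell.
#' @export
sc_active <- function(state, chart, region) {
  r <- chart[[region]]
  if (is.null(r)) stop(sprintf("unknown region '%s'", region), call. = FALSE)
  r$states[state$active[[region]]]
}

#' Advance statechart instances by one time step
#'
#' For every region independently: while any transition out of the active state
#' has a true guard, the first such transition (definition order) fires
#' immediately, its actions and the target's entry actions are emitted, and the
#' region timer resets to zero. Chained transitions fire within the same step
#' up to `max_chain` hops; exceeding the limit signals a guard cycle. Timers of
#' states that did not change advance by `dt` (unless a `timer_hold` guard is
#' true). Guards read a frozen snapshot of the context taken at the start of
#' the step, including all regions' pre-step active states, so orthogonal
#' regions cannot observe each other's intra-step changes.
#'
#' @param state an `sc_state`.
#' @param chart an `sc_chart`.
#' @param ctx context list; vector fields must have length 1 or `state$n`.
#' @param dt step length in hours (> 0).
#' @param max_chain chained-transition limit per region per step.
#' @return list with `state` (updated) and `events` (named list: action
#'   identifier -> integer vector of cell indices, in emission order).
#' @export
sc_step <- function(state, chart, ctx, dt, max_chain = 8L) {
  stopifnot(inherits(state, "sc_state"), inherits(chart, "sc_chart"), dt > 0)
  n <- state$n
  if (!setequal(names(state$active), names(chart)))
    stop("instance regions do not match chart regions", call. = FALSE)
  frozen_active <- lapply(names(chart), function(rn)
    chart[[rn]]$states[state$active[[rn]]])
  names(frozen_active) <- names(chart)
  ctx$active <- frozen_active

  events <- list()
  emit <- function(acts, idx) {
    for (a in acts) events[[a]] <<- c(events[[a]], idx)
  }

  for (r in chart) {
    act <- state$active[[r$name]]
    tim <- state$timers[[r$name]]
    changed <- logical(n)
    if (length(r$transitions)) {
      src_code <- vapply(r$transitions, function(tr)
        match(tr$source, r$states), 0L)
      tgt_code <- vapply(r$transitions, function(tr)
        match(tr$target, r$states), 0L)
      chain <- 0L
      repeat {
        fired_now <- logical(n)
        any_fired <- FALSE
        ctx$timer <- tim
        for (k in seq_along(r$transitions)) {
          cand <- which(act == src_code[k] & !fired_now)
          if (!length(cand)) next
          g <- r$transitions[[k]]$guard(ctx)
          if (length(g) == 1L) g <- rep.int(g, n)
          hit <- cand[which(g[cand])]
          if (!length(hit)) next
          act[hit] <- tgt_code[k]
          tim[hit] <- 0
          fired_now[hit] <- TRUE
          changed[hit] <- TRUE
          any_fired <- TRUE
          emit(r$transitions[[k]]$actions, hit)
          ea <- r$entry_actions[[r$transitions[[k]]$target]]
          if (!is.null(ea)) emit(ea, hit)
          ctx$timer <- tim
        }
        if (!any_fired) break
        chain <- chain + 1L
        if (chain >= max_chain)
          stop(sprintf(
            "region '%s': chained-transition limit (%d) exceeded; guard cycle?",
            r$name, max_chain), call. = FALSE)
      }
    }
    # timers: advance unchanged states, respecting holds
    held <- logical(n)
    if (length(r$timer_hold)) {
      ctx$timer <- tim
      for (sn in names(r$timer_hold)) {
        idx <- which(act == match(sn, r$states))
        if (!length(idx)) next
        h <- r$timer_hold[[sn]](ctx)
        if (length(h) == 1L) h <- rep.int(h, n)
        held[idx[h[idx]]] <- TRUE
      }
    }
    adv <- !changed & !held
    tim[adv] <- tim[adv] + dt
    # during actions on settled active states
    for (sn in names(r$during_actions)) {
      idx <- which(act == match(sn, r$states))
      if (length(idx)) emit(r$during_actions[[sn]], idx)
    }
    state$active[[r$name]] <- act
    state$timers[[r$name]] <- tim
  }
  list(state = state, events = events)
}

#' Fork statechart instances on division
#'
#' For each parent index a daughter row is appended that copies the parent's
#' active configuration across all regions; the timers of both the parent row
#' (which becomes the first daughter) and the new row are reset to zero.
#' Per-phase sampled durations live outside the engine and must be resampled
#' by the caller for both daughters.
#'
#' @param state an `sc_state`.
#' @param parents integer vector of parent indices.
#' @return list with `state` (n grown by `length(parents)`) and `daughters`
#'   (integer indices of the appended rows, aligned with `parents`).
#' @export
sc_fork <- function(state, parents) {
  stopifnot(inherits(state, "sc_state"))
  if (!length(parents)) return(list(state = state, daughters = integer()))
  if (any(parents < 1L | parents > state$n))
    stop("parent index out of range", call. = FALSE)
  m <- length(parents)
  new_idx <- state$n + seq_len(m)
  for (rn in names(state$active)) {
    state$active[[rn]] <- c(state$active[[rn]], state$active[[rn]][parents])
    state$timers[[rn]][parents] <- 0
    state$timers[[rn]] <- c(state$timers[[rn]], numeric(m))
  }
  state$n <- state$n + m
  list(state = state, daughters = new_idx)
}

#' Drop statechart instances (deaths, ovulation)
#'
#' @param state an `sc_state`.
#' @param drop integer indices to remove.
#' @return the shrunken `sc_state`.
#' @export
sc_remove <- function(state, drop) {
  if (!length(drop)) return(state)
  keep <- setdiff(seq_len(state$n), drop)
  for (rn in names(state$active)) {
    state$active[[rn]] <- state$active[[rn]][keep]
    state$timers[[rn]] <- state$timers[[rn]][keep]
  }
  state$n <- length(keep)
  state
}
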