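# shared simulation runs, computed once per test session

.run_cache <- new.env(parent = emptyenv())

shared_run <- function(name) {
  if (!is.null(.run_cache[[name]])) return(.run_cache[[name]])
  sim <- switch(name,
    default70 = {
      s <- initialize_simulation(preset("default", seed = 1))
      label_cells_at(s, "all")  # clonal labels ride along for free
      simulate_until(s, 70)
      s
    },
    no_stretch47 = {
      s <- initialize_simulation(preset("no_stretch_pausing", seed = 1))
      simulate_until(s, 47)
      s
    },
    stop(sprintf("unknown shared run '%s'", name))
  )
  .run_cache[[name]] <- sim
  sim
}

snapshot_at <- function(sim, t) {
  tt <- vapply(sim$snapshots, function(s) s$t_hph[1L], 0)
  sim$snapshots[[which.min(abs(tt - t))]]
}

no_feedback_run <- function(p) {
  key <- sprintf("nofb_%g", p)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  s <- initialize_simulation(preset("no_feedback_fixed_death", seed = 1,
                                    death_prob = p))
  simulate_until(s, 56)
  .run_cache[[key]] <- s
  s
}

# mean arclength velocity (um/h) of cells within the mitotic region,
# averaged over consecutive snapshot pairs in a time window
zone_drift <- function(sim, lo, hi, zone_um = 70) {
  tt <- vapply(sim$snapshots, function(s) s$t_hph[1L], 0)
  idx <- which(tt >= lo & tt <= hi)
  step <- function(i1, i2) {
    a <- sim$snapshots[[i1]]; b <- sim$snapshots[[i2]]
    m <- merge(a[a$dtc_dist < zone_um, c("id", "s")], b[, c("id", "s")],
               by = "id")
    mean(m$s.y - m$s.x) / (tt[i2] - tt[i1])
  }
  mean(mapply(step, idx[-length(idx)], idx[-1]))
}
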