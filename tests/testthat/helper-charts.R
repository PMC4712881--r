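# tiny chart fixtures for the engine tests

two_state_region <- function(name = "R", guard = function(ctx) TRUE) {
  sc_region(name, states = c("A", "B"),
            transitions = list(sc_transition("A", "B", guard)),
            initial = "A")
}

# a probe context accepted by arbitrary guards
probe_ctx <- function(n = 1L, ...) {
  ctx <- list(time_hph = 0, dtc_distance_um = 0, volume_fraction = 1,
              radius_um = 1, life_stage = "larval")
  ctx[names(list(...))] <- list(...)
  ctx
}
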