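# shared fixtures: one thermal solve per protocol, reused across files
fix_sp <- skin_params()
fix_hot1 <- protocol_single("hot", 1)
fix_cold1 <- protocol_single("cold", 1)
fix_field_hot <- solve_skin_temperature(fix_hot1, fix_sp)
fix_field_cold <- solve_skin_temperature(fix_cold1, fix_sp)

# minimal hand-built session for estimator unit tests
fake_session <- function(spike_times, protocol, baseline_epoch = c(-2, 0),
                         onset = NULL) {
  structure(
    list(
      neuron_id = "fake", neuron_class = "MHC",
      protocol_name = protocol$name, protocol = protocol,
      params = NULL, baseline_epoch = baseline_epoch,
      onset = if (is.null(onset)) protocol$stimulus_onsets[1] else onset,
      spike_times = sort(spike_times), seed = NA_integer_,
      mechanical = mechanical_flags("MHC")
    ),
    class = "wdr_session"
  )
}
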