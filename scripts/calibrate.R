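#!/usr/bin/env Rscript
# Re-derive the shipped calibrations and print them next to their targets.
# The diffusivity is a single-scalar fit to the hot threshold-crossing
# latency; the neuron-model summaries are Monte-Carlo estimates under the
# shipped defaults. Usage: Rscript scripts/calibrate.R

suppressPackageStartupMessages(library(wdrtherm))

## skin diffusivity: hot crossing of 43 degC at 150 um in 470 ms
alpha <- calibrate_diffusivity(target_latency = 0.470, threshold = 43,
                               depth = 150e-6)
cat(sprintf("calibrated diffusivity: %.6e m^2/s (shipped %.6e)\n",
            alpha, skin_params()$diffusivity))

sp <- skin_params(diffusivity = alpha)
hot <- solve_skin_temperature(protocol_single("hot", 1), sp)
cold <- solve_skin_temperature(protocol_single("cold", 1), sp)
cat(sprintf("hot crossing  43 degC @150um: %6.1f ms (target 470)\n",
            1000 * threshold_crossing_latency(hot, 150e-6, 43, "heating")))
cat(sprintf("cold crossing 18 degC @150um: %6.1f ms (cross-check vs 270)\n",
            1000 * threshold_crossing_latency(cold, 150e-6, 18, "cooling")))

## neuron-model operating point under the shipped defaults
for (m in c("hot", "cold")) {
  p <- protocol_single(m, 1)
  lt <- latency_trials(p, n_trials = 200, seed = 11)
  cat(sprintf("%4s single 1000 ms: mean first-spike latency %5.1f ms, ",
              m, 1000 * lt$mean_latency))
  f <- solve_skin_temperature(p, sp)
  er <- mean(vapply(1:100, function(i) {
    evoked_rate(simulate_recording(p, neuron_params("MHC"), sp, seed = i,
                                   field = f))$evoked_rate
  }, numeric(1)))
  cat(sprintf("mean 2-s evoked rate %4.1f Hz\n", er))
}

## wind-up profile of the continuous 1-Hz train
for (m in c("hot", "cold")) {
  p <- protocol_iterative(protocol_single(m, 1), n = 30, rate = 1)
  f <- solve_skin_temperature(p, sp)
  s <- simulate_recording(p, neuron_params("MHC"), sp, seed = 42, field = f)
  pr <- iterative_profile(s, fit_from = if (m == "hot") "peak" else "first")
  g <- glance(pr)
  cat(sprintf(
    "%4s 30x1Hz: stim1 %4.1f Hz, peak %4.1f Hz, end %4.1f Hz, windup %.2f, tau %s s\n",
    m, pr$rates$rate[1], max(pr$rates$rate[1:3]),
    mean(utils::tail(pr$rates$rate, 3)), pr$windup_index,
    if (g$fit_valid) sprintf("%.1f", g$fit_tau) else "n/a"
  ))
}
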