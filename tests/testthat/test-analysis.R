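test_that("first-spike latency matches a brute-force scan and flags no-spike cases", {
  p <- protocol_single("hot", 1)
  withr::with_seed(21, {
    for (i in 1:50) {
      spikes <- sort(runif(rpois(1, 20), -2, 3))
      onset <- runif(1, -0.5, 1.5)
      res <- first_spike_latency(fake_session(spikes, p), onset = onset,
                                 end = Inf)
      after <- spikes[spikes > onset]
      if (length(after) == 0) {
        expect_false(res$defined)
      } else {
        expect_equal(res$latency, min(after) - onset)
      }
    }
  })
  # spikes only before onset
  s <- fake_session(c(-1.5, -0.2), p)
  expect_false(first_spike_latency(s)$defined)
  # a spike exactly at onset is not evoked
  s2 <- fake_session(c(0, 0.49), p)
  expect_equal(first_spike_latency(s2)$latency, 0.49)
})

test_that("evoked rate subtracts the baseline measured before stimulation", {
  p <- protocol_single("hot", 1)
  # 34 spikes in the 2-s window, silent baseline
  s <- fake_session(seq(0.05, 1.95, length.out = 34), p)
  er <- evoked_rate(s)
  expect_equal(er$raw_rate, 17)
  expect_equal(er$baseline_rate, 0)
  expect_equal(er$evoked_rate, 17) # zero baseline: evoked == raw exactly

  # 2 Hz spontaneous activity, 24 spikes post-stimulus
  s2 <- fake_session(c(seq(-1.9, -0.1, length.out = 4),
                       seq(0.05, 1.95, length.out = 24)), p)
  er2 <- evoked_rate(s2)
  expect_equal(er2$evoked_rate, 12 - 2)

  # empty window
  s3 <- fake_session(numeric(0), p)
  expect_equal(evoked_rate(s3)$raw_rate, 0)
  expect_error(evoked_rate(s, window_len = 0), "positive")
})

test_that("ramp threshold reads the probe temperature at the first spike", {
  ph <- protocol_slow_ramp("hot")
  th <- ramp_threshold(fake_session(4.47, ph))
  expect_equal(th$threshold_temp, 30 + 3 * 4.47) # 43.41 degC
  expect_equal(th$modality, "hot")

  pc <- protocol_slow_ramp("cold")
  tc <- ramp_threshold(fake_session(2.55, pc))
  expect_equal(tc$threshold_temp, 30 - 4 * 2.55) # 19.8 degC

  # first spike at the very start of the ramp reads the baseline
  expect_equal(ramp_threshold(fake_session(1e-6, ph))$threshold_temp, 30,
               tolerance = 1e-5)
  # no evoked spike: undefined result, not an error
  expect_false(ramp_threshold(fake_session(numeric(0), ph))$defined)
})

test_that("heating thresholds from simulated ramps sit above the depth threshold", {
  # thermal lag biases the surface read-back upward under heating;
  # spontaneous activity is disabled so every first spike is evoked
  np <- neuron_params("MHC", baseline_rate = 0)
  p <- protocol_slow_ramp("hot")
  f <- solve_skin_temperature(p, fix_sp)
  ths <- vapply(1:15, function(seed) {
    s <- simulate_recording(p, np, fix_sp, seed = seed, field = f)
    ramp_threshold(s)$threshold_temp
  }, numeric(1))
  ths <- ths[!is.na(ths)]
  expect_gt(length(ths), 0)
  expect_true(all(ths >= np$heat_threshold))
})

test_that("exponential decay fitting recovers exact and noisy parameters", {
  tt <- seq(0, 29, by = 1)
  y <- 3.7 + 19.4 * exp(-tt / 8.12)
  fit <- fit_exp_decay(tt, y)
  expect_equal(fit$A, 19.4, tolerance = 1e-4)
  expect_equal(fit$tau, 8.12, tolerance = 1e-4)
  expect_equal(fit$c, 3.7, tolerance = 1e-4)

  withr::with_seed(31, {
    yn <- y + rnorm(length(y), 0, 0.5)
    fn <- fit_exp_decay(tt, yn)
    expect_equal(fn$tau, 8.12, tolerance = 0.1 * 8.12)
    expect_equal(fn$A, 19.4, tolerance = 0.1 * 19.4)
  })

  expect_equal(glance(fit)$tau, fit$tau)
  expect_equal(tidy(fit)$estimate, c(fit$A, fit$tau, fit$c))
})

test_that("iterative profile computes per-stimulus rates and the wind-up index", {
  # 0.2 Hz train, 5-s windows, 0.1 Hz baseline: counts 48/80/116 give
  # baseline-subtracted rates 9.5 / 15.9 / 23.1 Hz
  base <- protocol_single("hot", 5, tail_s = 0)
  p <- protocol_iterative(base, n = 4, rate = 0.2, tail_s = 1)
  spikes <- c(
    -5, # one baseline spike in 10 s
    seq(0.01, 4.99, length.out = 48),
    seq(5.01, 9.99, length.out = 80),
    seq(10.01, 14.99, length.out = 116),
    seq(15.01, 19.99, length.out = 40)
  )
  s <- fake_session(spikes, p, baseline_epoch = c(-10, 0))
  pr <- iterative_profile(s)
  expect_equal(pr$rates$rate[1:3], c(9.5, 15.9, 23.1))
  expect_equal(pr$windup_index, 23.1 / 9.5, tolerance = 1e-12)
  expect_equal(pr$peak_stimulus, 3)

  # constant series: no wind-up, near-zero amplitude, asymptote at the rate
  pc <- protocol_iterative(protocol_single("hot", 1), n = 10, rate = 1)
  const <- fake_session(
    c(unlist(lapply(0:9, function(k) seq(k + 0.05, k + 0.95, length.out = 12)))),
    pc
  )
  prc <- iterative_profile(const, fit_from = "first")
  expect_equal(prc$windup_index, 1)
  expect_true(all(prc$rates$rate == 12))
  if (prc$fit_valid) expect_lt(abs(prc$fit$A), 0.1)

  expect_error(iterative_profile(fake_session(1, protocol_single("hot", 1))),
               "onsets")
})

test_that("response curve counts are baseline-corrected and batteries checked", {
  batt <- protocol_response_curve("hot")
  sessions <- lapply(batt, function(p) {
    tg <- protocol_target(p)$target
    n <- if (tg == 30) 0 else round((tg - 30) * 4)
    fake_session(if (n > 0) seq(0.2, 4.8, length.out = n) else numeric(0), p)
  })
  rc <- response_curve(sessions, expected_temps = c(30, 35, 40, 45, 52))
  expect_equal(rc$temperature, c(30, 35, 40, 45, 52))
  expect_equal(rc$ap_count[rc$temperature == 30], 0)
  expect_equal(rc$ap_count[rc$temperature == 52], 88)
  expect_error(response_curve(sessions[1:4], expected_temps = c(30, 52)),
               "incomplete")
})

test_that("PSTH bins conserve the total spike count", {
  p <- protocol_single("hot", 1)
  withr::with_seed(77, {
    for (i in 1:100) {
      spikes <- sort(runif(rpois(1, 30), -2, 3))
      s <- fake_session(spikes, p)
      h <- psth(s, bin = 0.2)
      expect_equal(sum(h$count), length(spikes))
    }
  })
  empty <- psth(fake_session(numeric(0), p), bin = 0.2)
  expect_true(all(empty$count == 0))
  one_bin <- psth(c(1.01, 1.05, 1.19), bin = 0.2, from = 0, to = 2)
  expect_equal(max(one_bin$count), 3)
  expect_equal(sum(one_bin$count), 3)
})

test_that("classification follows the mechanical then thermal decision rules", {
  expect_equal(
    classify_neuron(TRUE, TRUE, TRUE, heat_rate = 18, cold_rate = 10),
    tibble::tibble(primary = "WDR", thermal = "MHC")
  )
  expect_equal(
    classify_neuron(TRUE, TRUE, TRUE, heat_rate = 18, cold_rate = 0.5),
    tibble::tibble(primary = "WDR", thermal = "MH")
  )
  expect_equal(
    classify_neuron(TRUE, TRUE, TRUE, heat_rate = 0, cold_rate = 0),
    tibble::tibble(primary = "WDR", thermal = "M")
  )
  expect_equal(
    classify_neuron(TRUE, TRUE, FALSE)$primary, "non_nociceptive"
  )
  expect_equal(
    classify_neuron(FALSE, FALSE, TRUE)$primary, "nociceptive_specific"
  )
  expect_error(classify_neuron(NA, TRUE, TRUE), "mechanical")
  # detection criterion scales with spontaneous activity
  expect_equal(
    classify_neuron(TRUE, TRUE, TRUE, heat_rate = 5, cold_rate = 0,
                    baseline = 4, baseline_sd = 1)$thermal,
    "M"
  )
})
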