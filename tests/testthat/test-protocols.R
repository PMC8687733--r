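test_that("single fast stimulus follows the ramp-hold-return program", {
  p <- protocol_single("hot", 1)
  expect_equal(protocol_temperature(p, 0), 30)
  # ramp at 300 degC/s reaches 52 degC after 22/300 s, held until 1 s
  expect_equal(protocol_temperature(p, 22 / 300), 52)
  expect_equal(protocol_temperature(p, 0.5), 52)
  expect_equal(protocol_temperature(p, 0.999), 52)
  # midpoint of the rising ramp
  expect_equal(protocol_temperature(p, 11 / 300), 41)
  # symmetric return, then baseline tail
  expect_equal(protocol_temperature(p, 1 + 22 / 300), 30)
  expect_equal(p$stimulus_onsets, 0)

  pc <- protocol_single("cold", 1)
  # 30 degC excursion at 300 degC/s: ramp completes at 0.1 s
  expect_equal(protocol_temperature(pc, 0.1), 0)
  expect_equal(protocol_temperature(pc, 0.05), 15)
  expect_error(protocol_single("hot", duration = -0.5), "positive")
})

test_that("slow ramps reach their targets at the programmed speeds", {
  ph <- protocol_slow_ramp("hot")
  expect_equal(protocol_temperature(ph, 0), 30)
  expect_equal(protocol_temperature(ph, 22 / 3), 52) # 3 degC/s
  expect_equal(protocol_temperature(ph, 2), 36)
  pc <- protocol_slow_ramp("cold")
  expect_equal(protocol_temperature(pc, 7.5), 0) # 30/4 s at 4 degC/s
  expect_equal(protocol_temperature(pc, 3), 18)
})

test_that("iterative trains place onsets arithmetically and plateau when continuous", {
  p <- protocol_iterative(protocol_single("hot", 1), n = 30, rate = 1)
  expect_equal(p$stimulus_onsets, 0:29)
  # 1000-ms episodes at 1 Hz: continuous plateau between ramps
  expect_equal(protocol_temperature(p, 14.5), 52)
  expect_equal(protocol_temperature(p, 28.9), 52)

  # 500-ms episodes alternate plateau and baseline
  p5 <- protocol_iterative(protocol_single("hot", 0.5), n = 30, rate = 1)
  expect_equal(p5$stimulus_onsets, 0:29)
  for (k in c(0, 7, 29)) {
    expect_equal(protocol_temperature(p5, k + 0.3), 52)
  }
  for (k in c(0, 7, 28)) {
    expect_equal(protocol_temperature(p5, k + 0.8), 30)
  }

  expect_error(
    protocol_iterative(protocol_single("hot", 1.5), n = 5, rate = 1),
    "overlap"
  )
})

test_that("iterative train with n = 1 is the base protocol pointwise", {
  base <- protocol_single("hot", 0.75)
  p1 <- protocol_iterative(base, n = 1, rate = 1)
  tt <- seq(0, base$total_duration, by = 1e-3)
  expect_equal(protocol_temperature(p1, tt), protocol_temperature(base, tt))
})

test_that("response-curve battery covers the probe temperatures", {
  hot <- protocol_response_curve("hot")
  expect_named(hot, c("30C", "35C", "40C", "45C", "52C"))
  cold <- protocol_response_curve("cold")
  expect_named(cold, c("20C", "15C", "10C", "5C", "0C"))
  # the 30 degC "stimulus" is flat at baseline throughout
  flat <- hot[["30C"]]
  tt <- seq(0, flat$total_duration, length.out = 100)
  expect_true(all(protocol_temperature(flat, tt) == 30))
  # 5-s plateaus
  expect_equal(protocol_temperature(hot[["52C"]], 3), 52)
  expect_equal(protocol_temperature(cold[["0C"]], 3), 0)
})

test_that("waveforms are continuous at the device slew-rate limit", {
  protos <- list(
    protocol_single("hot", 0.25), protocol_single("cold", 1),
    protocol_slow_ramp("cold"),
    protocol_iterative(protocol_single("hot", 0.5), 10, 1)
  )
  for (p in protos) {
    tt <- seq(0, p$total_duration, by = 1e-3)
    jumps <- abs(diff(protocol_temperature(p, tt)))
    expect_lte(max(jumps), 300 * 1e-3 + 1e-9)
  }
})

test_that("protocols survive a serialize/parse round trip", {
  p <- protocol_iterative(protocol_single("cold", 0.75), n = 5, rate = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(p, path)
  q <- read_protocol(path)
  expect_equal(q$stimulus_onsets, p$stimulus_onsets)
  tt <- withr::with_seed(1, runif(1e4, 0, p$total_duration))
  expect_equal(protocol_temperature(q, tt), protocol_temperature(p, tt))
})

test_that("construction rejects out-of-range programs and times", {
  expect_error(
    thermal_protocol("bad", segments = tibble::tibble(
      start_time = 0, target_temp = 70, ramp_rate = 300, hold_duration = 1
    )),
    "device range"
  )
  expect_error(
    thermal_protocol("bad", segments = tibble::tibble(
      start_time = 0, target_temp = 52, ramp_rate = 400, hold_duration = 1
    )),
    "300"
  )
  p <- protocol_single("hot", 0.5)
  expect_error(protocol_temperature(p, p$total_duration + 1), "outside")
  expect_error(protocol_temperature(p, -0.5), "outside")
})

test_that("shipped protocol presets load and evaluate correctly", {
  f <- system.file("extdata", "single-hot-1000ms.yaml", package = "wdrtherm")
  p <- read_protocol(f)
  expect_equal(protocol_temperature(p, 0.5), 52)
  expect_equal(p$stimulus_onsets, 0)
  it <- read_protocol(system.file("extdata", "iterative-hot-30x1Hz.yaml",
                                  package = "wdrtherm"))
  expect_length(it$stimulus_onsets, 30)
})
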