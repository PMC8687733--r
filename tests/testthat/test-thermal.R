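test_that("analytic step response has the right limits", {
  sp <- skin_params(diffusivity = 1.1e-7)
  # boundary identity at the surface
  expect_equal(analytic_step_response(sp, 0, 22, c(0.01, 1, 10)),
               rep(52, 3))
  # steady state at long times
  expect_equal(analytic_step_response(sp, 150e-6, 22, 1e8), 52,
               tolerance = 1e-4)
  # before the step: initial temperature
  expect_equal(analytic_step_response(sp, 150e-6, 22, 0), 30)
  # inverting the closed form: the time at which 150 um reaches 43 degC
  tstar <- uniroot(
    function(t) analytic_step_response(sp, 150e-6, 22, t) - 43,
    c(1e-4, 10), tol = 1e-12
  )$root
  expect_equal(analytic_step_response(sp, 150e-6, 22, tstar), 43,
               tolerance = 1e-9)
})

test_that("finite-difference solver matches the closed-form oracle", {
  # ramp-superposition (Duhamel) solution for the full protocol waveform,
  # compared over the upper 2 mm where the semi-infinite form applies
  for (fld in list(fix_field_hot, fix_field_cold)) {
    idx <- fld$depth <= 2e-3
    err <- 0
    for (d in fld$depth[idx][c(1, 6, 16, 31, 101, 201)]) {
      ana <- analytic_protocol_response(fld$protocol, fix_sp, d, fld$time)
      num <- depth_trace(fld, d)$temp
      err <- max(err, max(abs(ana - num)))
    }
    expect_lt(err, 0.1)
  }
})

test_that("flat protocol stays at equilibrium and fields obey the maximum principle", {
  flat <- protocol_response_curve("hot")[["30C"]]
  f <- solve_skin_temperature(flat, fix_sp, dt = 5e-3)
  expect_equal(max(abs(f$temp - 30)), 0)

  for (fld in list(fix_field_hot, fix_field_cold)) {
    lims <- range(c(fix_sp$initial_temp, fix_sp$far_boundary_temp,
                    range(fld$protocol$knots$temp)))
    expect_gte(min(fld$temp), lims[1] - 1e-9)
    expect_lte(max(fld$temp), lims[2] + 1e-9)
  }
})

test_that("nociceptor-depth trace lags and undershoots the surface trace", {
  surf <- depth_trace(fix_field_hot, 0)
  deep <- depth_trace(fix_field_hot, fix_sp$nociceptor_depth)
  expect_lt(max(deep$temp), max(surf$temp))
  t_surf <- threshold_crossing_latency(fix_field_hot, 0, 43, "heating")
  t_deep <- threshold_crossing_latency(fix_field_hot,
                                       fix_sp$nociceptor_depth, 43,
                                       "heating")
  expect_lt(t_surf, t_deep)
})

test_that("crossing latency is monotone in depth and in excursion", {
  lat <- vapply(c(50e-6, 100e-6, 150e-6, 200e-6), function(d) {
    threshold_crossing_latency(fix_field_hot, d, 43, "heating")
  }, numeric(1))
  expect_true(all(diff(lat) > 0))

  # smaller excursion -> later crossing of the same threshold
  p46 <- protocol_single("hot", 1, target_temp = 46)
  f46 <- solve_skin_temperature(p46, fix_sp)
  t46 <- threshold_crossing_latency(f46, 150e-6, 40, "heating")
  t52 <- threshold_crossing_latency(fix_field_hot, 150e-6, 40, "heating")
  expect_lt(t52, t46)
})

test_that("unreachable thresholds give the no-crossing sentinel", {
  expect_true(is.na(
    threshold_crossing_latency(fix_field_hot, 150e-6, 55, "heating")
  ))
  expect_true(is.na(
    threshold_crossing_latency(fix_field_hot, 150e-6, 20, "cooling")
  ))
  # threshold at baseline: crossed essentially immediately, strictly after 0
  t0 <- threshold_crossing_latency(fix_field_hot, 150e-6, 30, "heating")
  expect_gt(t0, 0)
  expect_lt(t0, 0.47)
})

test_that("reported latencies are grid-converged to under 1 ms", {
  p <- protocol_single("hot", 1, tail_s = 0)
  f1 <- solve_skin_temperature(p, fix_sp, dt = 1e-3, dx = 1e-5)
  f2 <- solve_skin_temperature(p, fix_sp, dt = 5e-4, dx = 5e-6)
  l1 <- threshold_crossing_latency(f1, 150e-6, 43, "heating")
  l2 <- threshold_crossing_latency(f2, 150e-6, 43, "heating")
  expect_lt(abs(l1 - l2), 1e-3)
})

test_that("solver rejects grids that cannot resolve the nociceptor depth", {
  expect_error(
    solve_skin_temperature(fix_hot1, fix_sp, dx = 100e-6),
    "coarse"
  )
})

test_that("diffusivity calibration reproduces the shipped default", {
  a <- calibrate_diffusivity()
  expect_equal(a, skin_params()$diffusivity, tolerance = 1e-3)
})
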