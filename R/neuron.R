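#' Phenomenological WDR neuron parameters
#'
#' Parameters of the rate-model spike generator standing in for in vivo
#' recordings of spinal wide-dynamic-range (WDR) neurons. The model is
#' explicitly phenomenological: temperature at nociceptor depth is converted
#' to an instantaneous firing-rate drive, heat via a rectified suprathreshold
#' term with slow facilitation (wind-up-like) and slow adaptation, cold via a
#' rectified static term with a low saturating ceiling plus a
#' change-of-temperature term, both with fast adaptation. Spikes are an
#' inhomogeneous Poisson realization with an absolute refractory period and,
#' for heat, an exponentially decaying post-discharge tail.
#'
#' Defaults are calibrated against the summary statistics of the modelled
#' preparation: mean first-spike latencies near 0.49 s (hot) and 0.21 s
#' (cold) for 1000-ms single stimuli, 2-s evoked rates in the 12--17 Hz
#' range, slow-ramp activation thresholds near 43.4 and 19.8 degC, hot
#' wind-up rising over the first three 1-Hz stimuli then decaying with a
#' time constant of about 8 s, and 5-s response-curve counts that plateau
#' near 25 spikes for deep cold but exceed 100 for noxious heat.
#'
#' @param neuron_class one of `"MHC"`, `"MH"`, `"M"`, `"NS"`,
#'   `"non_nociceptive"`. `"M"` and `"non_nociceptive"` have their thermal
#'   gains zeroed; classes differ in mechanical response flags.
#' @param heat_threshold,cold_threshold transduction thresholds at nociceptor
#'   depth, degC.
#' @param heat_gain static heat drive gain, Hz/degC.
#' @param heat_supra_sat saturation of the suprathreshold excursion feeding
#'   the static heat drive, degC.
#' @param heat_dynamic_gain gain on the warming rate dT/dt above threshold
#'   (the onset-burst component), Hz/(degC/s).
#' @param cold_static_gain cold static drive gain, Hz/degC.
#' @param cold_static_max ceiling of the cold static drive, Hz.
#' @param cold_dynamic_gain gain on the cooling rate -dT/dt, Hz/(degC/s).
#' @param facilitation_gain,facilitation_tau heat facilitation amplitude
#'   (unitless) and time constant (s of accumulated suprathreshold exposure).
#' @param adaptation_tau_heat,adaptation_floor_heat heat adaptation time
#'   constant (s) and asymptotic fraction.
#' @param adaptation_tau_cold,adaptation_floor_cold cold adaptation time
#'   constant (s) and asymptotic fraction.
#' @param conduction_delay_heat,conduction_delay_cold afferent conduction
#'   delays, s (cold shorter: A-delta-like vs C-fibre-like).
#' @param postdischarge_tau decay constant of the heat post-discharge tail, s.
#' @param refractory absolute refractory period, s.
#' @param baseline_rate spontaneous rate, Hz.
#' @param max_rate firing-rate ceiling, Hz.
#' @return an object of class `wdr_neuron_params`.
#' @export
neuron_params <- function(neuron_class = c("MHC", "MH", "M", "NS",
                                           "non_nociceptive"),
                          heat_threshold = 43,
                          cold_threshold = 19.8,
                          heat_gain = 20,
                          heat_supra_sat = 3,
                          heat_dynamic_gain = 6,
                          cold_static_gain = 2.6,
                          cold_static_max = 14,
                          cold_dynamic_gain = 1.4,
                          facilitation_gain = 0.8,
                          facilitation_tau = 1.5,
                          adaptation_tau_heat = 8.12,
                          adaptation_floor_heat = 0.01,
                          adaptation_tau_cold = 0.8,
                          adaptation_floor_cold = 0.2,
                          conduction_delay_heat = 0.008,
                          conduction_delay_cold = 0.004,
                          postdischarge_tau = 0.35,
                          refractory = 0.002,
                          baseline_rate = 0.1,
                          max_rate = 100) {
  neuron_class <- match.arg(neuron_class)
  stopifnot(cold_threshold < 30, heat_threshold > 30, refractory > 0,
            conduction_delay_cold < conduction_delay_heat)
  p <- list(
    neuron_class = neuron_class,
    heat_threshold = heat_threshold, cold_threshold = cold_threshold,
    heat_gain = heat_gain, heat_supra_sat = heat_supra_sat,
    heat_dynamic_gain = heat_dynamic_gain,
    cold_static_gain = cold_static_gain, cold_static_max = cold_static_max,
    cold_dynamic_gain = cold_dynamic_gain,
    facilitation_gain = facilitation_gain, facilitation_tau = facilitation_tau,
    adaptation_tau_heat = adaptation_tau_heat,
    adaptation_floor_heat = adaptation_floor_heat,
    adaptation_tau_cold = adaptation_tau_cold,
    adaptation_floor_cold = adaptation_floor_cold,
    conduction_delay_heat = conduction_delay_heat,
    conduction_delay_cold = conduction_delay_cold,
    postdischarge_tau = postdischarge_tau,
    refractory = refractory, baseline_rate = baseline_rate,
    max_rate = max_rate
  )
  # class contracts: no thermal transduction for mechano-only and
  # non-nociceptive units
  if (neuron_class %in% c("M", "non_nociceptive")) {
    p$heat_gain <- 0
    p$heat_dynamic_gain <- 0
    p$cold_static_gain <- 0
    p$cold_dynamic_gain <- 0
  }
  if (neuron_class %in% c("MH", "NS")) {
    # heat-responsive but cold-insensitive
    p$cold_static_gain <- 0
    p$cold_dynamic_gain <- 0
  }
  structure(p, class = "wdr_neuron_params")
}

#' Mechanical response flags implied by a neuron class
#'
#' WDR classes respond to innocuous brush/pressure and to noxious pinch;
#' nociceptive-specific units only to pinch; non-nociceptive units only to
#' innocuous stimuli.
#'
#' @param neuron_class class label.
#' @return a tibble with logical columns `brush`, `pressure`, `pinch`.
#' @export
mechanical_flags <- function(neuron_class) {
  wdr <- neuron_class %in% c("M", "MH", "MHC")
  tibble::tibble(
    brush = wdr | neuron_class == "non_nociceptive",
    pressure = wdr | neuron_class == "non_nociceptive",
    pinch = wdr | neuron_class == "NS"
  )
}

#' Firing-rate drive from a temperature trace
#'
#' Converts the temperature trace at nociceptor depth into a non-negative
#' instantaneous firing-rate drive (Hz), before conduction delay and
#' spike generation.
#'
#' Heat: `(heat_gain * min(max(T - heat_threshold, 0), heat_supra_sat) +
#' heat_dynamic_gain * max(dT/dt, 0)) * F(t) * A(t)`, active only above
#' `heat_threshold`. The facilitation factor F rises with accumulated
#' suprathreshold exposure (saturating over ~`facilitation_tau` seconds of
#' exposure), the adaptation factor A decays toward `adaptation_floor_heat`
#' with constant `adaptation_tau_heat`, and the warming-rate term produces
#' the sharp onset burst. After each suprathreshold episode an exponentially
#' decaying post-discharge tail is appended (`postdischarge_tau`).
#'
#' Cold: `(min(cold_static_gain * max(cold_threshold - T, 0),
#' cold_static_max) + cold_dynamic_gain * max(-dT/dt, 0)) * A(t)`, active
#' only below `cold_threshold`, with fast adaptation
#' (`adaptation_tau_cold` much smaller than the heat constant) toward
#' `adaptation_floor_cold`.
#'
#' @param trace a tibble with columns `time` (s, uniform grid) and `temp`
#'   (degC), e.g. from [depth_trace()].
#' @param np a [wdr_neuron_params][neuron_params].
#' @param modality `"hot"` or `"cold"`.
#' @return a tibble with columns `time` and `drive` (Hz).
#' @export
transduction_drive <- function(trace, np, modality = c("hot", "cold")) {
  modality <- match.arg(modality)
  stopifnot(inherits(np, "wdr_neuron_params"),
            all(c("time", "temp") %in% names(trace)))
  tt <- trace$time
  temp <- trace$temp
  n <- length(tt)
  if (n < 2) stop("trace needs at least two samples", call. = FALSE)
  dt <- tt[2] - tt[1]

  if (modality == "hot") {
    supra <- pmax(temp - np$heat_threshold, 0)
    active <- supra > 0
    s <- cumsum(active) * dt # accumulated suprathreshold exposure
    fac <- 1 + np$facilitation_gain * (1 - exp(-s / np$facilitation_tau))
    ada <- np$adaptation_floor_heat +
      (1 - np$adaptation_floor_heat) * exp(-s / np$adaptation_tau_heat)
    warm_rate <- pmax(c(0, diff(temp)) / dt, 0)
    drive <- (np$heat_gain * pmin(supra, np$heat_supra_sat) +
                np$heat_dynamic_gain * warm_rate * as.numeric(active)) *
      as.numeric(active) * fac * ada
    # post-discharge: after each offset, the drive decays from its last
    # value instead of dropping to zero (characteristic of C-fibre input)
    offs <- which(!active & c(FALSE, active[-n]))
    for (i0 in offs) {
      tail_idx <- i0:n
      tail_val <- drive[i0 - 1] *
        exp(-(tt[tail_idx] - tt[i0 - 1]) / np$postdischarge_tau)
      drive[tail_idx] <- pmax(drive[tail_idx], tail_val)
    }
  } else {
    below <- pmax(np$cold_threshold - temp, 0)
    active <- below > 0
    s <- cumsum(active) * dt
    ada <- np$adaptation_floor_cold +
      (1 - np$adaptation_floor_cold) * exp(-s / np$adaptation_tau_cold)
    static <- pmin(np$cold_static_gain * below, np$cold_static_max)
    cool_rate <- pmax(-c(0, diff(temp)) / dt, 0)
    dyn <- np$cold_dynamic_gain * cool_rate
    drive <- (static + dyn) * as.numeric(active) * ada
  }
  tibble::tibble(time = tt, drive = drive)
}

#' Generate a spike train from a rate drive
#'
#' Inhomogeneous Poisson realization of
#' `rate(t) = min(baseline_rate + drive(t - delay), max_rate)` with an
#' absolute refractory period, by per-bin thinning on the drive's time grid.
#' Deterministic for a fixed seed.
#'
#' @param drive a tibble with columns `time` and `drive` (Hz, non-negative).
#' @param np a [wdr_neuron_params][neuron_params].
#' @param seed integer seed.
#' @param delay conduction delay applied to the drive, s.
#' @return sorted numeric vector of spike times, s.
#' @export
generate_spike_train <- function(drive, np, seed, delay = 0) {
  stopifnot(inherits(np, "wdr_neuron_params"))
  if (any(drive$drive < 0)) {
    stop("drive must be non-negative", call. = FALSE)
  }
  tt <- drive$time
  dt <- tt[2] - tt[1]
  d <- if (delay > 0) {
    stats::approx(tt + delay, drive$drive, xout = tt, yleft = 0,
                  yright = drive$drive[length(tt)])$y
  } else {
    drive$drive
  }
  rate <- pmin(np$baseline_rate + d, np$max_rate)
  withr::with_seed(seed, {
    p <- 1 - exp(-rate * dt)
    hit <- which(stats::runif(length(p)) < p)
    cand <- tt[hit] + stats::runif(length(hit)) * dt
  })
  enforce_refractory(sort(cand), np$refractory)
}

# drop spikes closer than the refractory period to the previous kept spike
enforce_refractory <- function(times, refractory) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate one recording session
#'
#' Runs the full chain for one neuron under one protocol: solve the skin
#' temperature field, read the trace at nociceptor depth, build hot and cold
#' transduction drives (each shifted by its conduction delay), and draw the
#' spike train, including a spontaneous-rate baseline epoch before stimulus
#' onset.
#'
#' @param p a [wdr_protocol][thermal_protocol].
#' @param np a [wdr_neuron_params][neuron_params].
#' @param sp a [wdr_skin_params][skin_params].
#' @param seed integer seed.
#' @param baseline_s baseline epoch duration before protocol start, s.
#' @param dt simulation time step, s.
#' @param neuron_id identifier stored in the session.
#' @param field optional pre-solved [wdr_field][solve_skin_temperature] for
#'   `p` (lets cohort simulations share one solve per protocol).
#' @return an object of class `wdr_session`.
#' @export
simulate_recording <- function(p, np, sp = skin_params(), seed,
                               baseline_s = 2, dt = 1e-3,
                               neuron_id = "n1", field = NULL) {
  stopifnot(inherits(p, "wdr_protocol"), inherits(np, "wdr_neuron_params"))
  if (is.null(field)) field <- solve_skin_temperature(p, sp, dt = dt)
  tr <- depth_trace(field, sp$nociceptor_depth)

  # extend the time axis with the pre-stimulus baseline epoch
  pre <- seq(-baseline_s, -dt, by = dt)
  tt <- c(pre, tr$time)
  flat <- rep(0, length(pre))

  dh <- transduction_drive(tr, np, "hot")
  dc <- transduction_drive(tr, np, "cold")
  shift <- function(d, delay) {
    stats::approx(c(pre, d$time + delay), c(flat, d$drive), xout = tt,
                  yleft = 0, yright = d$drive[nrow(d)])$y
  }
  total <- shift(dh, np$conduction_delay_heat) +
    shift(dc, np$conduction_delay_cold)
  spikes <- generate_spike_train(
    tibble::tibble(time = tt, drive = total), np, seed
  )

  structure(
    list(
      neuron_id = neuron_id,
      neuron_class = np$neuron_class,
      protocol_name = p$name,
      protocol = p,
      params = np,
      baseline_epoch = c(-baseline_s, 0),
      onset = if (length(p$stimulus_onsets)) p$stimulus_onsets[1] else 0,
      spike_times = spikes,
      seed = seed,
      mechanical = mechanical_flags(np$neuron_class)
    ),
    class = "wdr_session"
  )
}

#' @export
print.wdr_session <- function(x, ...) {
  cat(sprintf(
    "<wdr_session> %s (%s) under %s: %d spikes on [%.3g, %.3g] s\n",
    x$neuron_id, x$neuron_class, x$protocol_name, length(x$spike_times),
    x$baseline_epoch[1], x$protocol$total_duration
  ))
  invisible(x)
}

#' Tidy a session into a spike-event table
#'
#' @param x a [wdr_session][simulate_recording].
#' @param ... unused.
#' @return a tibble with columns `neuron_id`, `protocol_name`,
#'   `spike_time_s`.
#' @export
tidy.wdr_session <- function(x, ...) {
  tibble::tibble(
    neuron_id = x$neuron_id,
    protocol_name = x$protocol_name,
    spike_time_s = x$spike_times
  )
}

#' Cohort specification
#'
#' Counts per neuron class for a simulated cohort. The default fixture
#' mirrors the modelled study population: 37 recorded units of which 5
#' non-nociceptive and 2 nociceptive-specific are excluded, leaving 30 WDR
#' units (5 mechano-only, 8 mechano-heat, 17 mechano-heat-cold).
#'
#' @param non_nociceptive,NS,M,MH,MHC class counts.
#' @return an object of class `wdr_cohort_spec`.
#' @export
cohort_spec <- function(non_nociceptive = 5, NS = 2, M = 5, MH = 8,
                        MHC = 17) {
  counts <- c(non_nociceptive = non_nociceptive, NS = NS, M = M, MH = MH,
              MHC = MHC)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(counts = counts), class = "wdr_cohort_spec")
}

#' Default protocol battery for cohort simulation
#'
#' The minimal thermal battery needed for classification: the 1000-ms single
#' hot and cold stimuli. `full = TRUE` adds the slow ramps.
#'
#' @param full include slow-ramp protocols.
#' @return a named list of [wdr_protocol][thermal_protocol] objects.
#' @export
cohort_battery <- function(full = FALSE) {
  b <- list(
    single_hot = protocol_single("hot", 1),
    single_cold = protocol_single("cold", 1)
  )
  if (full) {
    b$ramp_hot <- protocol_slow_ramp("hot")
    b$ramp_cold <- protocol_slow_ramp("cold")
  }
  b
}

#' Generate a simulated cohort
#'
#' One neuron per count entry of the spec, with parameters jittered around
#' the class defaults (log-normal, 10% coefficient of variation), each run
#' through every protocol of the battery. Temperature fields are solved once
#' per protocol and shared across neurons. Ground-truth class labels are
#' retained for recovery tests.
#'
#' @param cs a [wdr_cohort_spec][cohort_spec].
#' @param battery named list of protocols, see [cohort_battery()].
#' @param sp a [wdr_skin_params][skin_params].
#' @param seed integer seed driving jitter and spike generation.
#' @param jitter_cv coefficient of variation of the parameter jitter.
#' @param baseline_s baseline epoch per session, s.
#' @return a tibble with one row per session: `neuron_id`, `true_class`,
#'   `protocol_name`, `brush`, `pressure`, `pinch`, and a `session` list
#'   column of [wdr_session][simulate_recording] objects.
#' @export
generate_cohort <- function(cs = cohort_spec(), battery = cohort_battery(),
                            sp = skin_params(), seed = 7, jitter_cv = 0.1,
                            baseline_s = 2) {
  stopifnot(inherits(cs, "wdr_cohort_spec"))
  classes <- rep(names(cs$counts), cs$counts)
  if (length(classes) == 0) {
    return(tibble::tibble(
      neuron_id = character(), true_class = character(),
      protocol_name = character(), brush = logical(), pressure = logical(),
      pinch = logical(), session = list()
    ))
  }
  fields <- lapply(battery, solve_skin_temperature, sp = sp)

  withr::with_seed(seed, {
    neurons <- purrr::imap(classes, function(cl, i) {
      jitter_params(neuron_params(cl), jitter_cv)
    })
    spike_seeds <- matrix(
      sample.int(.Machine$integer.max, length(classes) * length(battery)),
      nrow = length(classes)
    )
  })

  purrr::imap_dfr(classes, function(cl, i) {
    np <- neurons[[i]]
    id <- sprintf("n%02d", i)
    purrr::imap_dfr(battery, function(p, pname) {
      j <- match(pname, names(battery))
      s <- simulate_recording(p, np, sp, seed = spike_seeds[i, j],
                              baseline_s = baseline_s, neuron_id = id,
                              field = fields[[pname]])
      fl <- s$mechanical
      tibble::tibble(
        neuron_id = id, true_class = cl, protocol_name = pname,
        brush = fl$brush, pressure = fl$pressure, pinch = fl$pinch,
        session = list(s)
      )
    })
  })
}

# log-normal multiplicative jitter (cv coefficient of variation) on the
# positive rate/time-constant parameters; thresholds get additive jitter so
# ordering constraints survive
jitter_params <- function(np, cv) {
  if (cv <= 0) return(np)
  sdlog <- sqrt(log(1 + cv^2))
  jit <- function(x) {
    if (x <= 0) return(x)
    x * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  for (f in c("heat_gain", "heat_dynamic_gain", "cold_static_gain",
              "cold_static_max",
              "cold_dynamic_gain", "facilitation_gain", "facilitation_tau",
              "adaptation_tau_heat", "adaptation_tau_cold",
              "postdischarge_tau")) {
    np[[f]] <- jit(np[[f]])
  }
  np$heat_threshold <- np$heat_threshold + stats::rnorm(1, 0, 0.4)
  np$cold_threshold <- np$cold_threshold + stats::rnorm(1, 0, 0.6)
  np
}
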