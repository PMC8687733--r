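#' First-spike latency
#'
#' Latency from stimulus onset to the first spike strictly after onset.
#' Spontaneous spikes in the baseline epoch never count. When no spike occurs
#' between onset and the end of the session, the result is flagged
#' undefined rather than raising an error.
#'
#' @param s a [wdr_session][simulate_recording] or a numeric vector of spike
#'   times (s).
#' @param onset stimulus onset time, s; defaults to the session's first
#'   stimulus onset.
#' @param end latest time considered, s; defaults to the protocol end.
#' @return a one-row tibble with columns `latency` (s), `first_spike_time`
#'   (s) and `defined`.
#' @export
first_spike_latency <- function(s, onset = NULL, end = NULL) {
  spikes <- spike_times_of(s)
  if (is.null(onset)) onset <- onset_of(s)
  if (is.null(end)) end <- end_of(s)
  hit <- spikes[spikes > onset & spikes <= end]
  if (length(hit) == 0) {
    return(tibble::tibble(latency = NA_real_, first_spike_time = NA_real_,
                          defined = FALSE))
  }
  tibble::tibble(latency = hit[1] - onset, first_spike_time = hit[1],
                 defined = TRUE)
}

spike_times_of <- function(s) {
  if (inherits(s, "wdr_session")) s$spike_times else as.numeric(s)
}
onset_of <- function(s) {
  if (inherits(s, "wdr_session")) s$onset else 0
}
end_of <- function(s) {
  if (inherits(s, "wdr_session")) s$protocol$total_duration else Inf
}

#' Baseline firing rate of a session
#'
#' Mean rate over the pre-stimulus baseline epoch.
#'
#' @param s a [wdr_session][simulate_recording].
#' @return rate, Hz.
#' @export
baseline_rate <- function(s) {
  stopifnot(inherits(s, "wdr_session"))
  ep <- s$baseline_epoch
  len <- diff(ep)
  if (len <= 0) stop("empty baseline epoch", call. = FALSE)
  sum(s$spike_times >= ep[1] & s$spike_times < ep[2]) / len
}

#' Windowed evoked firing rate
#'
#' Spike rate in the left-closed right-open window `[onset, onset +
#' window_len)`, with the mean baseline rate (from the pre-stimulus epoch)
#' subtracted. The 2-s default window matches the duration of the
#' stereotypical bursting discharge after a single fast stimulus.
#'
#' @param s a [wdr_session][simulate_recording].
#' @param onset window start, s; defaults to the first stimulus onset.
#' @param window_len window length, s.
#' @return a one-row tibble with `window_start`, `window_end`, `raw_rate`,
#'   `baseline_rate`, `evoked_rate` (all rates in Hz).
#' @export
evoked_rate <- function(s, onset = NULL, window_len = 2) {
  stopifnot(inherits(s, "wdr_session"))
  if (window_len <= 0) stop("window_len must be positive", call. = FALSE)
  if (is.null(onset)) onset <- onset_of(s)
  raw <- sum(s$spike_times >= onset &
               s$spike_times < onset + window_len) / window_len
  base <- baseline_rate(s)
  tibble::tibble(window_start = onset, window_end = onset + window_len,
                 raw_rate = raw, baseline_rate = base,
                 evoked_rate = raw - base)
}

#' Activation threshold from a slow-ramp session
#'
#' The probe (surface setpoint) temperature at the moment of the first
#' evoked spike during a slow heating or cooling ramp: the study's estimator
#' of the afferent activation threshold.
#'
#' @param s a [wdr_session][simulate_recording].
#' @param p the ramp protocol; defaults to the session's protocol.
#' @return a one-row tibble with `threshold_temp` (degC),
#'   `first_spike_time` (s), `modality` and `defined`.
#' @export
ramp_threshold <- function(s, p = NULL) {
  stopifnot(inherits(s, "wdr_session") || is.numeric(s))
  if (is.null(p)) p <- s$protocol
  stopifnot(inherits(p, "wdr_protocol"))
  lat <- first_spike_latency(s, onset = p$stimulus_onsets[1],
                             end = p$total_duration)
  modality <- protocol_target(p)$modality
  if (!lat$defined) {
    return(tibble::tibble(threshold_temp = NA_real_,
                          first_spike_time = NA_real_,
                          modality = modality, defined = FALSE))
  }
  tibble::tibble(
    threshold_temp = protocol_temperature(p, lat$first_spike_time),
    first_spike_time = lat$first_spike_time,
    modality = modality, defined = TRUE
  )
}

#' Exponential decay fit
#'
#' Least-squares fit of `y = c + A * exp(-(t - t[1]) / tau)`, the model used
#' for the progressive rate decrease under iterative stimulation. Starting
#' values come from a log-linear regression on the baseline-shifted series.
#'
#' @param t,y numeric vectors (time in s, rate in Hz).
#' @return an object of class `wdr_decay_fit` with elements `A`, `tau`, `c`,
#'   `fitted` and the underlying `nls` model, or with `NA` parameters when
#'   the fit fails.
#' @export
fit_exp_decay <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 3)
  t0 <- t[1]
  ts <- t - t0
  c0 <- min(y) - 0.05 * (max(y) - min(y)) - 1e-9
  pos <- y - c0 > 0
  lf <- stats::lm(log(y[pos] - c0) ~ ts[pos])
  start <- list(
    A = exp(stats::coef(lf)[[1]]),
    tau = max(-1 / stats::coef(lf)[[2]], 1e-3),
    c = c0
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c + A * exp(-ts / tau),
      data = data.frame(ts = ts, y = y),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(A = NA_real_, tau = NA_real_, c = mean(y), t0 = t0,
           fitted = rep(mean(y), length(t)), model = NULL, converged = FALSE),
      class = "wdr_decay_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(A = unname(cf["A"]), tau = unname(cf["tau"]), c = unname(cf["c"]),
         t0 = t0, fitted = as.numeric(stats::fitted(fit)), model = fit,
         converged = TRUE),
    class = "wdr_decay_fit"
  )
}

#' @export
print.wdr_decay_fit <- function(x, ...) {
  cat(sprintf("<wdr_decay_fit> y = %.4g + %.4g exp(-(t-%g)/%.4g)\n",
              x$c, x$A, x$t0, x$tau))
  invisible(x)
}

#' @export
tidy.wdr_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "tau", "c"),
                 estimate = c(x$A, x$tau, x$c))
}

#' @export
glance.wdr_decay_fit <- function(x, ...) {
  tibble::tibble(A = x$A, tau = x$tau, c = x$c, converged = x$converged)
}

#' Per-stimulus rate profile of an iterative train
#'
#' Splits an iterative-protocol session into one window per stimulus (window
#' length = the inter-stimulus interval), computes baseline-subtracted rates,
#' fits the exponential decay of the post-peak portion, and reports the
#' wind-up index: the peak rate over the first three stimuli divided by the
#' first-stimulus rate.
#'
#' @param s a [wdr_session][simulate_recording].
#' @param p the iterative protocol; defaults to the session's protocol.
#' @param fit_from `"peak"` (decay fitted from the highest of the first
#'   three stimuli onward, appropriate for hot trains) or `"first"`.
#' @return an object of class `wdr_iterative_profile` with a `rates` tibble
#'   (`stimulus`, `onset`, `rate`), the decay `fit`, `fit_valid` (`FALSE`
#'   when the fitted tau exceeds 10x the protocol duration, in which case
#'   only the asymptote is meaningful) and `windup_index`.
#' @export
iterative_profile <- function(s, p = NULL, fit_from = c("peak", "first")) {
  fit_from <- match.arg(fit_from)
  stopifnot(inherits(s, "wdr_session"))
  if (is.null(p)) p <- s$protocol
  onsets <- p$stimulus_onsets
  if (length(onsets) < 2) {
    stop("iterative_profile needs a protocol with >= 2 stimulus onsets",
         call. = FALSE)
  }
  period <- onsets[2] - onsets[1]
  base <- baseline_rate(s)
  rates <- purrr::map_dbl(onsets, function(o) {
    sum(s$spike_times >= o & s$spike_times < o + period) / period - base
  })
  rt <- tibble::tibble(stimulus = seq_along(onsets), onset = onsets,
                       rate = rates)

  k3 <- min(3, length(rates))
  peak_i <- if (fit_from == "peak") which.max(rates[1:k3]) else 1L
  fit <- NULL
  fit_valid <- FALSE
  if (length(rates) - peak_i + 1 >= 3) {
    fit <- fit_exp_decay(onsets[peak_i:length(onsets)] + period / 2,
                         rates[peak_i:length(rates)])
    fit_valid <- isTRUE(fit$converged) &&
      is.finite(fit$tau) && fit$tau <= 10 * p$total_duration
  }
  windup <- if (rates[1] > 0) max(rates[1:k3]) / rates[1] else NA_real_

  structure(
    list(rates = rt, fit = fit, fit_valid = fit_valid,
         windup_index = windup, peak_stimulus = peak_i,
         baseline_rate = base, protocol_name = p$name),
    class = "wdr_iterative_profile"
  )
}

#' @export
print.wdr_iterative_profile <- function(x, ...) {
  cat(sprintf(
    "<wdr_iterative_profile> %s: %d stimuli, windup index %.3g%s\n",
    x$protocol_name, nrow(x$rates), x$windup_index,
    if (x$fit_valid) sprintf(", decay tau %.3g s", x$fit$tau) else ""
  ))
  invisible(x)
}

#' @export
tidy.wdr_iterative_profile <- function(x, ...) x$rates

#' @export
glance.wdr_iterative_profile <- function(x, ...) {
  tibble::tibble(
    n_stimuli = nrow(x$rates),
    windup_index = x$windup_index,
    peak_stimulus = x$peak_stimulus,
    fit_A = if (is.null(x$fit)) NA_real_ else x$fit$A,
    fit_tau = if (is.null(x$fit)) NA_real_ else x$fit$tau,
    fit_asymptote = if (is.null(x$fit)) NA_real_ else x$fit$c,
    fit_valid = x$fit_valid
  )
}

#' @export
autoplot.wdr_iterative_profile <- function(object, ...) {
  g <- ggplot2::ggplot(object$rates,
                       ggplot2::aes(.data$stimulus, .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "stimulus", y = "evoked rate (Hz)")
  if (object$fit_valid) {
    i <- object$peak_stimulus
    df <- object$rates[i:nrow(object$rates), ]
    df$fitted <- object$fit$fitted
    g <- g + ggplot2::geom_line(data = df,
                                ggplot2::aes(.data$stimulus, .data$fitted),
                                colour = "firebrick")
  }
  g
}

#' Hot/cold response curve
#'
#' Baseline-corrected spike counts within the 5-s stimulus, one per probe
#' temperature of the response-curve battery.
#'
#' @param sessions a list of [wdr_session][simulate_recording] objects, one
#'   per battery temperature (e.g. simulated over
#'   [protocol_response_curve()]).
#' @param window count window length, s; defaults to the plateau duration.
#' @param expected_temps if given, temperatures that must all be present;
#'   a missing one is an error (incomplete battery).
#' @return an object of class `wdr_response_curve`: a tibble with columns
#'   `temperature` (degC) and `ap_count`.
#' @export
response_curve <- function(sessions, window = 5, expected_temps = NULL) {
  stopifnot(length(sessions) >= 1)
  df <- purrr::map_dfr(sessions, function(s) {
    stopifnot(inherits(s, "wdr_session"))
    tg <- protocol_target(s$protocol)
    o <- onset_of(s)
    raw <- sum(s$spike_times >= o & s$spike_times < o + window)
    corrected <- max(raw - baseline_rate(s) * window, 0)
    tibble::tibble(temperature = tg$target, ap_count = corrected)
  })
  if (!is.null(expected_temps)) {
    miss <- setdiff(expected_temps, df$temperature)
    if (length(miss) > 0) {
      stop("incomplete battery: missing temperature(s) ",
           paste(miss, collapse = ", "), " degC", call. = FALSE)
    }
  }
  df <- dplyr::arrange(df, .data$temperature)
  class(df) <- c("wdr_response_curve", class(df))
  df
}

#' @export
autoplot.wdr_response_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$temperature, .data$ap_count)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "probe temperature (degC)",
                  y = "AP count per stimulus")
}

#' Peristimulus time histogram
#'
#' Left-closed right-open binning of spike counts over the session (default
#' 200-ms bins). Bin edges are anchored at the start of the baseline epoch so
#' every spike falls in exactly one bin.
#'
#' @param s a [wdr_session][simulate_recording] or numeric spike times.
#' @param bin bin width, s.
#' @param from,to histogram range, s; default the session extent.
#' @return a tibble with columns `bin_start`, `bin_mid`, `count`.
#' @export
psth <- function(s, bin = 0.2, from = NULL, to = NULL) {
  if (bin <= 0) stop("bin must be positive", call. = FALSE)
  spikes <- spike_times_of(s)
  if (is.null(from)) {
    from <- if (inherits(s, "wdr_session")) s$baseline_epoch[1]
            else if (length(spikes)) min(spikes) else 0
  }
  if (is.null(to)) {
    to <- if (inherits(s, "wdr_session")) s$protocol$total_duration
          else if (length(spikes)) max(spikes) + bin else bin
  }
  edges <- seq(from, to + bin - 1e-12, by = bin)
  counts <- as.integer(table(cut(spikes[spikes >= from & spikes < max(edges)],
                                 breaks = edges, right = FALSE)))
  tibble::tibble(bin_start = edges[-length(edges)],
                 bin_mid = edges[-length(edges)] + bin / 2,
                 count = counts)
}

#' Plot a PSTH
#'
#' @param s a [wdr_session][simulate_recording].
#' @param bin bin width, s.
#' @return a ggplot.
#' @export
plot_psth <- function(s, bin = 0.2) {
  df <- psth(s, bin)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = bin, fill = "grey30") +
    ggplot2::labs(x = "time (s)", y = sprintf("spikes / %g ms", bin * 1000))
}

#' Classify a neuron from its battery results
#'
#' Mechanical flags determine the primary label: innocuous-only responders
#' are non-nociceptive, pinch-only responders are nociceptive-specific, and
#' units responding to both innocuous and noxious mechanical stimuli are
#' wide-dynamic-range (WDR). WDR units are sub-labelled M / MH / MHC by
#' whether their evoked rate at 52 degC and 0 degC exceeds the detection
#' criterion `max(criterion_hz, baseline + 3 * baseline_sd)`.
#'
#' @param brush,pressure,pinch logical mechanical response flags.
#' @param heat_rate,cold_rate evoked rates (Hz) at the 52 degC and 0 degC
#'   single stimuli; `NA` is treated as no response.
#' @param baseline mean spontaneous rate, Hz.
#' @param baseline_sd between-epoch SD of the spontaneous rate, Hz.
#' @param criterion_hz minimum evoked rate counted as a response, Hz.
#' @return a one-row tibble with columns `primary`
#'   (`non_nociceptive` / `nociceptive_specific` / `WDR`) and `thermal`
#'   (`M` / `MH` / `MHC`, `NA` unless WDR).
#' @export
classify_neuron <- function(brush, pressure, pinch, heat_rate = NA,
                            cold_rate = NA, baseline = 0, baseline_sd = 0,
                            criterion_hz = 2) {
  if (any(is.na(c(brush, pressure, pinch)))) {
    stop("mechanical flags are required for classification", call. = FALSE)
  }
  innocuous <- brush || pressure
  primary <- if (innocuous && pinch) {
    "WDR"
  } else if (pinch) {
    "nociceptive_specific"
  } else if (innocuous) {
    "non_nociceptive"
  } else {
    stop("unit responds to no mechanical stimulus; not classifiable",
         call. = FALSE)
  }
  thermal <- NA_character_
  if (primary == "WDR") {
    crit <- max(criterion_hz, baseline + 3 * baseline_sd)
    heat <- !is.na(heat_rate) && heat_rate > crit
    cold <- !is.na(cold_rate) && cold_rate > crit
    thermal <- if (heat && cold) "MHC" else if (heat) "MH" else "M"
    # cold response without heat is not part of the observed repertoire;
    # label by the stronger evidence but keep the cold flag visible
    if (cold && !heat) thermal <- "MHC"
  }
  tibble::tibble(primary = primary, thermal = thermal)
}

#' Classify every neuron of a simulated cohort
#'
#' Runs [evoked_rate()] on each neuron's single hot and cold sessions and
#' [classify_neuron()] on the results.
#'
#' @param cohort a cohort tibble from [generate_cohort()].
#' @param hot_protocol,cold_protocol names of the battery entries holding
#'   the 52 degC and 0 degC single stimuli.
#' @param criterion_hz detection criterion, Hz.
#' @return a tibble with one row per neuron: `neuron_id`, `true_class`,
#'   `brush`, `pressure`, `pinch`, `heat_rate`, `cold_rate`, `primary`,
#'   `thermal`.
#' @export
classify_cohort <- function(cohort, hot_protocol = "single_hot",
                            cold_protocol = "single_cold",
                            criterion_hz = 2) {
  stopifnot(all(c("neuron_id", "protocol_name", "session") %in%
                  names(cohort)))
  cohort |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(df, key) {
      hot <- df$session[df$protocol_name == hot_protocol]
      cold <- df$session[df$protocol_name == cold_protocol]
      hr <- if (length(hot)) evoked_rate(hot[[1]])$evoked_rate else NA_real_
      cr <- if (length(cold)) evoked_rate(cold[[1]])$evoked_rate else NA_real_
      lab <- classify_neuron(df$brush[1], df$pressure[1], df$pinch[1],
                             heat_rate = hr, cold_rate = cr,
                             criterion_hz = criterion_hz)
      tibble::tibble(
        true_class = df$true_class[1],
        brush = df$brush[1], pressure = df$pressure[1], pinch = df$pinch[1],
        heat_rate = hr, cold_rate = cr,
        primary = lab$primary, thermal = lab$thermal
      )
    }) |>
    dplyr::ungroup()
}

#' Cohort classification summary
#'
#' Applies the exclusion filter (non-nociceptive and nociceptive-specific
#' units are dropped) and summarizes the retained WDR population.
#'
#' @param classified output of [classify_cohort()].
#' @return a one-row tibble: `n_total`, `n_excluded`, `n_wdr`,
#'   `n_heat` (MH or MHC), `n_mhc`, `pct_heat`, `pct_mhc` (percentages of
#'   the WDR population).
#' @export
cohort_summary <- function(classified) {
  wdr <- dplyr::filter(classified, .data$primary == "WDR")
  n_heat <- sum(wdr$thermal %in% c("MH", "MHC"))
  n_mhc <- sum(wdr$thermal == "MHC")
  tibble::tibble(
    n_total = nrow(classified),
    n_excluded = nrow(classified) - nrow(wdr),
    n_wdr = nrow(wdr),
    n_heat = n_heat,
    n_mhc = n_mhc,
    pct_heat = 100 * n_heat / nrow(wdr),
    pct_mhc = 100 * n_mhc / nrow(wdr)
  )
}
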