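#' Stimulation protocols for contact-thermode experiments
#'
#' A `wdr_protocol` is a piecewise-linear surface-temperature setpoint program
#' for one stimulation episode or train delivered by a Peltier contact
#' thermode. Protocols are built from ordered segments, each a ramp toward a
#' target temperature at a fixed rate followed by a hold, and carry the onset
#' time of every stimulus episode so analysis windows can be aligned.
#'
#' Device limits are enforced at construction: temperatures must stay within
#' 0--60 degC and ramp rates within (0, 300] degC/s.
#'
#' @param name protocol name.
#' @param baseline_temp neutral (inter-stimulus) temperature, degC.
#' @param segments a data frame with columns `start_time` (s), `target_temp`
#'   (degC), `ramp_rate` (degC/s) and `hold_duration` (s), time-ordered and
#'   non-overlapping. Each segment ramps from the current temperature to
#'   `target_temp` at `ramp_rate`, then holds for `hold_duration`.
#' @param stimulus_onsets numeric vector of stimulus onset times (s); an onset
#'   is the start of the away-from-baseline ramp of an episode.
#' @param total_duration total program duration (s); defaults to the end of
#'   the last segment.
#' @param area_mm2 stimulated skin area, mm^2 (metadata only).
#'
#' @return an object of class `wdr_protocol`.
#' @seealso [protocol_single()], [protocol_slow_ramp()], [protocol_iterative()],
#'   [protocol_response_curve()], [protocol_temperature()]
#' @export
thermal_protocol <- function(name, baseline_temp = 30, segments,
                             stimulus_onsets = numeric(),
                             total_duration = NULL, area_mm2 = 8) {
  segments <- tibble::as_tibble(segments)
  req <- c("start_time", "target_temp", "ramp_rate", "hold_duration")
  if (!all(req %in% names(segments))) {
    stop("segments must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (baseline_temp < 0 || baseline_temp > 60) {
    stop("baseline_temp outside the device range [0, 60] degC", call. = FALSE)
  }
  if (nrow(segments) > 0) {
    if (any(segments$target_temp < 0 | segments$target_temp > 60)) {
      stop("target temperatures outside the device range [0, 60] degC",
           call. = FALSE)
    }
    if (any(segments$ramp_rate <= 0 | segments$ramp_rate > 300)) {
      stop("ramp rates must lie in (0, 300] degC/s", call. = FALSE)
    }
    if (any(segments$hold_duration < 0)) {
      stop("hold durations must be non-negative", call. = FALSE)
    }
    if (is.unsorted(segments$start_time)) {
      stop("segments must be time-ordered", call. = FALSE)
    }
  }

  knots <- compile_segments(baseline_temp, segments)
  if (is.null(total_duration)) total_duration <- max(knots$time)
  if (total_duration < max(knots$time) - 1e-12) {
    stop("total_duration shorter than the compiled waveform", call. = FALSE)
  }
  if (total_duration > max(knots$time)) {
    knots <- dplyr::bind_rows(
      knots,
      tibble::tibble(time = total_duration,
                     temp = knots$temp[nrow(knots)])
    )
  }

  structure(
    list(
      name = name,
      baseline_temp = baseline_temp,
      segments = segments,
      knots = knots,
      stimulus_onsets = sort(stimulus_onsets),
      total_duration = total_duration,
      area_mm2 = area_mm2
    ),
    class = "wdr_protocol"
  )
}

# Compile ramp/hold segments into piecewise-linear (time, temp) knots.
# Overlap of a segment with the tail of the previous one is an error.
compile_segments <- function(baseline_temp, segments) {
  times <- 0
  temps <- baseline_temp
  cur_t <- 0
  cur_temp <- baseline_temp
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      s <- segments[i, ]
      if (s$start_time < cur_t - 1e-6) {
        stop("segments overlap at t = ", signif(s$start_time, 6), " s",
             call. = FALSE)
      }
      if (s$start_time > cur_t + 1e-6) {
        times <- c(times, s$start_time)
        temps <- c(temps, cur_temp)
        cur_t <- s$start_time
      }
      ramp_dur <- abs(s$target_temp - cur_temp) / s$ramp_rate
      if (ramp_dur > 0) {
        cur_t <- cur_t + ramp_dur
        times <- c(times, cur_t)
        temps <- c(temps, s$target_temp)
      }
      cur_temp <- s$target_temp
      if (s$hold_duration > 0) {
        cur_t <- cur_t + s$hold_duration
        times <- c(times, cur_t)
        temps <- c(temps, cur_temp)
      }
    }
  }
  keep <- !duplicated(times)
  tibble::tibble(time = times[keep], temp = temps[keep])
}

#' Evaluate a protocol's surface-temperature waveform
#'
#' Exact piecewise-linear evaluation of the setpoint program at arbitrary
#' times within `[0, total_duration]`.
#'
#' @param p a [wdr_protocol][thermal_protocol].
#' @param t numeric vector of times, s.
#' @return numeric vector of setpoint temperatures, degC.
#' @export
protocol_temperature <- function(p, t) {
  stopifnot(inherits(p, "wdr_protocol"))
  if (any(t < -1e-12 | t > p$total_duration + 1e-12)) {
    stop("t outside [0, ", p$total_duration, "] s", call. = FALSE)
  }
  protocol_temperature_padded(p, t)
}

# Internal evaluator: baseline before t = 0 and after the program end, so the
# simulator can run baseline epochs and post-stimulus tails on one time axis.
protocol_temperature_padded <- function(p, t) {
  stats::approx(p$knots$time, p$knots$temp, xout = t,
                yleft = p$knots$temp[1],
                yright = p$knots$temp[nrow(p$knots)])$y
}

stim_target <- function(modality, hot_target = 52, cold_target = 0) {
  modality <- match.arg(modality, c("hot", "cold"))
  if (modality == "hot") hot_target else cold_target
}

#' Single fast thermal stimulus
#'
#' One episode ramped at 300 degC/s from the 30 degC neutral temperature to
#' 52 degC (hot) or 0 degC (cold), held until `onset + duration`, then
#' returned to baseline at 300 degC/s. The stimulus duration is counted from
#' the onset of the rising ramp, so a 1000-ms episode repeated at 1 Hz forms a
#' continuous plateau.
#'
#' @param modality `"hot"` or `"cold"`.
#' @param duration stimulus duration, s (study values: 0.25, 0.5, 0.75, 1).
#' @param onset stimulus onset time, s.
#' @param tail_s baseline hold appended after the return ramp, s; the default
#'   leaves room for the 2-s analysis window and post-discharge.
#' @param target_temp plateau setpoint, degC; defaults to 52 (hot) / 0 (cold).
#' @param ramp_rate ramp speed, degC/s.
#' @param baseline_temp neutral temperature, degC.
#' @return a [wdr_protocol][thermal_protocol] with one stimulus onset.
#' @export
protocol_single <- function(modality = c("hot", "cold"), duration = 1,
                            onset = 0, tail_s = 2, target_temp = NULL,
                            ramp_rate = 300, baseline_temp = 30) {
  modality <- match.arg(modality)
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (is.null(target_temp)) target_temp <- stim_target(modality)
  ramp_dur <- abs(target_temp - baseline_temp) / ramp_rate
  if (duration < ramp_dur) {
    stop("duration shorter than the ramp to target (", signif(ramp_dur, 3),
         " s)", call. = FALSE)
  }
  segs <- tibble::tibble(
    start_time = c(onset, onset + duration),
    target_temp = c(target_temp, baseline_temp),
    ramp_rate = ramp_rate,
    hold_duration = c(duration - ramp_dur, tail_s)
  )
  if (target_temp == baseline_temp) {
    # zero-excursion "stimulus": flat program
    segs <- tibble::tibble(
      start_time = onset, target_temp = baseline_temp,
      ramp_rate = ramp_rate, hold_duration = duration + tail_s
    )
  }
  thermal_protocol(
    name = sprintf("single-%s-%gC-%gms", modality, target_temp,
                   duration * 1000),
    baseline_temp = baseline_temp, segments = segs,
    stimulus_onsets = onset
  )
}

#' Slow thermal ramp for activation-threshold estimation
#'
#' Ramps from 30 degC toward 52 degC at 3 degC/s (hot) or toward 0 degC at
#' 4 degC/s (cold), for at most 7.5 s of stimulation, then returns to
#' baseline at 300 degC/s.
#'
#' @inheritParams protocol_single
#' @param heat_rate,cold_rate ramp speeds, degC/s.
#' @param max_duration stimulation cap, s.
#' @return a [wdr_protocol][thermal_protocol].
#' @export
protocol_slow_ramp <- function(modality = c("hot", "cold"), heat_rate = 3,
                               cold_rate = 4, max_duration = 7.5,
                               tail_s = 2, baseline_temp = 30) {
  modality <- match.arg(modality)
  target <- stim_target(modality)
  rate <- if (modality == "hot") heat_rate else cold_rate
  ramp_dur <- abs(target - baseline_temp) / rate
  ramp_dur <- min(ramp_dur, max_duration)
  # temperature actually reached if the cap truncates the ramp
  reached <- baseline_temp + sign(target - baseline_temp) * rate * ramp_dur
  segs <- tibble::tibble(
    start_time = c(0, max_duration),
    target_temp = c(reached, baseline_temp),
    ramp_rate = c(rate, 300),
    hold_duration = c(max_duration - ramp_dur, tail_s)
  )
  thermal_protocol(
    name = sprintf("slow-ramp-%s", modality),
    baseline_temp = baseline_temp, segments = segs, stimulus_onsets = 0
  )
}

#' Iterative (wind-up) stimulation train
#'
#' Concatenates `n` copies of a single-stimulus protocol at a fixed repetition
#' rate (study protocol: 30 stimuli at 1 Hz). When the episode duration equals
#' the inter-stimulus interval the program is a continuous plateau.
#'
#' @param base a single-stimulus [wdr_protocol][thermal_protocol] (one onset).
#' @param n number of stimuli.
#' @param rate repetition rate, Hz.
#' @param tail_s baseline hold after the last return ramp, s.
#' @return a [wdr_protocol][thermal_protocol] with `n` stimulus onsets.
#' @export
protocol_iterative <- function(base, n = 30, rate = 1, tail_s = 2) {
  stopifnot(inherits(base, "wdr_protocol"))
  if (length(base$stimulus_onsets) != 1) {
    stop("base must be a single-stimulus protocol", call. = FALSE)
  }
  if (n < 1 || rate <= 0) stop("need n >= 1 and rate > 0", call. = FALSE)
  period <- 1 / rate
  onset0 <- base$stimulus_onsets[1]
  stim <- base$segments[1, ]
  ret <- base$segments[2, ] # may be absent for zero-excursion bases
  duration <- if (nrow(base$segments) >= 2) {
    base$segments$start_time[2] - onset0
  } else {
    stim$hold_duration
  }
  if (duration > period + 1e-12) {
    stop("episode duration exceeds the inter-stimulus interval; episodes ",
         "would overlap", call. = FALSE)
  }
  if (n == 1) return(base)

  fall_dur <- abs(stim$target_temp - base$baseline_temp) / 300
  gap <- period - duration
  segs <- list()
  for (k in seq_len(n) - 1) {
    s <- stim
    s$start_time <- onset0 + k * period
    segs <- c(segs, list(s))
    last <- k == n - 1
    if (gap > fall_dur + 1e-12 || last) {
      r <- tibble::tibble(
        start_time = onset0 + k * period + duration,
        target_temp = base$baseline_temp,
        ramp_rate = 300,
        hold_duration = if (last) tail_s else max(gap - fall_dur, 0)
      )
      segs <- c(segs, list(r))
    }
    # gap too short for a full return: plateau continues into the next episode
  }
  thermal_protocol(
    name = sprintf("iterative-%s-n%d-%gHz", base$name, n, rate),
    baseline_temp = base$baseline_temp,
    segments = dplyr::bind_rows(segs),
    stimulus_onsets = onset0 + (seq_len(n) - 1) * period
  )
}

#' Hot/cold response-curve battery
#'
#' One 5-s constant-plateau protocol per probe temperature, each ramped at
#' 300 degC/s from the 30 degC baseline. Default grids follow the study
#' battery: hot 30/35/40/45/52 degC, cold 20/15/10/5/0 degC. `grid = "by5"`
#' selects the alternative 5-degC-increment grid.
#'
#' @inheritParams protocol_single
#' @param temps probe temperatures, degC; overrides `grid`.
#' @param grid `"battery"` (default study grid) or `"by5"`.
#' @param duration plateau duration, s.
#' @return a named list of [wdr_protocol][thermal_protocol] objects.
#' @export
protocol_response_curve <- function(modality = c("hot", "cold"), temps = NULL,
                                    grid = c("battery", "by5"), duration = 5,
                                    tail_s = 2, baseline_temp = 30) {
  modality <- match.arg(modality)
  grid <- match.arg(grid)
  if (is.null(temps)) {
    temps <- if (modality == "hot") {
      if (grid == "battery") c(30, 35, 40, 45, 52) else c(seq(30, 50, 5), 52)
    } else {
      if (grid == "battery") c(20, 15, 10, 5, 0) else seq(25, 0, -5)
    }
  }
  out <- lapply(temps, function(tt) {
    protocol_single(modality, duration = duration, tail_s = tail_s,
                    target_temp = tt, baseline_temp = baseline_temp)
  })
  names(out) <- sprintf("%gC", temps)
  out
}

#' Plateau setpoint of a protocol
#'
#' The most extreme setpoint relative to baseline (the stimulus target), and
#' the implied modality.
#'
#' @param p a [wdr_protocol][thermal_protocol].
#' @return a list with `target` (degC) and `modality`
#'   (`"hot"`, `"cold"` or `"none"`).
#' @export
protocol_target <- function(p) {
  stopifnot(inherits(p, "wdr_protocol"))
  dev <- p$knots$temp - p$baseline_temp
  i <- which.max(abs(dev))
  if (abs(dev[i]) < 1e-9) {
    list(target = p$baseline_temp, modality = "none")
  } else {
    list(target = p$knots$temp[i],
         modality = if (dev[i] > 0) "hot" else "cold")
  }
}

#' @export
print.wdr_protocol <- function(x, ...) {
  cat(sprintf(
    "<wdr_protocol> %s\n  baseline %g degC, %d segment(s), %d stimulus onset(s), %.3g s total\n",
    x$name, x$baseline_temp, nrow(x$segments), length(x$stimulus_onsets),
    x$total_duration
  ))
  invisible(x)
}

#' Tidy a protocol into its waveform knots
#'
#' @param x a [wdr_protocol][thermal_protocol].
#' @param ... unused.
#' @return a tibble with columns `time` (s) and `temp` (degC).
#' @export
tidy.wdr_protocol <- function(x, ...) x$knots

#' @export
autoplot.wdr_protocol <- function(object, ...) {
  ggplot2::ggplot(object$knots, ggplot2::aes(.data$time, .data$temp)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$stimulus_onsets,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "surface setpoint (degC)",
                  title = object$name)
}

#' Write / read a protocol as human-readable YAML
#'
#' @param p a [wdr_protocol][thermal_protocol].
#' @param path file path.
#' @return `read_protocol()` returns a [wdr_protocol][thermal_protocol];
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "wdr_protocol"))
  yaml::write_yaml(
    list(
      name = p$name,
      baseline_temp = p$baseline_temp,
      area_mm2 = p$area_mm2,
      total_duration = p$total_duration,
      stimulus_onsets = as.numeric(p$stimulus_onsets),
      segments = lapply(seq_len(nrow(p$segments)), function(i) {
        as.list(p$segments[i, ])
      })
    ),
    path,
    precision = 12
  )
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  thermal_protocol(
    name = y$name,
    baseline_temp = y$baseline_temp,
    segments = dplyr::bind_rows(lapply(y$segments, tibble::as_tibble)),
    stimulus_onsets = as.numeric(unlist(y$stimulus_onsets)),
    total_duration = y$total_duration,
    area_mm2 = y$area_mm2
  )
}
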