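#' Skin thermal parameters
#'
#' Parameters of the one-dimensional heat-conduction model of the skin under
#' a contact thermode: a homogeneous half-space with the surface clamped to
#' the thermode setpoint (perfect thermal contact), a uniform initial
#' temperature, and a far boundary held at the neutral temperature.
#'
#' The default diffusivity is calibrated so that, under the 52 degC /
#' 300 degC/s single hot stimulus, the modelled temperature at 150 um depth
#' first reaches the 43 degC heat-nociceptive threshold 470 ms after stimulus
#' onset (see [calibrate_diffusivity()]). The cold prediction (18 degC at the
#' same depth under the 0 degC stimulus) then involves no further freedom.
#'
#' @param diffusivity thermal diffusivity alpha, m^2/s.
#' @param nociceptor_depth depth of the modelled nociceptive endings, m
#'   (150 um default; a 100-um preset is in common use).
#' @param initial_temp uniform initial skin temperature, degC.
#' @param domain_depth depth of the computational domain, m.
#' @param far_boundary_temp fixed temperature at `domain_depth`, degC.
#' @return an object of class `wdr_skin_params`.
#' @export
skin_params <- function(diffusivity = 9.000089e-08,
                        nociceptor_depth = 150e-6,
                        initial_temp = 30,
                        domain_depth = 5e-3,
                        far_boundary_temp = 30) {
  stopifnot(diffusivity > 0, nociceptor_depth > 0,
            nociceptor_depth < domain_depth)
  structure(
    list(diffusivity = diffusivity, nociceptor_depth = nociceptor_depth,
         initial_temp = initial_temp, domain_depth = domain_depth,
         far_boundary_temp = far_boundary_temp),
    class = "wdr_skin_params"
  )
}

#' Solve skin temperature under a protocol
#'
#' Crank--Nicolson finite-difference solution of the 1-D diffusion equation
#' dT/dt = alpha d2T/dx2 with Dirichlet boundary conditions: the surface
#' (x = 0) follows the protocol setpoint waveform and the far boundary is
#' fixed. Unconditionally stable, second order in time and space.
#'
#' @param p a [wdr_protocol][thermal_protocol].
#' @param sp a [wdr_skin_params][skin_params].
#' @param dt time step, s.
#' @param dx node spacing, m.
#' @param t_end final time, s; defaults to the protocol duration. Beyond the
#'   protocol end the surface holds the final setpoint.
#' @return an object of class `wdr_field` with elements `time` (s), `depth`
#'   (m), `temp` (time x depth matrix, degC), `protocol` and `params`.
#' @export
solve_skin_temperature <- function(p, sp = skin_params(), dt = 1e-3,
                                   dx = 1e-5, t_end = NULL) {
  stopifnot(inherits(p, "wdr_protocol"), inherits(sp, "wdr_skin_params"),
            dt > 0, dx > 0)
  if (is.null(t_end)) t_end <- p$total_duration
  if (sp$nociceptor_depth / dx < 3) {
    stop("grid too coarse: fewer than 3 nodes above nociceptor_depth",
         call. = FALSE)
  }
  x <- seq(0, sp$domain_depth, by = dx)
  nx <- length(x)
  tg <- seq(0, t_end, by = dt)
  nt <- length(tg)
  surf <- protocol_temperature_padded(p, tg)

  r <- sp$diffusivity * dt / dx^2
  ni <- nx - 2
  A <- Matrix::bandSparse(
    ni, ni, k = c(-1, 0, 1),
    diagonals = list(rep(-r / 2, ni - 1), rep(1 + r, ni),
                     rep(-r / 2, ni - 1))
  )
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A))

  temp <- matrix(sp$initial_temp, nt, nx)
  temp[, nx] <- sp$far_boundary_temp
  temp[1, 1] <- surf[1]
  u <- rep(sp$initial_temp, ni)
  far <- sp$far_boundary_temp
  for (k in 2:nt) {
    rhs <- (1 - r) * u +
      (r / 2) * (c(surf[k - 1], u[-ni]) + c(u[-1], far))
    rhs[1] <- rhs[1] + (r / 2) * surf[k]
    rhs[ni] <- rhs[ni] + (r / 2) * far
    u <- as.numeric(Matrix::solve(ch, rhs))
    temp[k, 2:(nx - 1)] <- u
    temp[k, 1] <- surf[k]
  }

  structure(
    list(time = tg, depth = x, temp = temp, protocol = p, params = sp),
    class = "wdr_field"
  )
}

#' Temperature trace at a given depth
#'
#' Linear interpolation of a solved field between depth nodes.
#'
#' @param f a [wdr_field][solve_skin_temperature].
#' @param depth depth below the surface, m.
#' @return a tibble with columns `time` (s) and `temp` (degC).
#' @export
depth_trace <- function(f, depth) {
  stopifnot(inherits(f, "wdr_field"))
  if (depth < 0 || depth > max(f$depth)) {
    stop("depth outside the solved domain", call. = FALSE)
  }
  i <- findInterval(depth, f$depth, all.inside = TRUE)
  w <- (depth - f$depth[i]) / (f$depth[i + 1] - f$depth[i])
  tibble::tibble(time = f$time,
                 temp = (1 - w) * f$temp[, i] + w * f$temp[, i + 1])
}

#' Closed-form semi-infinite step and ramp responses
#'
#' `analytic_step_response()` gives the temperature at depth after a step
#' change of the surface temperature by `delta` at t = 0:
#' `initial + delta * erfc(x / (2 sqrt(alpha t)))`.
#' `analytic_protocol_response()` superposes ramp responses (Duhamel's
#' principle) over the piecewise-linear setpoint program, giving the exact
#' semi-infinite solution for any protocol; it is the independent oracle
#' against which the finite-difference solver is verified.
#'
#' @param sp a [wdr_skin_params][skin_params].
#' @param depth depth, m.
#' @param delta surface step amplitude, degC.
#' @param t time since the step, s (vectorized).
#' @return temperature(s), degC.
#' @export
analytic_step_response <- function(sp, depth, delta, t) {
  stopifnot(inherits(sp, "wdr_skin_params"))
  out <- rep(sp$initial_temp, length(t))
  pos <- t > 0
  if (depth == 0) {
    out[pos] <- sp$initial_temp + delta
    return(out)
  }
  eta <- depth / (2 * sqrt(sp$diffusivity * t[pos]))
  out[pos] <- sp$initial_temp + delta * erfc(eta)
  out
}

# complementary error function via the normal CDF
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# response at depth x, time tau, to a unit-slope surface ramp started at 0
# (Carslaw & Jaeger: 4 tau i2erfc(eta))
ramp_kernel <- function(x, tau, alpha) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (x == 0) {
    out[pos] <- tau[pos]
    return(out)
  }
  eta <- x / (2 * sqrt(alpha * tau[pos]))
  out[pos] <- tau[pos] *
    ((1 + 2 * eta^2) * erfc(eta) - (2 / sqrt(pi)) * eta * exp(-eta^2))
  out
}

#' @rdname analytic_step_response
#' @param p a [wdr_protocol][thermal_protocol].
#' @export
analytic_protocol_response <- function(p, sp, depth, t) {
  stopifnot(inherits(p, "wdr_protocol"), inherits(sp, "wdr_skin_params"))
  kn <- p$knots
  slopes <- diff(kn$temp) / diff(kn$time)
  slopes[!is.finite(slopes)] <- 0
  dslope <- diff(c(0, slopes))
  out <- rep(sp$initial_temp, length(t))
  for (j in seq_along(dslope)) {
    if (dslope[j] != 0) {
      out <- out + dslope[j] *
        ramp_kernel(depth, t - kn$time[j], sp$diffusivity)
    }
  }
  # waveform past its last knot holds the final setpoint
  last <- length(slopes)
  if (length(slopes) >= 1 && slopes[last] != 0) {
    out <- out - slopes[last] *
      ramp_kernel(depth, t - kn$time[last + 1], sp$diffusivity)
  }
  out
}

#' First threshold crossing of a depth trace
#'
#' Time at which the temperature at `depth` first crosses `threshold` in the
#' stated direction, linearly interpolated between time samples. Returns `NA`
#' (a no-crossing sentinel, not an error) when the threshold is never reached.
#'
#' @param f a [wdr_field][solve_skin_temperature].
#' @param depth depth, m.
#' @param threshold temperature, degC.
#' @param direction `"heating"` (upward crossing) or `"cooling"` (downward).
#' @param after only count crossings at or after this time, s.
#' @return crossing time, s, or `NA_real_`.
#' @export
threshold_crossing_latency <- function(f, depth, threshold,
                                       direction = c("heating", "cooling"),
                                       after = 0) {
  direction <- match.arg(direction)
  tr <- depth_trace(f, depth)
  y <- if (direction == "heating") tr$temp else -tr$temp
  thr <- if (direction == "heating") threshold else -threshold
  idx <- which(tr$time >= after & y > thr)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i > 1 && y[i - 1] < thr) {
    t0 <- tr$time[i - 1]
    t0 + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (tr$time[i] - t0)
  } else {
    tr$time[i]
  }
}

#' Calibrate the skin diffusivity to a target crossing latency
#'
#' Single-scalar fit of the diffusivity so that the modelled temperature at
#' `depth` first reaches `threshold` at `target_latency` after onset of the
#' reference protocol (default: the single hot stimulus, 43 degC at 150 um in
#' 470 ms). Uses the closed-form ramp-superposition solution, so it is fast
#' and grid-free.
#'
#' @param target_latency target crossing time, s.
#' @param threshold threshold temperature, degC.
#' @param depth depth, m.
#' @param p reference protocol.
#' @param interval search interval for the diffusivity, m^2/s.
#' @return calibrated diffusivity, m^2/s.
#' @export
calibrate_diffusivity <- function(target_latency = 0.470, threshold = 43,
                                  depth = 150e-6,
                                  p = protocol_single("hot", 1),
                                  interval = c(1e-8, 1e-6)) {
  cross_at <- function(alpha) {
    sp <- skin_params(diffusivity = alpha)
    resp <- function(t) analytic_protocol_response(p, sp, depth, t)
    tg <- seq(1e-4, p$total_duration, by = 1e-3)
    hit <- which(resp(tg) >= threshold)
    # never crossing within the protocol: penalize so the outer root search
    # is pushed toward larger diffusivities
    if (length(hit) == 0) return(10 * p$total_duration)
    lo <- if (hit[1] > 1) tg[hit[1] - 1] else 1e-6
    stats::uniroot(function(t) resp(t) - threshold, c(lo, tg[hit[1]]),
                   tol = 1e-10)$root
  }
  stats::uniroot(function(a) cross_at(a) - target_latency, interval,
                 tol = 1e-15)$root
}

#' Tidy a solved field into long format
#'
#' @param x a [wdr_field][solve_skin_temperature].
#' @param depths depths to extract, m; default surface and nociceptor depth.
#' @param ... unused.
#' @return a tibble with columns `time`, `depth`, `temp`.
#' @export
tidy.wdr_field <- function(x, depths = NULL, ...) {
  if (is.null(depths)) depths <- c(0, x$params$nociceptor_depth)
  purrr::map_dfr(depths, function(d) {
    dplyr::mutate(depth_trace(x, d), depth = d, .after = "time")
  })
}

#' @export
autoplot.wdr_field <- function(object, depths = NULL, ...) {
  df <- tidy.wdr_field(object, depths)
  df$depth_um <- factor(round(df$depth * 1e6))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$temp,
                                   colour = .data$depth_um)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "temperature (degC)",
                  colour = "depth (um)")
}

#' @export
print.wdr_field <- function(x, ...) {
  cat(sprintf(
    "<wdr_field> %s: %d times x %d depths, alpha = %.4g m^2/s\n",
    x$protocol$name, length(x$time), length(x$depth), x$params$diffusivity
  ))
  invisible(x)
}
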