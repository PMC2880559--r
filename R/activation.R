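#' Simulate the excitation-contraction cascade
#'
#' The lag between electrical stimulation and force-generating activation is
#' modelled as two first-order stages with real poles (calcium release and
#' re-uptake):
#' \deqn{\tau_c \dot c = g u - c, \qquad \tau_a \dot a = c - a,}
#' so a constant stimulus `u` settles at `a = g u` (and `g = 1` here).
#'
#' @param params A [muscle_params()] (only `tau_c`, `tau_a`, `gain` and the
#'   control bounds are used).
#' @param stimulus Either a function of time returning the stimulus in
#'   `[u_min, u_max]`, or a data frame with columns `time_s` and `u`
#'   (zero-order hold between samples).
#' @param initial Named numeric `c(a = , c = )` initial state.
#' @param horizon Duration (s), `> 0`.
#' @param dt Integration/output step (s).
#' @return A tibble with columns `time_s`, `u`, `c`, `a`.
#' @examples
#' m <- muscle_params()
#' tr <- simulate_activation(m, function(t) as.numeric(t < 0.001), horizon = 1)
#' @export
simulate_activation <- function(params, stimulus, initial = c(a = 0, c = 0),
                                horizon, dt = 1e-4) {
  stopifnot(inherits(params, "muscle_params"), horizon > 0, dt > 0)
  n <- ceiling(horizon / dt)
  tt <- seq(0, by = dt, length.out = n + 1)
  u <- sample_stimulus(stimulus, tt)
  if (any(!is.finite(u))) stop("stimulus contains non-finite values")
  if (any(u < params$u_min - 1e-12 | u > params$u_max + 1e-12))
    stop("stimulus violates the control bounds [u_min, u_max]")
  # reuse the coupled-system core with a rigid, force-free configuration:
  # zero force coefficients decouple the load, leaving the pure cascade
  m <- params; m$A <- 0; m$B <- 0; m$C <- 0; m$D <- 0
  pars <- pack_pars(list(m, null_muscle(m)), list(M = 1, b = 1, k = 1))
  z0 <- c(0, 0, initial[["a"]], initial[["c"]], 0, 0)
  out <- ml_sim_states(pars, z0, dt, n, u, numeric(length(u)), dt, 0L, 1L, Inf)
  tibble::tibble(time_s = out[, 1], u = u, c = out[, 5], a = out[, 4])
}

sample_stimulus <- function(stimulus, tt) {
  if (is.function(stimulus)) return(as.numeric(stimulus(tt)))
  if (is.data.frame(stimulus)) {
    stopifnot(all(c("time_s", "u") %in% names(stimulus)))
    idx <- findInterval(tt + 1e-12, stimulus$time_s)
    idx[idx < 1] <- 1
    return(stimulus$u[idx])
  }
  stop("stimulus must be a function of time or a data frame with time_s, u")
}

#' Isometric twitch response to a single brief pulse
#'
#' @param params A [muscle_params()].
#' @param pulse_width Stimulus pulse width (s).
#' @param amplitude Pulse amplitude (defaults to `u_max`).
#' @param horizon Simulated duration (s); defaults to long enough to capture
#'   the decay.
#' @param dt Output step (s).
#' @return A tibble as from [simulate_activation()].
#' @export
twitch_response <- function(params, pulse_width = 1e-3, amplitude = NULL,
                            horizon = NULL, dt = 1e-4) {
  amplitude <- amplitude %||% params$u_max
  horizon <- horizon %||% (10 * max(params$tau_a, params$tau_c))
  simulate_activation(params, function(t) amplitude * (t < pulse_width),
                      horizon = horizon, dt = dt)
}

#' Rise and fall times of a twitch trace
#'
#' Rise time is stimulus onset (t = 0) to the activation peak; fall time is
#' peak to 10% of peak. These definitions are used consistently by
#' [calibrate_activation_params()] and the tests.
#' @param trace A tibble from [twitch_response()].
#' @return Named numeric `c(rise_s = , fall_s = , peak = )`.
#' @export
twitch_times <- function(trace) {
  i <- which.max(trace$a)
  peak <- trace$a[i]
  rise <- trace$time_s[i]
  after <- trace[-seq_len(i - 1), ]
  j <- which(after$a <= 0.1 * peak)[1]
  fall <- if (is.na(j)) NA_real_ else after$time_s[j] - rise
  c(rise_s = rise, fall_s = fall, peak = peak)
}

# closed-form impulse/pulse response machinery for the two-pole cascade -----

# activation response at time t to a unit-amplitude pulse of width w
pulse_response <- function(t, tau_c, tau_a, w) {
  step_resp <- function(t) {
    t <- pmax(t, 0)
    if (abs(tau_c - tau_a) < 1e-9 * tau_a) {
      tau <- 0.5 * (tau_c + tau_a)
      1 - (1 + t / tau) * exp(-t / tau)
    } else {
      1 - (tau_c * exp(-t / tau_c) - tau_a * exp(-t / tau_a)) / (tau_c - tau_a)
    }
  }
  step_resp(t) - step_resp(t - w)
}

pulse_peak_time <- function(tau_c, tau_a, w) {
  stats::optimize(function(t) -pulse_response(t, tau_c, tau_a, w),
                  interval = c(0, w + 12 * max(tau_c, tau_a)),
                  tol = 1e-10)$minimum
}

pulse_fall_time <- function(tau_c, tau_a, w, frac = 0.1) {
  tp <- pulse_peak_time(tau_c, tau_a, w)
  peak <- pulse_response(tp, tau_c, tau_a, w)
  f <- function(t) pulse_response(t, tau_c, tau_a, w) - frac * peak
  upper <- tp + 60 * max(tau_c, tau_a)
  stats::uniroot(f, lower = tp, upper = upper, tol = 1e-12)$root - tp
}

#' Calibrate activation time constants from twitch timing targets
#'
#' Finds `(tau_c, tau_a)` such that the twitch elicited by a single brief
#' pulse has a rise time (onset to peak) matching `target_rise` within 1 ms,
#' and a fall time (peak to 10% of peak) as close to `target_fall` as the
#' two-real-pole family allows. Linearity makes the family time-scale
#' invariant, so the search is over the pole ratio only, with the overall
#' scale pinned by the rise target. Equal poles minimise the fall/rise ratio
#' (about 3.9), so fall targets below `3.9 * target_rise` are infeasible; the
#' best fit (equal poles) is then returned with `feasible = FALSE` and a
#' warning.
#'
#' @param target_rise,target_fall Timing targets (s), `> 0`. `target_fall`
#'   may be `NULL` to request the equal-pole solution matching the rise only.
#' @param pulse_width Stimulus pulse width used in the calibration (s).
#' @return A list with `tau_c`, `tau_a`, `rise_s`, `fall_s`,
#'   `fall_residual_s`, `feasible`.
#' @export
calibrate_activation_params <- function(target_rise, target_fall = NULL,
                                        pulse_width = 1e-3) {
  stopifnot(target_rise > 0, is.null(target_fall) || target_fall > 0)
  # scale-solve: for a pole ratio r = tau_c/tau_a (<= 1 wlog), find tau_a
  # with peak time = target_rise (monotone in tau_a)
  scale_for_rise <- function(r) {
    g <- function(tau_a) pulse_peak_time(r * tau_a, tau_a, pulse_width) - target_rise
    stats::uniroot(g, lower = 1e-4 * target_rise, upper = 5 * target_rise,
                   tol = 1e-12)$root
  }
  fall_at <- function(r) {
    tau_a <- scale_for_rise(r)
    pulse_fall_time(r * tau_a, tau_a, pulse_width)
  }
  if (is.null(target_fall)) {
    r_best <- 1
  } else {
    obj <- function(r) abs(fall_at(r) - target_fall)
    opt <- stats::optimize(obj, interval = c(0.02, 1), tol = 1e-6)
    # equal poles live on the boundary of the search interval; compare
    r_best <- if (obj(1) <= opt$objective + 1e-12) 1 else opt$minimum
  }
  tau_a <- scale_for_rise(r_best)
  tau_c <- r_best * tau_a
  rise <- pulse_peak_time(tau_c, tau_a, pulse_width)
  fall <- pulse_fall_time(tau_c, tau_a, pulse_width)
  feasible <- is.null(target_fall) || abs(fall - target_fall) < 1e-3
  if (!feasible)
    warning(sprintf(paste0("fall-time target %.1f ms is unreachable for a ",
                           "two-real-pole cascade with rise %.1f ms; best ",
                           "achievable fall is %.1f ms"),
                    1e3 * target_fall, 1e3 * target_rise, 1e3 * fall),
            call. = FALSE)
  list(tau_c = tau_c, tau_a = tau_a, rise_s = rise, fall_s = fall,
       fall_residual_s = if (is.null(target_fall)) 0 else fall - target_fall,
       feasible = feasible)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
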