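#' Build a workloop from force and displacement traces
#'
#' A workloop is the closed curve traced by muscle (or net) force against
#' displacement over one oscillation cycle; its signed area is the net
#' mechanical work done per cycle, positive when the loop runs
#' counter-clockwise (force leading shortening). Cycles are segmented by the
#' known stimulus period rather than by zero crossings, which is robust to
#' offsets.
#'
#' @param traj A data frame with `time_s` plus force/displacement columns, or
#'   an `ml_trajectory`.
#' @param freq Cycle frequency (Hz); defaults to the frequency stored on an
#'   `ml_trajectory`.
#' @param force,displacement Column names to use.
#' @return An `ml_workloop` tibble: `cycle`, `time_s`, `x_m`, `F_N`, with
#'   attribute `freq`.
#' @export
workloop <- function(traj, freq = NULL, force = "Fnet_N",
                     displacement = "x_m") {
  freq <- freq %||% attr(traj, "freq")
  if (is.null(freq)) stop("cycle frequency needed to segment workloop cycles")
  stopifnot(all(c("time_s", force, displacement) %in% names(traj)))
  Tp <- 1 / freq
  wl <- tibble::tibble(
    cycle = floor(traj$time_s / Tp * (1 - 1e-12)) + 1L,
    time_s = traj$time_s,
    x_m = traj[[displacement]],
    F_N = traj[[force]])
  structure(wl, class = c("ml_workloop", class(wl)), freq = freq)
}

#' Cyclic work and mean power of a workloop
#'
#' Signed trapezoidal shoelace area per cycle, `W = closed integral of F dx`;
#' positive work means the loop is traversed counter-clockwise in the
#' force-displacement plane (the muscle does net work on the load). Cycles
#' that fail to close within 1% of their force or displacement excursion are
#' warned about and excluded from the averages.
#'
#' @param loop An `ml_workloop`, or anything [workloop()] accepts (then
#'   `freq` etc. are forwarded).
#' @param require_closed Exclude open cycles from the averages (with a
#'   warning)? Set `FALSE` for from-rest recordings whose early cycles
#'   legitimately fail to close (closure is still reported per cycle).
#' @param ... Passed to [workloop()] when `loop` is a raw trajectory.
#' @return A list with per-cycle tibble `cycles` (`cycle`, `work_J`,
#'   `mean_power_W`, `closed`), and scalars `work_J`, `mean_power_W`
#'   (means over the retained cycles).
#' @export
cyclic_work <- function(loop, require_closed = TRUE, ...) {
  if (!inherits(loop, "ml_workloop")) loop <- workloop(loop, ...)
  freq <- attr(loop, "freq")
  per_cycle <- function(d) {
    # close the polygon explicitly
    x <- c(d$x_m, d$x_m[1]); f <- c(d$F_N, d$F_N[1])
    W <- sum(diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
    gap_x <- abs(d$x_m[nrow(d)] - d$x_m[1])
    gap_f <- abs(d$F_N[nrow(d)] - d$F_N[1])
    exc_x <- max(d$x_m) - min(d$x_m)
    exc_f <- max(d$F_N) - min(d$F_N)
    closed <- gap_x <= 0.01 * max(exc_x, .Machine$double.eps) &&
      gap_f <= 0.01 * max(exc_f, .Machine$double.eps)
    tibble::tibble(work_J = W, mean_power_W = W * freq, closed = closed)
  }
  cycles <- loop |>
    dplyr::group_by(.data$cycle) |>
    dplyr::group_modify(~ per_cycle(.x)) |>
    dplyr::ungroup()
  if (require_closed && any(!cycles$closed))
    warning(sprintf("%d open workloop cycle(s) excluded from averages",
                    sum(!cycles$closed)), call. = FALSE)
  ok <- if (require_closed) cycles$closed else rep(TRUE, nrow(cycles))
  if (!any(ok)) stop("no closed workloop cycles")
  list(cycles = cycles,
       work_J = mean(cycles$work_J[ok]),
       mean_power_W = mean(cycles$mean_power_W[ok]))
}

#' Energy dissipated in the load damper per cycle
#'
#' `integral of b v^2 dt` over each cycle. Over an exact steady-state cycle
#' the stored energy change is zero, so this equals the cyclic muscle work.
#'
#' @param traj An `ml_trajectory` (needs `time_s`, `v_m_s`).
#' @param load A [load_params()]; defaults to the one stored on `traj`.
#' @param freq Cycle frequency (Hz); defaults to the stored one.
#' @return A tibble with `cycle` and `dissipation_J`.
#' @export
damper_dissipation <- function(traj, load = NULL, freq = NULL) {
  load <- load %||% attr(traj, "load")
  freq <- freq %||% attr(traj, "freq")
  stopifnot(inherits(load, "load_params"), !is.null(freq))
  Tp <- 1 / freq
  d <- tibble::tibble(time_s = traj$time_s,
                      p = load$b * traj$v_m_s^2,
                      cycle = floor(traj$time_s / Tp * (1 - 1e-12)) + 1L)
  d |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(dissipation_J = trapz(.data$time_s, .data$p),
                     .groups = "drop")
}

#' Synergy ratio of a paired-versus-single work measurement
#'
#' `S = W12 / (W1 + W2)`: cyclic work of the pair acting in concert over the
#' sum of the works of the two muscles acting individually on the same load.
#' Constant-impedance (force-source) actuators give `S <= 2`; values above 2
#' require activation-dependent impedance.
#'
#' @param W1,W2 Individual cyclic works (J), or a data frame with columns
#'   `W1`, `W2`, `W12` as the first argument.
#' @param W12 Joint cyclic work (J).
#' @return Numeric ratio(s) `S`.
#' @export
synergy_ratio <- function(W1, W2 = NULL, W12 = NULL) {
  if (is.data.frame(W1)) {
    stopifnot(all(c("W1", "W2", "W12") %in% names(W1)))
    return(synergy_ratio(W1$W1, W1$W2, W1$W12))
  }
  if (any(!is.finite(c(W1, W2, W12)))) stop("works must be finite")
  if (any(W1 + W2 <= 0))
    stop("synergy ratio undefined: W1 + W2 must be positive")
  W12 / (W1 + W2)
}

#' Impedance-matched source stiffness
#'
#' For a purely reactive (stiffness-dominated) source driving the load at
#' angular frequency `omega`, maximum power transfer requires the source
#' reactance to cancel the load reactance: `k_s/omega = M omega - k/omega`,
#' i.e. `k_s = M omega^2 - k`. The combined natural frequency
#' `sqrt((k + k_s)/M)/(2 pi)` then equals the drive frequency. Below the load
#' resonance the required stiffness would be negative; since activation can
#' only add stiffness in this model, `k_s` is clamped at zero and flagged.
#'
#' @param load A [load_params()].
#' @param omega Angular drive frequency(ies), rad/s, `> 0`.
#' @return A tibble with `omega`, `k_s_N_m`, `combined_f_n_Hz`, `clamped`.
#' @export
matched_stiffness <- function(load, omega) {
  stopifnot(inherits(load, "load_params"), all(omega > 0))
  ks <- load$M * omega^2 - load$k
  clamped <- ks < 0
  ks[clamped] <- 0
  tibble::tibble(omega = omega, k_s_N_m = ks,
                 combined_f_n_Hz = sqrt((load$k + ks) / load$M) / (2 * pi),
                 clamped = clamped)
}

#' Normalised power table across measurement sets
#'
#' Each measurement set contains one power measurement per test frequency;
#' powers are normalised within each set by the measurement at the load
#' natural frequency, so `P_hat(f_n) = 1` with zero variance by construction
#' while the other frequencies carry dispersion across sets. One-sample
#' two-sided t-tests compare each frequency's normalised power against 1.
#'
#' @param measurements A data frame with columns `set_id`, `freq_Hz`,
#'   `power_W` (one row per measurement).
#' @param f_n The normalising frequency (Hz), present in every set.
#' @return A list with `measurements` (input plus `normalized_power`),
#'   `summary` (per-frequency mean, sd, n, t, p, stars), `excluded_sets`.
#' @export
normalized_power_table <- function(measurements, f_n) {
  stopifnot(all(c("set_id", "freq_Hz", "power_W") %in% names(measurements)))
  norm_one <- function(d) {
    i <- which(abs(d$freq_Hz - f_n) < 1e-9)
    if (length(i) != 1 || d$power_W[i] <= 0) {
      d$normalized_power <- NA_real_
      return(d)
    }
    d$normalized_power <- d$power_W / d$power_W[i]
    d
  }
  out <- measurements |>
    dplyr::group_by(.data$set_id) |>
    dplyr::group_modify(~ norm_one(.x)) |>
    dplyr::ungroup()
  excluded <- unique(out$set_id[is.na(out$normalized_power)])
  if (length(excluded) > 0)
    warning(sprintf("%d set(s) without a positive P(f_n) normaliser excluded",
                    length(excluded)), call. = FALSE)
  ok <- !is.na(out$normalized_power)
  summary <- out[ok, ] |>
    dplyr::group_by(freq_Hz = .data$freq_Hz) |>
    dplyr::summarise(
      mean = mean(.data$normalized_power),
      sd = stats::sd(.data$normalized_power),
      n = dplyr::n(), .groups = "drop")
  tests <- lapply(seq_len(nrow(summary)), function(i) {
    s <- out$normalized_power[ok & abs(out$freq_Hz - summary$freq_Hz[i]) < 1e-9]
    compare_ratio_test(s, 1)
  })
  summary$t <- vapply(tests, `[[`, numeric(1), "t")
  summary$p <- vapply(tests, `[[`, numeric(1), "p")
  summary$stars <- vapply(tests, `[[`, character(1), "stars")
  list(measurements = out, summary = summary, excluded_sets = excluded)
}
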