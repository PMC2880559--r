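# Emulated virtual-load experiments: stimulation waveforms, workloop
# sessions with measurement noise and fatigue drift, identification-dataset
# synthesis, and the two hypothesis protocols.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Periodic stimulation waveform
#'
#' Builds the electrical stimulus delivered to each muscle: within the active
#' burst windows of each oscillation cycle, unit-amplitude pulses at
#' `pulse_rate` (200 Hz by default, ensuring full recruitment) with width
#' `pulse_width` (100 microseconds by default); zero elsewhere; exactly
#' periodic at the oscillation frequency.
#'
#' @param freq Oscillation (waveform repetition) frequency, Hz.
#' @param burst_windows List of one or two elements (agonist, antagonist);
#'   each a 2-column matrix of phase intervals `[start, end)` in radians
#'   within `[0, 2 pi)`. Overlapping windows for one muscle are merged with a
#'   warning. An interval with `end > 2 pi` wraps.
#' @param pulse_rate Pulse rate within bursts, Hz.
#' @param pulse_width Pulse width, s. Must satisfy
#'   `pulse_rate * pulse_width < 1`.
#' @param amplitude Normalised stimulus amplitude (1 = full recruitment).
#' @param dt Sample step of the stored waveform, s (defaults to half the
#'   pulse width so every pulse is resolved).
#' @return A `stim_waveform`: list with `freq`, `dt`, `time_s`, `u1`, `u2`
#'   (one period, zero-order hold) and the generating settings.
#' @export
generate_stim_waveform <- function(freq, burst_windows, pulse_rate = 200,
                                   pulse_width = 1e-4, amplitude = 1,
                                   dt = NULL) {
  stopifnot(freq > 0, pulse_rate > 0, pulse_width > 0)
  if (pulse_rate * pulse_width >= 1)
    stop("pulse_rate * pulse_width must be < 1 (non-overlapping pulses)")
  if (!is.list(burst_windows)) burst_windows <- list(burst_windows)
  if (length(burst_windows) == 1) burst_windows <- c(burst_windows, list(NULL))
  stopifnot(length(burst_windows) == 2)
  dt <- dt %||% (pulse_width / 2)
  Tp <- 1 / freq
  n <- max(2L, round(Tp / dt))
  dt <- Tp / n   # exact periodicity on the sample grid
  tt <- seq(0, by = dt, length.out = n)
  channel <- function(win) {
    u <- numeric(n); env <- numeric(n)
    if (is.null(win) || length(win) == 0)
      return(list(pulses = u, envelope = env))
    win <- matrix(as.numeric(win), ncol = 2)
    if (any(win[, 1] < 0 | win[, 1] >= 2 * pi | win[, 2] <= win[, 1]))
      stop("burst windows must be [start, end) with start in [0, 2 pi), end > start")
    win <- win[order(win[, 1]), , drop = FALSE]
    if (nrow(win) > 1 && any(win[-nrow(win), 2] > win[-1, 1])) {
      warning("overlapping burst windows merged", call. = FALSE)
      merged <- win[1, , drop = FALSE]
      for (i in seq_len(nrow(win))[-1]) {
        if (win[i, 1] <= merged[nrow(merged), 2])
          merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], win[i, 2])
        else merged <- rbind(merged, win[i, ])
      }
      win <- merged
    }
    period_pulse <- 1 / pulse_rate
    for (i in seq_len(nrow(win))) {
      t0 <- win[i, 1] / (2 * pi) * Tp
      t1 <- win[i, 2] / (2 * pi) * Tp
      ei <- which(tt >= t0 - 1e-12 & tt < t1 - 1e-12)
      env[(ei - 1L) %% n + 1L] <- amplitude
      onsets <- seq(t0, t1 - 1e-12, by = period_pulse)
      onsets <- onsets[onsets + pulse_width <= t1 + 1e-12]
      for (on in onsets) {
        idx <- which(tt >= on - 1e-12 & tt < on + pulse_width - 1e-12)
        u[(idx - 1L) %% n + 1L] <- amplitude
      }
    }
    list(pulses = u, envelope = env)
  }
  ch1 <- channel(burst_windows[[1]]); ch2 <- channel(burst_windows[[2]])
  structure(list(freq = freq, dt = dt, time_s = tt,
                 u1 = ch1$pulses, u2 = ch2$pulses,
                 env1 = ch1$envelope, env2 = ch2$envelope,
                 burst_windows = burst_windows, pulse_rate = pulse_rate,
                 pulse_width = pulse_width, amplitude = amplitude),
            class = "stim_waveform")
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> %.4g Hz, %d samples/period (dt = %.3g s), pulses %g Hz x %g s\n",
              x$freq, length(x$u1), x$dt, x$pulse_rate, x$pulse_width))
  invisible(x)
}

# periodic zero-order-hold lookup functions for both channels. The model is
# driven by the recruitment envelope: the 200 Hz pulse train within a burst
# fuses to a tetanic (fully recruited) drive, which the unity-gain cascade
# represents as a constant input over the burst.
stim_functions <- function(wf, channel = c("envelope", "pulses")) {
  channel <- match.arg(channel)
  Tp <- 1 / wf$freq
  n <- length(wf$u1)
  make <- function(u) {
    force(u)
    function(t) u[(floor((t %% Tp) / wf$dt + 1e-9) %% n) + 1L]
  }
  if (channel == "envelope") list(make(wf$env1), make(wf$env2))
  else list(make(wf$u1), make(wf$u2))
}

#' Continuous burst windows without a pulse substructure
#'
#' Convenience constructor of burst-window matrices: a single window of the
#' given duty per muscle, antiphase by default.
#' @param duty Burst duration as a fraction of the cycle.
#' @param phase1,phase2 Burst onset phases (fractions of the cycle);
#'   `phase2 = NULL` places the antagonist burst half a cycle after the
#'   agonist.
#' @param single Omit the antagonist channel?
#' @return A list of window matrices suitable for
#'   [generate_stim_waveform()].
#' @export
burst_windows <- function(duty = 0.4, phase1 = 0, phase2 = NULL,
                          single = FALSE) {
  phase2 <- phase2 %||% (phase1 + 0.5)
  w <- function(ph) matrix(2 * pi * c(ph %% 1, ph %% 1 + duty), ncol = 2)
  list(w(phase1), if (single) NULL else w(phase2))
}

#' Burst windows from an optimal-control solution
#'
#' Thresholds the solved control traces at the midpoint of the control bounds
#' and converts the saturated-on segments into phase intervals, i.e. the
#' stimulation schedule the emulated experiments replay (quantised to the
#' pulse grid by [generate_stim_waveform()]).
#' @param sol An `ml_ocp_solution`.
#' @return A list of two window matrices (antagonist `NULL` for single-muscle
#'   problems).
#' @export
burst_windows_from_solution <- function(sol) {
  stopifnot(inherits(sol, "ml_ocp_solution"), !is.null(sol$trajectory))
  tr <- sol$trajectory
  Tp <- sol$problem$T
  one <- function(u, m) {
    on <- u > (m$u_min + m$u_max) / 2
    if (!any(on)) return(NULL)
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ph <- cbind(tr$time_s[starts[r$values]] / Tp,
                tr$time_s[pmin(ends[r$values] + 1, nrow(tr))] / Tp)
    matrix(2 * pi * pmin(pmax(ph, 0), 1 - 1e-9), ncol = 2)
  }
  m1 <- sol$problem$muscles[[1]]; m2 <- sol$problem$muscles[[2]]
  list(one(tr$u1, m1),
       if (is_null_muscle(m2)) NULL else one(tr$u2, m2))
}

#' Session configuration for emulated workloop experiments
#'
#' @param load A [load_params()].
#' @param muscles A [muscle_params()] or list of two.
#' @param frequencies Test frequencies (Hz).
#' @param reps Measurement sets per condition (>= 2 for any statistics).
#' @param cycles Oscillation cycles recorded per measurement.
#' @param discard_first Drop the first (from-rest, atypical) cycle from the
#'   energetic averages?
#' @param force_noise_sd Measurement noise SD on recorded muscle forces (N);
#'   `NULL` = 2% of the peak noiseless net force of each measurement.
#' @param pos_noise_sd Measurement noise SD on recorded position (m); `NULL`
#'   = 0.1% of the noiseless excursion.
#' @param fatigue_rate Per-measurement multiplicative decay of the active
#'   force coefficients (0.01 = 1% per measurement, chronological).
#' @param seed RNG seed recorded in all outputs.
#' @return An `ml_session_config`.
#' @export
session_config <- function(load, muscles, frequencies, reps = 6, cycles = 7,
                           discard_first = TRUE, force_noise_sd = NULL,
                           pos_noise_sd = NULL, fatigue_rate = 0.01,
                           seed = 1) {
  stopifnot(inherits(load, "load_params"), reps >= 2, cycles >= 2)
  if (!is.null(force_noise_sd) && force_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (!is.null(pos_noise_sd) && pos_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (fatigue_rate < 0 || fatigue_rate >= 1)
    stop("fatigue_rate must be in [0, 1)")
  structure(list(load = load, muscles = as_muscle_pair(muscles),
                 frequencies = frequencies, reps = reps, cycles = cycles,
                 discard_first = discard_first,
                 force_noise_sd = force_noise_sd,
                 pos_noise_sd = pos_noise_sd,
                 fatigue_rate = fatigue_rate, seed = seed),
            class = "ml_session_config")
}

fatigued_muscles <- function(muscles, scale) {
  lapply(muscles, function(m) {
    # fatigue attenuates active force generation, not the passive tissue
    m$C <- m$C * scale
    m$D <- m$D * scale
    m
  })
}

# one emulated measurement: integrate the coupled system under the waveform,
# then corrupt the recorded channels
emulate_measurement <- function(cfg, wf, fatigue_scale = 1, mute = c(FALSE, FALSE)) {
  muscles <- fatigued_muscles(cfg$muscles, fatigue_scale)
  for (i in 1:2) if (mute[i]) muscles[[i]] <- null_muscle(muscles[[i]])
  horizon <- cfg$cycles / wf$freq
  truth <- simulate_coupled_system(muscles, cfg$load, wf, horizon = horizon,
                                   record_dt = max(wf$dt, 1 / (400 * wf$freq)),
                                   freq = wf$freq)
  rec <- truth
  f_sd <- cfg$force_noise_sd %||% (0.02 * max(abs(truth$Fnet_N)))
  x_sd <- cfg$pos_noise_sd %||% (0.001 * (max(truth$x_m) - min(truth$x_m)))
  n <- nrow(rec)
  if (f_sd > 0) {
    rec$F1_N <- rec$F1_N + stats::rnorm(n, 0, f_sd)
    if (!is_null_muscle(muscles[[2]]))
      rec$F2_N <- rec$F2_N + stats::rnorm(n, 0, f_sd)
    rec$Fnet_N <- rec$F1_N - rec$F2_N
  }
  if (x_sd > 0) rec$x_m <- rec$x_m + stats::rnorm(n, 0, x_sd)
  attr(rec, "truth") <- truth
  rec
}

measure_power <- function(rec, freq, discard_first = TRUE) {
  cw <- cyclic_work(workloop(rec, freq = freq), require_closed = FALSE)
  keep <- if (discard_first) cw$cycles$cycle > 1 else rep(TRUE, nrow(cw$cycles))
  keep <- keep & !is.na(cw$cycles$work_J)
  list(work_J = mean(cw$cycles$work_J[keep]),
       power_W = mean(cw$cycles$work_J[keep]) * freq)
}

#' Emulate a full workloop session
#'
#' Repeats a stimulation condition `reps` times against the emulated
#' mass-spring-damper load. Each repetition integrates the coupled system
#' exactly as [simulate_coupled_system()] (ground truth retained as an
#' attribute of each recording), then adds Gaussian measurement noise to the
#' recorded force and position channels and applies the cumulative fatigue
#' scale to the contractile (not passive) force coefficients.
#'
#' @param cfg An [session_config()].
#' @param stim A [generate_stim_waveform()] object (its frequency defines the
#'   condition).
#' @return A list with `recordings` (list of noisy `ml_trajectory`s, truth in
#'   `attr(, "truth")`), `measurements` (tibble `rep`, `work_J`, `power_W`),
#'   `seed`.
#' @export
emulate_workloop_session <- function(cfg, stim) {
  stopifnot(inherits(cfg, "ml_session_config"), inherits(stim, "stim_waveform"))
  with_seed(cfg$seed, {
    recs <- vector("list", cfg$reps)
    meas <- vector("list", cfg$reps)
    for (r in seq_len(cfg$reps)) {
      scale <- (1 - cfg$fatigue_rate)^(r - 1)
      recs[[r]] <- emulate_measurement(cfg, stim, scale)
      p <- measure_power(recs[[r]], stim$freq, cfg$discard_first)
      meas[[r]] <- tibble::tibble(rep = r, work_J = p$work_J,
                                  power_W = p$power_W)
    }
    list(recordings = recs, measurements = dplyr::bind_rows(meas),
         seed = cfg$seed)
  })
}

#' One-sample ratio comparison against a threshold
#'
#' Two-sided one-sample t-test of the per-set ratios (or normalised powers)
#' against the stated threshold, annotated with the significance stars used
#' throughout: `**` for p < 0.01, `*` for p < 0.05.
#'
#' @param samples Numeric vector, `n >= 2`.
#' @param threshold Null value.
#' @return A list with `t`, `p`, `stars`, `mean`, `sd`, `n`,
#'   `degenerate_variance`.
#' @export
compare_ratio_test <- function(samples, threshold) {
  stopifnot(length(samples) >= 2)
  if (stats::sd(samples) <= 1e-12 * max(abs(mean(samples)), 1)) {
    exact <- abs(samples[1] - threshold) <= 1e-12 * max(abs(threshold), 1)
    return(list(t = if (exact) 0 else Inf * sign(samples[1] - threshold),
                p = if (exact) 1 else 0,
                stars = if (exact) "" else "**",
                mean = mean(samples), sd = 0, n = length(samples),
                degenerate_variance = TRUE))
  }
  tt <- stats::t.test(samples, mu = threshold)
  p <- tt$p.value
  list(t = unname(tt$statistic), p = p,
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
       mean = mean(samples), sd = stats::sd(samples), n = length(samples),
       degenerate_variance = FALSE)
}

protocol_schedules <- function(cfg, freqs, stim_source, schedules, single,
                               pulse_rate, pulse_width) {
  if (!is.null(schedules)) {
    stopifnot(length(schedules) == length(freqs))
    return(schedules)
  }
  lapply(freqs, function(f) {
    if (stim_source == "optimal") {
      mus <- if (single) cfg$muscles[[1]] else cfg$muscles
      sol <- suppressWarnings(
        solve_cyclic_optimal_control(ocp(mus, cfg$load, f)))
      if (isTRUE(sol$converged) && !isTRUE(sol$trivial))
        return(burst_windows_from_solution(sol))
      warning(sprintf(paste0("optimal-control schedule unavailable at %g Hz ",
                             "(solver did not converge); using heuristic ",
                             "bursts"), f), call. = FALSE)
    }
    burst_windows(duty = 0.4, single = single)
  })
}

#' Hypothesis 1 protocol: single-muscle power across three frequencies
#'
#' Emulates the virtual-load comparison of single-muscle power output at the
#' load natural frequency `f_n`, the model-predicted optimum `f_opt`, and a
#' distinctly higher `f_high`. Conditions are measured in randomised order
#' within each set (to decorrelate the slow fatigue drift from condition),
#' powers are averaged over the recorded cycles with the first discarded,
#' and each set is normalised by its own `P(f_n)`.
#'
#' @param cfg An [session_config()] whose `frequencies` are
#'   `c(f_n, f_opt, f_high)` in increasing order, with
#'   `frequencies[1] = load f_n`.
#' @param stim_source `"optimal"` derives each frequency's burst schedule
#'   from the cyclic optimal control solution; `"heuristic"` uses fixed
#'   antiphase 40%-duty bursts.
#' @param schedules Optional list of precomputed burst-window lists, one per
#'   frequency (overrides `stim_source`).
#' @param pulse_rate,pulse_width Stimulation pulse train settings.
#' @return An `ml_protocol`: list with `measurements` (tibble `set_id`,
#'   `order`, `freq_Hz`, `work_J`, `power_W`, `normalized_power`), `table`
#'   (from [normalized_power_table()]), `tests` (`P(f_opt) vs 1` and
#'   `P(f_opt) vs P(f_high)` paired comparison), `config`, `seed`.
#' @export
run_hypothesis1_protocol <- function(cfg, stim_source = c("optimal", "heuristic"),
                                     schedules = NULL, pulse_rate = 200,
                                     pulse_width = 1e-4) {
  stopifnot(inherits(cfg, "ml_session_config"), length(cfg$frequencies) == 3)
  stim_source <- match.arg(stim_source)
  freqs <- cfg$frequencies
  if (!(freqs[1] < freqs[2] && freqs[2] < freqs[3]))
    stop("frequencies must be increasing: c(f_n, f_opt, f_high)")
  sched <- protocol_schedules(cfg, freqs, stim_source, schedules,
                              single = is_null_muscle(cfg$muscles[[2]]),
                              pulse_rate, pulse_width)
  wfs <- lapply(seq_along(freqs), function(i)
    generate_stim_waveform(freqs[i], sched[[i]], pulse_rate, pulse_width))
  with_seed(cfg$seed, {
    rows <- list()
    m_idx <- 0
    for (s in seq_len(cfg$reps)) {
      ord <- sample(seq_along(freqs))
      for (pos in seq_along(ord)) {
        i <- ord[pos]
        m_idx <- m_idx + 1
        scale <- (1 - cfg$fatigue_rate)^(m_idx - 1)
        rec <- emulate_measurement(cfg, wfs[[i]], scale)
        p <- measure_power(rec, freqs[i], cfg$discard_first)
        rows[[m_idx]] <- tibble::tibble(
          set_id = s, order = pos, freq_Hz = freqs[i],
          work_J = p$work_J, power_W = p$power_W)
      }
    }
    meas <- dplyr::bind_rows(rows)
    tab <- normalized_power_table(meas, f_n = freqs[1])
    np <- tab$measurements
    p_opt <- np$normalized_power[abs(np$freq_Hz - freqs[2]) < 1e-9]
    p_high <- np$normalized_power[abs(np$freq_Hz - freqs[3]) < 1e-9]
    tests <- list(
      opt_vs_1 = compare_ratio_test(p_opt, 1),
      opt_vs_high = compare_ratio_test(p_opt - p_high, 0))
    structure(list(measurements = tab$measurements, table = tab$summary,
                   tests = tests, schedules = sched, config = cfg,
                   seed = cfg$seed, hypothesis = "H1",
                   config_hash = rlang::hash(cfg)),
              class = "ml_protocol")
  })
}

#' Hypothesis 2 protocol: synergy of an antagonist pair at one frequency
#'
#' Emulates paired measurements of `W1` (agonist only), `W2` (antagonist
#' only) and `W12` (both in concert) on the same load, in randomised order
#' per set, and computes the synergy ratio `S = W12/(W1 + W2)` per set with a
#' one-sample test against the impedance-free value 2. The antagonist is a
#' contralateral muscle: its parameters equal the agonist's times
#' `(1 + epsilon)`, `epsilon ~ N(0, pair_cv^2)`, drawn from the session
#' seed.
#'
#' @param cfg An [session_config()]; its `muscles` supply the agonist (the
#'   antagonist entry is regenerated unless `pair_cv = 0`).
#' @param freq Oscillation frequency (Hz).
#' @param pair_cv Contralateral variability coefficient (default 0.05).
#' @param stim_source,schedules,pulse_rate,pulse_width As in
#'   [run_hypothesis1_protocol()]; `schedules` here is a list of two burst
#'   window lists (single-muscle, pair).
#' @return An `ml_protocol` with per-set `measurements` (`W1`, `W2`, `W12`,
#'   `S`), `tests$S_vs_2`, `config`, `seed`.
#' @export
run_hypothesis2_protocol <- function(cfg, freq, pair_cv = 0.05,
                                     stim_source = c("optimal", "heuristic"),
                                     schedules = NULL, pulse_rate = 200,
                                     pulse_width = 1e-4) {
  stopifnot(inherits(cfg, "ml_session_config"), freq > 0)
  stim_source <- match.arg(stim_source)
  with_seed(cfg$seed, {
    if (pair_cv > 0) {
      eps <- stats::rnorm(1, 0, pair_cv)
      ant <- cfg$muscles[[1]]
      for (f in c("A", "B", "C", "D")) ant[[f]] <- ant[[f]] * (1 + eps)
      cfg$muscles[[2]] <- ant
    }
    if (is.null(schedules)) {
      schedules <- list(burst_windows(duty = 0.4, single = TRUE),
                        burst_windows(duty = 0.4))
      if (stim_source == "optimal") {
        sol1 <- suppressWarnings(
          solve_cyclic_optimal_control(ocp(cfg$muscles[[1]], cfg$load, freq)))
        sol12 <- suppressWarnings(
          solve_cyclic_optimal_control(ocp(cfg$muscles, cfg$load, freq)))
        if (isTRUE(sol1$converged) && !isTRUE(sol1$trivial))
          schedules[[1]] <- burst_windows_from_solution(sol1)
        else warning("single-muscle optimal schedule unavailable; heuristic bursts used",
                     call. = FALSE)
        if (isTRUE(sol12$converged) && !isTRUE(sol12$trivial))
          schedules[[2]] <- burst_windows_from_solution(sol12)
        else warning("pair optimal schedule unavailable; heuristic bursts used",
                     call. = FALSE)
      }
    }
    wf_single <- generate_stim_waveform(freq, schedules[[1]], pulse_rate,
                                        pulse_width)
    wf_pair <- generate_stim_waveform(freq, schedules[[2]], pulse_rate,
                                      pulse_width)
    # antagonist-only: mirror the single-muscle schedule onto channel 2
    wf_anta <- generate_stim_waveform(freq, list(NULL, schedules[[1]][[1]]),
                                      pulse_rate, pulse_width)
    conds <- c("agonist", "antagonist", "both")
    rows <- list()
    m_idx <- 0
    for (s in seq_len(cfg$reps)) {
      ord <- sample(conds)
      W <- c(agonist = NA_real_, antagonist = NA_real_, both = NA_real_)
      for (cond in ord) {
        m_idx <- m_idx + 1
        scale <- (1 - cfg$fatigue_rate)^(m_idx - 1)
        rec <- switch(cond,
          agonist = emulate_measurement(cfg, wf_single, scale,
                                        mute = c(FALSE, TRUE)),
          antagonist = emulate_measurement(cfg, wf_anta, scale,
                                           mute = c(TRUE, FALSE)),
          both = emulate_measurement(cfg, wf_pair, scale))
        W[cond] <- measure_power(rec, freq, cfg$discard_first)$work_J
      }
      rows[[s]] <- tibble::tibble(
        set_id = s, order = paste(ord, collapse = ","),
        W1 = W[["agonist"]], W2 = W[["antagonist"]], W12 = W[["both"]])
    }
    meas <- dplyr::bind_rows(rows)
    valid <- meas$W1 + meas$W2 > 0
    if (any(!valid))
      warning(sprintf("%d set(s) with non-positive W1 + W2 excluded",
                      sum(!valid)), call. = FALSE)
    meas$S <- NA_real_
    if (any(valid))
      meas$S[valid] <- synergy_ratio(meas$W1[valid], meas$W2[valid],
                                     meas$W12[valid])
    tests <- if (sum(valid) >= 2) {
      list(S_vs_2 = compare_ratio_test(meas$S[valid], 2))
    } else {
      warning("fewer than 2 valid sets: synergy test not computed", call. = FALSE)
      list(S_vs_2 = list(t = NA_real_, p = NA_real_, stars = "",
                         mean = mean(meas$S[valid]), sd = NA_real_,
                         n = sum(valid), degenerate_variance = FALSE))
    }
    structure(list(measurements = meas, tests = tests, freq = freq,
                   schedules = schedules, config = cfg, seed = cfg$seed,
                   hypothesis = "H2", config_hash = rlang::hash(cfg)),
              class = "ml_protocol")
  })
}

#' @export
print.ml_protocol <- function(x, ...) {
  cat(sprintf("<ml_protocol> %s, %d sets (seed %s)\n", x$hypothesis,
              max(x$measurements$set_id), format(x$seed)))
  if (x$hypothesis == "H1") {
    print(x$table)
    t1 <- x$tests$opt_vs_1
    cat(sprintf("  P(f_opt) vs 1: mean %.3f, t = %.3g, p = %.3g %s\n",
                t1$mean, t1$t, t1$p, t1$stars))
  } else {
    s <- x$tests$S_vs_2
    cat(sprintf("  S = W12/(W1+W2): mean %.3f +/- %.3f, vs 2: t = %.3g, p = %.3g %s\n",
                s$mean, s$sd, s$t, s$p, s$stars))
  }
  invisible(x)
}

#' Synthesise an identification dataset
#'
#' Emulates the model-identification experiments: sinusoidal length
#' trajectories are imposed on the muscle (motion-source mode, so the motion
#' is independent of contractile force) over a grid of frequencies and
#' amplitudes, short pulse-train bursts are triggered at fixed phases of each
#' oscillation, the activation regressor is estimated by convolving the
#' stimulus with the unity-gain twitch response (for this linear cascade the
#' estimate coincides with the true activation state), and force samples
#' come from the bilinear model plus optional velocity terms and Gaussian
#' noise.
#'
#' @param muscle A [muscle_params()].
#' @param frequencies Imposed oscillation frequencies (Hz), `>= 2` values.
#' @param amplitudes Oscillation amplitudes (m), `>= 2` values.
#' @param trigger_phases Stimulation trigger phases (rad) within each cycle.
#' @param noise_sd Gaussian force noise SD (N).
#' @param velocity_terms Named numeric `c(B_v = , D_v = )` adding
#'   `B_v v + D_v a v` to the generated force (to probe the term-reduction
#'   claim).
#' @param cycles Cycles per (frequency, amplitude) combination.
#' @param burst_duration Burst length at each trigger (s).
#' @param sample_rate Output sample rate (Hz).
#' @param seed RNG seed for the noise.
#' @return A tibble with `time_s`, `length_m`, `velocity_m_s`,
#'   `activation_est`, `force_N` and attributes `frequencies`, `amplitudes`,
#'   `trigger_phases`, `muscle`, `seed`.
#' @export
generate_identification_dataset <- function(muscle, frequencies = 1:6,
                                            amplitudes = c(0.001, 0.002, 0.003),
                                            trigger_phases = c(0, pi / 2, pi,
                                                               3 * pi / 2),
                                            noise_sd = 0,
                                            velocity_terms = c(B_v = 0, D_v = 0),
                                            cycles = 3,
                                            burst_duration = 0.04,
                                            sample_rate = 500, seed = 1) {
  stopifnot(inherits(muscle, "muscle_params"),
            length(frequencies) >= 2, length(amplitudes) >= 2)
  blocks <- with_seed(seed, {
    purrr::map(seq_along(frequencies), function(fi) {
      purrr::map(seq_along(amplitudes), function(ai) {
        f <- frequencies[fi]; amp <- amplitudes[ai]
        horizon <- cycles / f
        ph <- trigger_phases[(fi + ai) %% length(trigger_phases) + 1]
        win <- matrix(c(ph %% (2 * pi),
                        ph %% (2 * pi) + 2 * pi * burst_duration * f),
                      ncol = 2)
        wf <- generate_stim_waveform(f, list(win, NULL))
        act <- simulate_activation(muscle, stim_functions(wf)[[1]],  # envelope drive
                                   horizon = horizon, dt = wf$dt)
        idx <- seq(1, nrow(act), by = max(1L, round(1 / (sample_rate * wf$dt))))
        tt <- act$time_s[idx]
        a <- act$a[idx]
        l <- muscle$l0 + amp * sin(2 * pi * f * tt)
        v <- 2 * pi * f * amp * cos(2 * pi * f * tt)
        Fm <- muscle$A + muscle$B * l + (muscle$C + muscle$D * l) * a +
          velocity_terms[["B_v"]] * v + velocity_terms[["D_v"]] * a * v
        if (noise_sd > 0) Fm <- Fm + stats::rnorm(length(Fm), 0, noise_sd)
        tibble::tibble(time_s = tt, length_m = l, velocity_m_s = v,
                       activation_est = a, force_N = Fm,
                       freq_Hz = f, amplitude_m = amp)
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(blocks))
  structure(out, frequencies = frequencies, amplitudes = amplitudes,
            trigger_phases = trigger_phases, muscle = muscle, seed = seed)
}
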