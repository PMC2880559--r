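#' Passive equilibrium of the coupled system
#'
#' Displacement at which passive muscle forces balance the load spring with
#' zero activation: `x_e = (A1 + B1 l1_0 - A2 - B2 l2_0) / (k + B1 + B2)`.
#' @param muscles A `muscle_params` or list of two.
#' @param load A [load_params()].
#' @return Numeric displacement (m).
#' @export
passive_equilibrium <- function(muscles, load) {
  m <- as_muscle_pair(muscles)
  F0 <- m[[1]]$A + m[[1]]$B * m[[1]]$l0 - m[[2]]$A - m[[2]]$B * m[[2]]$l0
  F0 / (load$k + m[[1]]$B + m[[2]]$B)
}

#' Simulate the interconnected muscle-load system
#'
#' Integrates the six-state dynamics (load position/velocity plus two
#' activation cascades) driven by per-muscle stimulus signals, with a
#' classical fixed-step RK4 scheme whose step is aligned to the stimulus
#' sample grid (each step then integrates a smooth vector field). States are
#' recorded on a uniform output grid of at least 200 nodes per oscillation
#' cycle when `freq` is given.
#'
#' @param muscles A [muscle_params()] (single-muscle configuration: the
#'   antagonist is zeroed) or a list of two.
#' @param load A [load_params()].
#' @param stimulus A list of two stimulus signals (agonist, antagonist), each
#'   a function of time or a data frame `time_s`, `u` (zero-order hold), or a
#'   [stim_waveform()] carrying both channels.
#' @param initial Numeric state `c(x, v, a1, c1, a2, c2)`; default: passive
#'   equilibrium at rest.
#' @param horizon Duration (s), `> 0`.
#' @param dt Integration step (s). Defaults to the stimulus sample step (for
#'   waveforms) or 1e-4 s.
#' @param record_dt Output grid spacing (s); defaults to `max(dt, 5e-4)`.
#' @param freq Optional cycle frequency (Hz), stored for cycle segmentation
#'   by [workloop()].
#' @param state_guard Abort when `|x|` exceeds this (m); guards blow-up.
#' @return An `ml_trajectory`: a tibble with columns `time_s`, `x_m`,
#'   `v_m_s`, `a1`, `c1`, `a2`, `c2`, `u1`, `u2`, `F1_N`, `F2_N`, `Fnet_N`.
#' @export
simulate_coupled_system <- function(muscles, load, stimulus, initial = NULL,
                                    horizon, dt = NULL, record_dt = NULL,
                                    freq = NULL, state_guard = 1) {
  stopifnot(inherits(load, "load_params"), horizon > 0)
  m <- as_muscle_pair(muscles)
  if (inherits(stimulus, "stim_waveform")) {
    if (is.null(freq)) freq <- stimulus$freq
    dt <- dt %||% stimulus$dt
    stimulus <- stim_functions(stimulus)
  }
  stopifnot(is.list(stimulus), length(stimulus) == 2)
  dt <- dt %||% 1e-4
  n <- ceiling(horizon / dt)
  tt <- seq(0, by = dt, length.out = n + 1)
  u1 <- sample_stimulus(stimulus[[1]], tt)
  u2 <- sample_stimulus(stimulus[[2]], tt)
  for (ui in list(u1, u2)) {
    if (any(!is.finite(ui))) stop("stimulus contains non-finite values")
  }
  initial <- initial %||% c(passive_equilibrium(m, load), 0, 0, 0, 0, 0)
  stopifnot(length(initial) == 6)
  record_dt <- record_dt %||% max(dt, 5e-4)
  thin <- max(1L, round(record_dt / dt))
  out <- ml_sim_states(pack_pars(m, load), initial, dt, n, u1, u2, dt, 0L,
                       thin, state_guard)
  new_trajectory(out, m, load, freq = freq, dt = dt)
}

new_trajectory <- function(mat, muscles, load, freq = NULL, dt = NULL,
                           extra = NULL) {
  tr <- tibble::tibble(
    time_s = mat[, 1], x_m = mat[, 2], v_m_s = mat[, 3],
    a1 = mat[, 4], c1 = mat[, 5], a2 = mat[, 6], c2 = mat[, 7],
    u1 = mat[, 8], u2 = mat[, 9], F1_N = mat[, 10], F2_N = mat[, 11],
    Fnet_N = mat[, 10] - mat[, 11])
  if (!is.null(extra)) tr <- dplyr::bind_cols(tr, extra)
  structure(tr, class = c("ml_trajectory", class(tr)),
            muscles = muscles, load = load, freq = freq, dt = dt)
}

#' @export
print.ml_trajectory <- function(x, ...) {
  cat(sprintf("<ml_trajectory> %d nodes over %.4g s%s\n", nrow(x),
              max(x$time_s),
              if (!is.null(attr(x, "freq")))
                sprintf(" (cycle frequency %.3g Hz)", attr(x, "freq")) else ""))
  NextMethod()
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_s, x_m, v_m_s, a1, c1, a2, c2, u1, u2, F1_N, F2_N, Fnet_N`.
#' @param traj An `ml_trajectory` (or any data frame with those columns).
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_s", "x_m", "v_m_s", "a1", "c1", "a2", "c2",
            "u1", "u2", "F1_N", "F2_N", "Fnet_N")
  readr::write_csv(as.data.frame(traj)[, cols], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Energy bookkeeping along a trajectory
#'
#' Decomposes the work done by the net muscle force over the trajectory into
#' the change in stored energy (kinetic + spring potential) plus the damper
#' dissipation. On exact dynamics the residual is zero; its relative size is
#' an integration-accuracy diagnostic, and over one exact steady-state cycle
#' the stored-energy change vanishes so cyclic work equals dissipation.
#'
#' @param traj An `ml_trajectory`.
#' @param load A [load_params()]; defaults to the one stored on `traj`.
#' @return A list with `work_J`, `delta_energy_J`, `dissipation_J`,
#'   `residual_J`, `residual_rel`.
#' @export
energy_balance <- function(traj, load = NULL) {
  load <- load %||% attr(traj, "load")
  stopifnot(inherits(load, "load_params"))
  W <- trapz(traj$time_s, traj$Fnet_N * traj$v_m_s)
  E <- function(i) 0.5 * load$M * traj$v_m_s[i]^2 + 0.5 * load$k * traj$x_m[i]^2
  dE <- E(nrow(traj)) - E(1)
  Q <- trapz(traj$time_s, load$b * traj$v_m_s^2)
  res <- W - dE - Q
  list(work_J = W, delta_energy_J = dE, dissipation_J = Q, residual_J = res,
       residual_rel = abs(res) / max(abs(W), abs(Q), .Machine$double.eps))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
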