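#' Power-optimal cyclic control problem
#'
#' Defines the optimisation: find bounded stimulus inputs, periodic with
#' period `T = 1/freq`, that maximise the cyclic work delivered by the
#' muscle(s) to the mass-spring-damper load. With the Hamiltonian linear in
#' the controls, Pontryagin's minimum principle yields bang-bang inputs
#' switched by the costates conjugate to the stimulated calcium states; the
#' optimal trajectory solves a cyclic two-point boundary value problem in the
#' 12 state + costate variables.
#'
#' @param muscles A [muscle_params()] for the single-muscle problem, or a
#'   list of two for the antagonist pair.
#' @param load A [load_params()].
#' @param freq Oscillation frequency (Hz), `> 0`; the horizon is `1/freq`.
#' @return An object of class `ml_ocp`.
#' @export
ocp <- function(muscles, load, freq) {
  stopifnot(inherits(load, "load_params"), freq > 0)
  m <- as_muscle_pair(muscles)
  for (mi in m)
    if (!is.finite(mi$u_min) || !is.finite(mi$u_max))
      stop("control bounds must be finite: unbounded controls make the power-optimal problem ill-posed")
  structure(list(muscles = m, load = load, freq = freq, T = 1 / freq),
            class = "ml_ocp")
}

#' @export
print.ml_ocp <- function(x, ...) {
  single <- is_null_muscle(x$muscles[[2]])
  cat(sprintf("<ml_ocp> %s, f = %.4g Hz (T = %.4g s), load f_n = %.4g Hz\n",
              if (single) "single muscle" else "antagonist pair",
              x$freq, x$T, x$load$f_n))
  invisible(x)
}

is_null_muscle <- function(m) m$A == 0 && m$B == 0 && m$C == 0 && m$D == 0

#' Hamiltonian and costate dynamics
#'
#' For the running cost `L = -F_net v` (power maximisation as a minimum
#' problem), the Hamiltonian is `H = L + lambda' f(z, u)` and the costates
#' evolve as `lambda_dot = -dH/dz`, with the bilinear force model entering
#' through both the running cost and the load dynamics.
#'
#' @param problem An [ocp()].
#' @param state Numeric state `c(x, v, a1, c1, a2, c2)`.
#' @param costate Numeric length-6 multiplier vector.
#' @param controls Numeric `c(u1, u2)`.
#' @return A list with `H` (scalar), `state_dot`, `costate_dot`,
#'   `switching` (`c(s1, s2)`: the coefficients of `u1`, `u2` in `H`).
#' @export
hamiltonian_costate <- function(problem, state, costate, controls) {
  stopifnot(inherits(problem, "ml_ocp"), length(state) == 6,
            length(costate) == 6, length(controls) == 2)
  if (any(!is.finite(c(state, costate, controls))))
    stop("non-finite state, costate or control input")
  m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]; ld <- problem$load
  x <- state[1]; v <- state[2]
  a1 <- state[3]; c1 <- state[4]; a2 <- state[5]; c2 <- state[6]
  l1 <- m1$l0 - x; l2 <- m2$l0 + x
  F1 <- m1$A + m1$B * l1 + (m1$C + m1$D * l1) * a1
  F2 <- m2$A + m2$B * l2 + (m2$C + m2$D * l2) * a2
  Fnet <- F1 - F2
  f <- c(v,
         (Fnet - ld$k * x - ld$b * v) / ld$M,
         (c1 - a1) / m1$tau_a,
         (m1$gain * controls[1] - c1) / m1$tau_c,
         (c2 - a2) / m2$tau_a,
         (m2$gain * controls[2] - c2) / m2$tau_c)
  H <- -Fnet * v + sum(costate * f)
  K <- m1$B + m1$D * a1 + m2$B + m2$D * a2
  G1 <- m1$C + m1$D * l1
  G2 <- m2$C + m2$D * l2
  lx <- costate[1]; lv <- costate[2]
  la1 <- costate[3]; lc1 <- costate[4]; la2 <- costate[5]; lc2 <- costate[6]
  costate_dot <- c(
    -K * v + lv * (K + ld$k) / ld$M,
    Fnet - lx + lv * ld$b / ld$M,
    G1 * v - lv * G1 / ld$M + la1 / m1$tau_a,
    -la1 / m1$tau_a + lc1 / m1$tau_c,
    -G2 * v + lv * G2 / ld$M + la2 / m2$tau_a,
    -la2 / m2$tau_a + lc2 / m2$tau_c)
  switching <- c(lc1 * m1$gain / m1$tau_c, lc2 * m2$gain / m2$tau_c)
  list(H = H, state_dot = f, costate_dot = costate_dot, switching = switching)
}

#' Bang-bang control law
#'
#' The Hamiltonian is linear in each control with coefficient (switching
#' function) `s_i = lambda_{c_i} gain / tau_c`; minimising `H` pointwise
#' gives `u_i = u_max` when `s_i < 0` and `u_i = u_min` when `s_i > 0`, with
#' ties (`s_i = 0`) broken to `u_min`.
#'
#' @param problem An [ocp()].
#' @param costate Numeric length-6 costate vector.
#' @return Numeric `c(u1, u2)`.
#' @export
bang_bang_control <- function(problem, costate) {
  stopifnot(length(costate) == 6)
  if (any(!is.finite(costate))) stop("non-finite costate")
  m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]
  s1 <- costate[4] * m1$gain / m1$tau_c
  s2 <- costate[6] * m2$gain / m2$tau_c
  c(if (s1 < 0) m1$u_max else m1$u_min,
    if (s2 < 0) m2$u_max else m2$u_min)
}

smooth_controls <- function(problem, s1, s2, beta) {
  m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]
  list(u1 = m1$u_min + (m1$u_max - m1$u_min) * stats::plogis(-beta * s1),
       u2 = m2$u_min + (m2$u_max - m2$u_min) * stats::plogis(-beta * s2))
}

# ---------------------------------------------------------------------------
# initial guess: burst-stimulus forward simulation to periodic steady state,
# then a short forward-backward sweep to seed the costates. Also returns the
# typical switching-function magnitude, which sets the homotopy scale: the
# logistic sharpness is only meaningful relative to |s|.
ocp_initial_guess <- function(problem, phase = 0, duty = 0.4, n_sweeps = 5,
                              nsteps = 2048) {
  Tp <- problem$T
  pars <- pack_pars(problem$muscles, problem$load)
  dt <- Tp / nsteps
  single <- is_null_muscle(problem$muscles[[2]])
  m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]
  tt1 <- seq(0, by = dt, length.out = nsteps)
  ph <- ((tt1 / Tp + phase) %% 1)
  u1 <- m1$u_min + (m1$u_max - m1$u_min) * as.numeric(ph < duty)
  u2 <- if (single) numeric(nsteps)
        else m2$u_min + (m2$u_max - m2$u_min) *
          as.numeric(ph >= 0.5 & ph < 0.5 + duty)
  z_eq <- c(passive_equilibrium(problem$muscles, problem$load), 0, 0, 0, 0, 0)
  n_settle <- 12
  s_scale <- NA_real_
  for (s in seq_len(n_sweeps)) {
    u1_long <- rep(u1, n_settle); u2_long <- rep(u2, n_settle)
    sim <- ml_sim_states(pars, z_eq, dt, n_settle * nsteps, u1_long, u2_long,
                         dt, 0L, 1L, 1)
    # final 3 periods for the backward costate pass (transient-free tail)
    i0 <- (n_settle - 3) * nsteps + 1
    states <- sim[i0:(n_settle * nsteps + 1), 2:7, drop = FALSE]
    lam <- ml_costate_back(pars, states, dt, rep(0, 6))
    s1 <- lam[, 4] * m1$gain / m1$tau_c
    s2 <- lam[, 6] * m2$gain / m2$tau_c
    s_scale <- max(abs(s1), if (!single) abs(s2) else 0, 1e-12)
    if (s == n_sweeps)
      return(list(z0 = c(states[1, ], lam[1, ]), s_scale = s_scale))
    # control update from the smoothed law (sharpness ~ a few times 1/|s|),
    # relaxed towards the previous iterate
    lam1 <- lam[seq_len(nsteps), , drop = FALSE]
    sw <- smooth_controls(problem, s1[seq_len(nsteps)], s2[seq_len(nsteps)],
                          6 / s_scale)
    u1 <- 0.5 * u1 + 0.5 * sw$u1
    u2 <- if (single) u2 else 0.5 * u2 + 0.5 * sw$u2
    z_eq <- sim[n_settle * nsteps + 1, 2:7]
  }
}

residual_scale <- function(z0) {
  st <- pmax(abs(z0[1:6]), c(1e-3, 1e-2, rep(0.05, 4)))
  co <- pmax(abs(z0[7:12]), max(abs(z0[7:12]), 1e-4) * 0.05)
  c(st, co)
}

newton_cyclic <- function(pars, z0, Tp, nsteps, beta, tol = 1e-8,
                          max_iter = 22, anchor = TRUE) {
  sc <- residual_scale(z0)
  res_norm <- function(z) {
    zT <- ml_flow(pars, z, Tp, nsteps, beta)
    r <- (zT[1:12] - z) / sc
    if (anchor) r <- c(r, z[2] / sc[2])
    list(r = r, n = sqrt(sum(r^2)), work = zT[13])
  }
  cur <- res_norm(z0)
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$r)) < tol)
      return(list(z0 = z0, converged = TRUE, iter = it - 1,
                  residual = max(abs(cur$r)), work = cur$work))
    sh <- ml_shoot(pars, z0, Tp, nsteps, beta, TRUE, 1e-6)
    A <- (sh$J - diag(12)) / sc
    if (anchor) A <- rbind(A, (1:12 == 2) / sc[2])
    delta <- tryCatch(qr.solve(qr(A, LAPACK = TRUE), -cur$r),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) break
    step <- 1
    improved <- FALSE
    for (h in 1:5) {
      z_try <- z0 + step * delta
      nxt <- tryCatch(res_norm(z_try), error = function(e) NULL)
      if (!is.null(nxt) && is.finite(nxt$n) && nxt$n < cur$n) {
        z0 <- z_try; cur <- nxt; improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(z0 = z0, converged = max(abs(cur$r)) < tol, iter = max_iter,
       residual = max(abs(cur$r)), work = cur$work)
}

#' Solve the cyclic power-optimal control problem
#'
#' Solves the cyclic two-point boundary value problem of the Pontryagin
#' necessary conditions by a smoothed bang-bang homotopy: the discontinuous
#' control law is replaced by a steep logistic of the switching function with
#' sharpness `beta`, the smooth cyclic BVP is solved by damped-Newton single
#' shooting (finite-difference monodromy, least-squares step with a
#' `v(0) = 0` phase anchor), and `beta` is continued upward until the
#' controls sit at their bounds except in a measure-small neighbourhood of
#' the switches. Initialisation uses a burst-stimulus forward simulation to
#' periodic steady state plus a short forward-backward costate sweep; a small
#' deterministic restart schedule over burst phases guards against the
#' trivial (motionless) solution.
#'
#' @param problem An [ocp()].
#' @param init Optional warm start: a previous `ml_ocp_solution` (its
#'   `z0` and final sharpness are reused), or a length-12 numeric
#'   `c(state, costate)` at `t = 0`.
#' @param beta_schedule Increasing homotopy schedule for the switching
#'   sharpness, in units of the reciprocal typical switching-function
#'   magnitude (estimated from the initial guess); the logistic argument is
#'   `beta * s`, so only this product is meaningful.
#' @param nsteps RK4 steps per period.
#' @param tol Scaled cyclicity tolerance.
#' @param record Number of trajectory nodes to record (approximately).
#' @param interior_max Maximum tolerated fraction of nodes with controls
#'   farther than 1e-3 from a bound; the sharpness is pushed (up to
#'   `beta_cap` relative units) until met.
#' @param beta_cap Upper limit for the homotopy continuation (relative
#'   units).
#' @return An `ml_ocp_solution`: list with `trajectory` (tibble including
#'   costates, switching functions, controls and Hamiltonian trace),
#'   `work_J`, `mean_power_W`, `power_W_kg`, `converged`, `trivial`,
#'   `possibly_singular`, `residuals`, `H_rel_variation`, `interior_fraction`,
#'   `beta_final`, `z0`, `problem`.
#' @export
solve_cyclic_optimal_control <- function(problem, init = NULL,
                                         beta_schedule = c(3, 10, 30, 100,
                                                           300, 1000, 3000),
                                         nsteps = 4096, tol = 1e-8,
                                         record = 512, interior_max = 0.02,
                                         beta_cap = 3e4) {
  stopifnot(inherits(problem, "ml_ocp"))
  pars <- pack_pars(problem$muscles, problem$load)
  Tp <- problem$T
  warm <- NULL
  if (inherits(init, "ml_ocp_solution")) {
    warm <- init$z0
    warm_beta <- init$beta_final
  } else if (is.numeric(init) && length(init) == 12) {
    warm <- init
    warm_beta <- NULL
  }

  attempt <- function(z0, schedule) {
    best <- NULL
    misses <- 0
    for (beta in schedule) {
      fit <- newton_cyclic(pars, z0, Tp, nsteps, beta, tol = tol)
      # a failed or trivial stage is skipped without moving the iterate:
      # the current guess may still sit in the basin of a sharper stage
      if (!fit$converged || abs(fit$work) <= 1e-9) {
        misses <- misses + 1
        # once on a converged branch, two consecutive misses mean the
        # branch has been lost; sharper stages will not recover it
        if (!is.null(best) && misses >= 2) break
        next
      }
      misses <- 0
      z0 <- fit$z0
      best <- c(fit, list(beta = beta))
    }
    best
  }

  best <- NULL
  s_scale <- NULL
  if (!is.null(warm)) {
    # sharpness ladder up to the warm solution's final sharpness (or, for a
    # bare state/costate vector, scaled by its own switching magnitude)
    wb <- warm_beta %||% {
      m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]
      s_w <- max(abs(warm[10]) * m1$gain / m1$tau_c,
                 abs(warm[12]) * m2$gain / m2$tau_c, 1e-12)
      3000 / s_w
    }
    best <- attempt(warm, wb * c(1 / 27, 1 / 9, 1 / 3, 1))
  }
  if (is.null(best) || best$work <= 1e-9) {
    for (start in list(c(0, 0.4), c(0.25, 0.4), c(0, 0.7), c(0.25, 0.85),
                       c(0.5, 0.5), c(0.75, 0.3))) {
      guess <- ocp_initial_guess(problem, phase = start[1], duty = start[2])
      s_scale <- guess$s_scale
      cand <- attempt(guess$z0, beta_schedule / s_scale)
      if (!is.null(cand) && cand$work > 1e-9 &&
          (is.null(best) || cand$work > best$work)) {
        best <- cand
        break
      }
      if (is.null(best)) best <- cand
    }
  }
  if (is.null(best))
    return(failed_solution(problem, "no homotopy stage converged"))

  # push the sharpness until the bang-bang structure is resolved
  cap <- if (!is.null(s_scale)) beta_cap / s_scale else 10 * best$beta
  sol <- build_solution(problem, pars, best$z0, Tp, nsteps, best$beta,
                        record, best)
  while (!sol$trivial && sol$interior_fraction > interior_max &&
         best$beta < cap) {
    fit <- newton_cyclic(pars, best$z0, Tp, nsteps, 3 * best$beta, tol = tol)
    if (!fit$converged) break
    best <- c(fit, list(beta = 3 * best$beta))
    sol <- build_solution(problem, pars, best$z0, Tp, nsteps, best$beta,
                          record, best)
  }
  # phase representative: v(0) = 0 with x(0) above the cycle mean
  tr <- sol$trajectory
  if (tr$x_m[1] < mean(tr$x_m)) {
    half <- ml_flow(pars, best$z0, Tp / 2, ceiling(nsteps / 2), best$beta)[1:12]
    fit <- newton_cyclic(pars, half, Tp, nsteps, best$beta, tol = tol)
    if (fit$converged) {
      best <- c(fit, list(beta = best$beta))
      sol <- build_solution(problem, pars, best$z0, Tp, nsteps, best$beta,
                            record, best)
    }
  }
  sol
}

failed_solution <- function(problem, msg) {
  warning(sprintf("cyclic optimal control solve failed: %s", msg), call. = FALSE)
  structure(list(trajectory = NULL, work_J = NA_real_, mean_power_W = NA_real_,
                 power_W_kg = NA_real_, converged = FALSE, trivial = FALSE,
                 possibly_singular = FALSE, residuals = c(state = NA, costate = NA),
                 H_rel_variation = NA_real_, interior_fraction = NA_real_,
                 beta_final = NA_real_, z0 = NULL, problem = problem),
            class = "ml_ocp_solution")
}

build_solution <- function(problem, pars, z0, Tp, nsteps, beta, record, fit) {
  thin <- max(1L, floor(nsteps / record))
  mat <- ml_flow_traj(pars, z0, Tp, nsteps, beta, thin)
  m1 <- problem$muscles[[1]]; m2 <- problem$muscles[[2]]
  s1 <- mat[, 11] * m1$gain / m1$tau_c
  s2 <- mat[, 13] * m2$gain / m2$tau_c
  uu <- smooth_controls(problem, s1, s2, beta)
  n <- nrow(mat)
  H <- vapply(seq_len(n), function(i) {
    hamiltonian_costate(problem, mat[i, 2:7], mat[i, 8:13],
                        c(uu$u1[i], uu$u2[i]))$H
  }, numeric(1))
  l1 <- m1$l0 - mat[, 2]; l2 <- m2$l0 + mat[, 2]
  F1 <- m1$A + m1$B * l1 + (m1$C + m1$D * l1) * mat[, 4]
  F2 <- m2$A + m2$B * l2 + (m2$C + m2$D * l2) * mat[, 6]
  tr <- tibble::tibble(
    time_s = mat[, 1], x_m = mat[, 2], v_m_s = mat[, 3],
    a1 = mat[, 4], c1 = mat[, 5], a2 = mat[, 6], c2 = mat[, 7],
    lambda_x = mat[, 8], lambda_v = mat[, 9], lambda_a1 = mat[, 10],
    lambda_c1 = mat[, 11], lambda_a2 = mat[, 12], lambda_c2 = mat[, 13],
    u1 = uu$u1, u2 = uu$u2, s1 = s1, s2 = s2,
    F1_N = F1, F2_N = F2, Fnet_N = F1 - F2, H = H)
  J <- mat[n, 14]
  single <- is_null_muscle(m2)
  mass <- m1$mass + if (single) 0 else m2$mass
  sc <- residual_scale(z0)
  zT <- ml_flow(pars, z0, Tp, nsteps, beta)
  res_state <- max(abs((zT[1:6] - z0[1:6]) / sc[1:6]))
  res_costate <- max(abs((zT[7:12] - z0[7:12]) / sc[7:12]))
  s_scale <- pmax(max(abs(s1)), max(abs(s2)), .Machine$double.eps)
  singular <- FALSE
  active <- list(s1, if (!single) s2 else NULL)
  for (s in active[!vapply(active, is.null, TRUE)])
    if (mean(abs(s) < 1e-6 * s_scale) > 0.05) singular <- TRUE
  interior <- function(u, lo, hi) mean(u > lo + 1e-3 & u < hi - 1e-3)
  int_frac <- interior(uu$u1, m1$u_min, m1$u_max)
  if (!single) int_frac <- max(int_frac, interior(uu$u2, m2$u_min, m2$u_max))
  trivial <- (max(tr$x_m) - min(tr$x_m)) < 1e-7 || abs(J) < 1e-12
  Hvar <- (max(H) - min(H)) / max(max(abs(H)), abs(J) / Tp)
  structure(list(
    trajectory = tr, work_J = J, mean_power_W = J / Tp,
    power_W_kg = if (mass > 0) J / Tp / mass else NA_real_,
    converged = isTRUE(fit$converged), trivial = trivial,
    possibly_singular = singular,
    residuals = c(state = res_state, costate = res_costate),
    H_rel_variation = Hvar, interior_fraction = int_frac,
    beta_final = beta, z0 = z0, problem = problem),
    class = "ml_ocp_solution")
}

#' @export
print.ml_ocp_solution <- function(x, ...) {
  cat("<ml_ocp_solution>\n")
  cat(sprintf("  f = %.4g Hz, cyclic work J = %.6g J, mean power = %.6g W (%.3g W/kg)\n",
              x$problem$freq, x$work_J, x$mean_power_W, x$power_W_kg))
  cat(sprintf("  converged: %s (residuals: state %.2g, costate %.2g; beta = %g)\n",
              x$converged, x$residuals[1], x$residuals[2], x$beta_final))
  if (isTRUE(x$trivial)) cat("  NOTE: trivial (motionless) solution\n")
  if (isTRUE(x$possibly_singular)) cat("  NOTE: possibly singular arc\n")
  invisible(x)
}

#' Sweep the power-optimal solution across oscillation frequency
#'
#' One cyclic solve per grid frequency, warm-starting each solve from its
#' neighbour (continuation). The power-optimal frequency `f_star` is the
#' argmax of mean power over converged, nontrivial grid points.
#'
#' @param muscles,load As for [ocp()].
#' @param freqs Frequency grid (Hz), at least 5 points.
#' @param keep_solutions Keep the full solution objects (as an attribute)?
#' @param ... Passed to [solve_cyclic_optimal_control()].
#' @return An `ml_power_sweep` tibble with columns `freq_Hz`, `work_J`,
#'   `mean_power_W`, `power_W_kg`, `converged`, `trivial`; attributes
#'   `f_star` and (optionally) `solutions`.
#' @export
sweep_optimal_power <- function(muscles, load, freqs, keep_solutions = FALSE,
                                ...) {
  stopifnot(length(freqs) >= 5)
  freqs <- sort(freqs)
  sols <- vector("list", length(freqs))
  ok_sol <- function(s) !is.null(s) && isTRUE(s$converged) && !isTRUE(s$trivial)
  prev <- NULL
  for (i in seq_along(freqs)) {
    pr <- ocp(muscles, load, freqs[i])
    sols[[i]] <- solve_cyclic_optimal_control(pr, init = prev, ...)
    if (ok_sol(sols[[i]])) prev <- sols[[i]]
  }
  # second pass: retry failed points by continuation from the other side
  prev <- NULL
  for (i in rev(seq_along(freqs))) {
    if (ok_sol(sols[[i]])) { prev <- sols[[i]]; next }
    if (is.null(prev)) next
    pr <- ocp(muscles, load, freqs[i])
    retry <- suppressWarnings(
      solve_cyclic_optimal_control(pr, init = prev, ...))
    if (ok_sol(retry)) { sols[[i]] <- retry; prev <- retry }
  }
  tab <- dplyr::bind_rows(lapply(seq_along(freqs), function(i) {
    s <- sols[[i]]
    tibble::tibble(freq_Hz = freqs[i], work_J = s$work_J,
                   mean_power_W = s$mean_power_W, power_W_kg = s$power_W_kg,
                   converged = isTRUE(s$converged), trivial = isTRUE(s$trivial))
  }))
  ok <- tab$converged & !tab$trivial
  if (mean(ok) < 0.5)
    warning("more than half of the sweep points failed to converge; sweep flagged",
            call. = FALSE)
  f_star <- if (any(ok)) tab$freq_Hz[ok][which.max(tab$mean_power_W[ok])] else NA_real_
  structure(tab, class = c("ml_power_sweep", class(tab)),
            f_star = f_star, flagged = mean(ok) < 0.5,
            solutions = if (keep_solutions) sols else NULL)
}

#' Power-optimal frequency of a sweep
#' @param sweep An `ml_power_sweep`.
#' @return Frequency (Hz) maximising mean power over converged points.
#' @export
f_star <- function(sweep) attr(sweep, "f_star")

# ---------------------------------------------------------------------------
# impedance-free benchmark

#' Optimal mean power of a bounded impedance-free force source
#'
#' For an idealised force source limited in magnitude by `F_max` driving a
#' linear mass-spring-damper, the power-optimal periodic forcing at a given
#' frequency is the symmetric square wave of amplitude `F_max` phase-locked
#' to the velocity sign. The mean power is evaluated through the Fourier
#' steady-state solution of the load; over frequency it peaks exactly at the
#' load natural frequency.
#'
#' @param load A [load_params()] with `b > 0`.
#' @param F_max Force bound (N), `>= 0`.
#' @param freq Oscillation frequency(ies), Hz.
#' @param n_harmonics Number of odd harmonics retained.
#' @return A tibble with `freq_Hz`, `F_max_N` and `mean_power_W`
#'   (`F_max` and `freq` are recycled against each other).
#' @export
impedance_free_optimal_power <- function(load, F_max, freq, n_harmonics = 50) {
  stopifnot(inherits(load, "load_params"), all(F_max >= 0))
  if (load$b <= 0)
    stop("impedance-free optimum needs b > 0 (undamped resonance gives unbounded power)")
  n <- max(length(F_max), length(freq))
  F_max <- rep_len(F_max, n)
  freq <- rep_len(freq, n)
  power_one <- function(f, Fm) {
    h_max <- 2 * n_harmonics - 1
    co <- complex(length.out = h_max + 1)
    h_odd <- seq(1, h_max, by = 2)
    co[h_odd + 1] <- 4 * Fm / (pi * h_odd)   # square-wave harmonics
    steady_state_periodic_response(load, co, 2 * pi * f)$mean_power_W
  }
  tibble::tibble(freq_Hz = freq, F_max_N = F_max,
                 mean_power_W = mapply(power_one, freq, F_max))
}

#' Synergy ratio of two bounded impedance-free actuators
#'
#' Computes `S = W12 / (W1 + W2)` where each work term comes from the
#' power-optimal square-wave forcing of the corresponding actuator (bounds
#' `F1_max`, `F2_max`) or of the aligned pair (bound `F1_max + F2_max`) on
#' the same load. For equal bounds the quadratic power scaling of a linear
#' load gives `S = 2` at every frequency; unequal bounds give `1 < S <= 2`.
#'
#' @param load A [load_params()].
#' @param F1_max,F2_max Force bounds (N).
#' @param freq Frequency(ies), Hz.
#' @return A tibble with `freq_Hz`, `P1_W`, `P2_W`, `P12_W`, `S`.
#' @export
impedance_free_synergy <- function(load, F1_max, F2_max, freq) {
  P1 <- impedance_free_optimal_power(load, F1_max, freq)$mean_power_W
  P2 <- impedance_free_optimal_power(load, F2_max, freq)$mean_power_W
  P12 <- impedance_free_optimal_power(load, F1_max + F2_max, freq)$mean_power_W
  tibble::tibble(freq_Hz = freq, P1_W = P1, P2_W = P2, P12_W = P12,
                 S = P12 / (P1 + P2))
}

# ---------------------------------------------------------------------------
# direct transcription oracle

#' Direct transcription of the cyclic power-optimal problem
#'
#' Independent cross-check of the boundary-value solver: parameterises each
#' control as piecewise-constant on `n_intervals` equal sub-intervals of the
#' period, simulates the coupled system to periodic steady state, and
#' maximises the last-cycle work with a box-constrained quasi-Newton
#' optimiser.
#'
#' @param problem An [ocp()].
#' @param n_intervals Control intervals per period (divides
#'   `nsteps_per_period`).
#' @param n_periods Settling periods simulated per evaluation.
#' @param nsteps_per_period RK4 steps per period.
#' @param maxit Optimiser iteration cap.
#' @param duty,phase Initial burst guess.
#' @return A list with `work_J`, `mean_power_W`, `u1`, `u2`, `convergence`.
#' @export
solve_transcription <- function(problem, n_intervals = 32, n_periods = 10,
                                nsteps_per_period = 1024, maxit = 120,
                                duty = 0.4, phase = 0) {
  stopifnot(inherits(problem, "ml_ocp"),
            nsteps_per_period %% n_intervals == 0)
  pars <- pack_pars(problem$muscles, problem$load)
  Tp <- problem$T
  dt <- Tp / nsteps_per_period
  u_dt <- Tp / n_intervals
  single <- is_null_muscle(problem$muscles[[2]])
  z0 <- c(passive_equilibrium(problem$muscles, problem$load), 0, 0, 0, 0, 0)
  nsteps <- n_periods * nsteps_per_period
  last_work <- function(u1, u2) {
    u1_long <- rep(u1, n_periods + 1)  # +1 tile guards the endpoint lookup
    u2_long <- rep(u2, n_periods + 1)
    out <- ml_sim_states(pars, z0, dt, nsteps, u1_long, u2_long, u_dt, 0L,
                         nsteps_per_period, 1)
    nrows <- nrow(out)
    out[nrows, 12] - out[nrows - 1, 12]
  }
  obj <- function(theta) {
    if (single) -last_work(theta, numeric(n_intervals))
    else -last_work(theta[1:n_intervals], theta[-(1:n_intervals)])
  }
  ph <- ((seq_len(n_intervals) - 1) / n_intervals + phase) %% 1
  g1 <- as.numeric(ph < duty)
  g2 <- as.numeric(ph >= 0.5 & ph < 0.5 + duty)
  theta0 <- if (single) g1 else c(g1, g2)
  m1 <- problem$muscles[[1]]
  fit <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = m1$u_min, upper = m1$u_max,
                      control = list(maxit = maxit, factr = 1e7))
  u1 <- if (single) fit$par else fit$par[1:n_intervals]
  u2 <- if (single) numeric(n_intervals) else fit$par[-(1:n_intervals)]
  list(work_J = -fit$value, mean_power_W = -fit$value / Tp,
       u1 = u1, u2 = u2, convergence = fit$convergence)
}
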