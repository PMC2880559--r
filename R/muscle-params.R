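#' Bilinear muscle parameters
#'
#' Container for one muscle of the bilinear contractile model
#' \deqn{F(l, a) = A + B l + C a + D a l,}
#' where `l` is muscle length (m) and `a` the dimensionless activation state
#' produced by the second-order excitation-contraction cascade. Muscle
#' stiffness is `B + D a`, i.e. linear in activation, which is the property
#' that lets neural input retune the resonance of a coupled muscle-load
#' system.
#'
#' @param A Force offset (N).
#' @param B Passive stiffness (N/m), `>= 0`.
#' @param C Active force gain at zero length (N per unit activation). May be
#'   negative: only `C + D l` over the operating range must keep contractile
#'   force non-negative.
#' @param D Active stiffness gain (N/m per unit activation), `>= 0`.
#' @param l0 Nominal (rest) length (m), `> 0`.
#' @param tau_c First excitation-contraction time constant (s): calcium
#'   release/diffusion stage driven by the stimulus.
#' @param tau_a Second time constant (s): activation stage.
#' @param gain Steady-state activation gain; fixed at 1 (full recruitment).
#' @param u_min,u_max Control bounds (dimensionless), `u_min < u_max`.
#' @param mass Muscle mass (kg), used only to report mass-normalised power.
#' @param operating_range Fractional length range around `l0` within which the
#'   bilinear fit is trusted; outside it [muscle_force()] warns.
#'
#' @return An object of class `muscle_params` (a named list).
#' @seealso [muscle_force()], [default_muscle()], [calibrate_muscle_stiffness()]
#' @export
muscle_params <- function(A = 0, B = 100, C = -20.56364, D = 850, l0 = 0.03,
                          tau_c = 0.125, tau_a = 0.125, gain = 1,
                          u_min = 0, u_max = 1, mass = 0.0015,
                          operating_range = 0.10) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(D))
  if (B < 0 || D < 0) stop("passive and active stiffness gains B, D must be >= 0")
  if (tau_c <= 0 || tau_a <= 0) stop("time constants tau_c, tau_a must be positive")
  if (!isTRUE(u_min < u_max)) stop("control bounds require u_min < u_max")
  if (gain != 1) stop("steady-state activation gain is fixed at 1 in this model")
  if (l0 <= 0) stop("nominal length l0 must be positive")
  p <- structure(
    list(A = A, B = B, C = C, D = D, l0 = l0, tau_c = tau_c, tau_a = tau_a,
         gain = gain, u_min = u_min, u_max = u_max, mass = mass,
         operating_range = operating_range),
    class = "muscle_params")
  lr <- l0 * (1 + c(-1, 1) * operating_range)
  fmin <- min(outer(c(0, 1), lr, function(a, l) A + B * l + (C + D * l) * a))
  if (fmin < -1e-9)
    warning("contractile force is negative somewhere in the declared operating range",
            call. = FALSE)
  p
}

#' @export
print.muscle_params <- function(x, ...) {
  cat("<muscle_params>\n")
  cat(sprintf("  force:  F = %.4g + %.4g l + (%.4g + %.4g l) a  [N; l in m]\n",
              x$A, x$B, x$C, x$D))
  cat(sprintf("  l0 = %.4g m (+/- %.0f%%), stiffness B + D a in [%.4g, %.4g] N/m\n",
              x$l0, 100 * x$operating_range, x$B, x$B + x$D))
  cat(sprintf("  activation: tau_c = %.4g s, tau_a = %.4g s, gain = %g, u in [%g, %g]\n",
              x$tau_c, x$tau_a, x$gain, x$u_min, x$u_max))
  invisible(x)
}

#' A muscle with all force coefficients zeroed
#'
#' Used as the antagonist in single-muscle configurations: the coupled system
#' reduces exactly to one muscle driving the load, while keeping the state
#' dimension fixed.
#' @param template A `muscle_params` whose time constants and bounds to reuse.
#' @return A `muscle_params` with `A = B = C = D = 0`.
#' @export
null_muscle <- function(template = default_muscle()) {
  p <- template
  p$A <- 0; p$B <- 0; p$C <- 0; p$D <- 0
  p
}

#' Calibrate active stiffness for a target resonance shift
#'
#' Sets the active stiffness gain `D` so that one muscle holding a reference
#' mean activation `a_ref` shifts the coupled natural frequency of a load of
#' stiffness `k` from `f_n` to `ratio * f_n`. From
#' `sqrt((k + B + D a_ref)/k) = ratio`, this gives
#' `D = ((ratio^2 - 1) k - B)/a_ref`.
#'
#' The active force scale is specified at the operating point rather than at
#' nominal length: a single muscle activated at mean level `a_ref` pulls the
#' load to the equilibrium `x_bar = (A + B l0 + F_act0 a_ref)/(k + B)`, and
#' `C` is chosen so that the active force gain there,
#' `C + D (l0 - x_bar)`, equals `F_act0`. (Anchoring at `l0` instead can
#' leave the gain near zero at the shifted equilibrium, i.e. a muscle unable
#' to excite the load.) Scaling `F_act0` rescales the motion amplitude but
#' leaves optimal switching patterns, and hence optimal frequencies,
#' unchanged.
#'
#' @param k Load stiffness (N/m).
#' @param ratio Target ratio of matched coupled frequency to load natural
#'   frequency (default 1.2).
#' @param a_ref Reference cycle-mean activation at the optimum (default 0.4,
#'   the burst duty cycle typical of power-optimal solutions).
#' @param B Passive stiffness (N/m).
#' @param F_act0 Active force gain at the operating point and full
#'   activation (N).
#' @param l0 Nominal length (m).
#' @param ... Passed to [muscle_params()].
#' @return A `muscle_params`.
#' @export
calibrate_muscle_stiffness <- function(k = 1000, ratio = 1.2, a_ref = 0.4,
                                       B = 100, F_act0 = 2, l0 = 0.03, ...) {
  stopifnot(k > 0, ratio > 1, a_ref > 0, a_ref <= 1)
  D <- ((ratio^2 - 1) * k - B) / a_ref
  if (D < 0) stop("requested ratio is below the passive resonance shift; decrease B")
  A <- 0
  x_bar <- (A + B * l0 + F_act0 * a_ref) / (k + B)
  C <- F_act0 - D * (l0 - x_bar)
  muscle_params(A = A, B = B, C = C, D = D, l0 = l0, ...)
}

#' Default calibrated muscle
#'
#' The package-default frog plantaris-like muscle: equal-pole 125 ms
#' excitation-contraction dynamics and active stiffness calibrated (see
#' [calibrate_muscle_stiffness()]) so that power-optimal solutions against the
#' default 1000 N/m load resonate near 1.2 times the load natural frequency.
#' @param k Load stiffness the muscle is calibrated against (N/m).
#' @param ... Overrides passed to [calibrate_muscle_stiffness()].
#' @return A `muscle_params`.
#' @export
default_muscle <- function(k = 1000, ...) {
  calibrate_muscle_stiffness(k = k, ...)
}

#' Contractile force and instantaneous stiffness of the bilinear model
#'
#' @param params A [muscle_params()].
#' @param length Muscle length(s), m.
#' @param activation Activation(s) in `[0, 1]`.
#' @param check_range Warn when `length` leaves the declared operating range
#'   (the model then extrapolates).
#' @return A tibble with columns `length_m`, `activation`, `force_N`,
#'   `stiffness_N_m`.
#' @examples
#' m <- muscle_params(A = 0, B = 200, C = 10, D = 800, l0 = 0.01)
#' muscle_force(m, 0.01, 0.5)  # force = 2 + 5 + 4 = 11 N
#' @export
muscle_force <- function(params, length, activation, check_range = TRUE) {
  stopifnot(inherits(params, "muscle_params"))
  if (any(activation < 0 | activation > 1))
    stop("activation must lie in [0, 1]")
  if (check_range) {
    lr <- params$l0 * (1 + c(-1, 1) * params$operating_range)
    if (any(length < lr[1] | length > lr[2]))
      warning("length outside the declared operating range: bilinear model extrapolating",
              call. = FALSE)
  }
  tibble::tibble(
    length_m = length,
    activation = activation,
    force_N = params$A + params$B * length +
      (params$C + params$D * length) * activation,
    stiffness_N_m = params$B + params$D * activation)
}

#' Net force exerted by an antagonist muscle pair on the load
#'
#' Muscle lengths follow the load coordinate as `l1 = l1_0 - x` (agonist
#' shortens as the load moves in +x) and `l2 = l2_0 + x`. The net force along
#' +x is `F1(l1, a1) - F2(l2, a2)`; the net muscle stiffness seen by the load
#' is `(B1 + D1 a1) + (B2 + D2 a2)`, acting as a restoring term
#' (`d F_net / d x = -stiffness`). Co-activating both muscles therefore
#' stiffens the system without changing the net force of a symmetric pair at
#' `x = 0`.
#'
#' @param agonist,antagonist [muscle_params()] for the two muscles.
#' @param x Load displacement(s), m.
#' @param a1,a2 Activations in `[0, 1]`.
#' @param check_range Warn on operating-range extrapolation.
#' @return A tibble with `x_m`, `a1`, `a2`, `F1_N`, `F2_N`, `Fnet_N`,
#'   `stiffness_N_m`.
#' @export
net_load_force <- function(agonist, antagonist, x, a1, a2, check_range = TRUE) {
  if (any(a1 < 0 | a1 > 1) || any(a2 < 0 | a2 > 1))
    stop("activations must lie in [0, 1]")
  f1 <- muscle_force(agonist, agonist$l0 - x, a1, check_range = check_range)
  f2 <- muscle_force(antagonist, antagonist$l0 + x, a2,
                     check_range = check_range && antagonist$D + antagonist$B > 0)
  tibble::tibble(
    x_m = x, a1 = a1, a2 = a2,
    F1_N = f1$force_N, F2_N = f2$force_N,
    Fnet_N = f1$force_N - f2$force_N,
    stiffness_N_m = f1$stiffness_N_m + f2$stiffness_N_m)
}

# pack a muscle pair + load into the 23-vector the C++ core expects
pack_pars <- function(muscles, load) {
  m1 <- muscles[[1]]; m2 <- muscles[[2]]
  c(m1$A, m1$B, m1$C, m1$D, m1$l0, m1$tau_c, m1$tau_a, m1$gain, m1$u_min, m1$u_max,
    m2$A, m2$B, m2$C, m2$D, m2$l0, m2$tau_c, m2$tau_a, m2$gain, m2$u_min, m2$u_max,
    load$M, load$b, load$k)
}

# coerce a muscles argument: a single muscle_params becomes
# list(muscle, null antagonist); a list of two is used as-is
as_muscle_pair <- function(muscles) {
  if (inherits(muscles, "muscle_params"))
    return(list(agonist = muscles, antagonist = null_muscle(muscles)))
  stopifnot(is.list(muscles), length(muscles) == 2)
  lapply(muscles, function(m) { stopifnot(inherits(m, "muscle_params")); m })
  list(agonist = muscles[[1]], antagonist = muscles[[2]])
}
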