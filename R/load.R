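#' Mass-spring-damper load parameters
#'
#' The external load is a second-order system
#' \deqn{M \ddot x + b \dot x + k x = F_{net}(t),}
#' with natural frequency `f_n = sqrt(k/M)/(2 pi)` and damping ratio
#' `zeta = b / (2 sqrt(k M))`. Either `(M, b, k)` or `(f_n, zeta, k)` may be
#' supplied; the remaining quantities are derived and exposed read-only.
#'
#' @param M Mass (kg), `> 0`.
#' @param b Damping constant (N s/m), `>= 0`.
#' @param k Stiffness (N/m), `> 0`.
#' @param f_n Natural frequency (Hz); with `zeta`, an alternative
#'   parameterisation.
#' @param zeta Damping ratio (dimensionless).
#' @return An object of class `load_params`.
#' @examples
#' load_params(f_n = 2, zeta = 0.1, k = 1000)
#' @export
load_params <- function(M = NULL, b = NULL, k = 1000, f_n = NULL, zeta = NULL) {
  stopifnot(k > 0)
  if (!is.null(f_n)) {
    stopifnot(f_n > 0, !is.null(zeta), zeta >= 0)
    M <- k / (2 * pi * f_n)^2
    b <- 2 * zeta * sqrt(k * M)
  }
  stopifnot(!is.null(M), !is.null(b), M > 0, b >= 0)
  structure(
    list(M = M, b = b, k = k,
         f_n = sqrt(k / M) / (2 * pi),
         zeta = b / (2 * sqrt(k * M))),
    class = "load_params")
}

#' @export
print.load_params <- function(x, ...) {
  cat(sprintf("<load_params> M = %.4g kg, b = %.4g N s/m, k = %.4g N/m (f_n = %.4g Hz, zeta = %.4g)\n",
              x$M, x$b, x$k, x$f_n, x$zeta))
  invisible(x)
}

#' Default load
#'
#' `f_n` = 2 Hz, `zeta` = 0.1, `k` = 1000 N/m (mid-range of stiffness values
#' comparable with co-activated muscle stiffness).
#' @param f_n,zeta,k Overrides.
#' @return A `load_params`.
#' @export
default_load <- function(f_n = 2, zeta = 0.1, k = 1000) {
  load_params(f_n = f_n, zeta = zeta, k = k)
}

#' Mechanical impedance of the load
#'
#' `Z_L(j w) = (M (jw)^2 + b (jw) + k)/(jw) = b + j(M w - k/w)`: the transfer
#' function from velocity to force. Its real part is the damping `b` at every
#' frequency; the reactance `M w - k/w` vanishes at resonance.
#'
#' @param load A [load_params()].
#' @param omega Angular frequency(ies), rad/s, `> 0`.
#' @return Complex impedance(s), N s/m.
#' @export
load_impedance <- function(load, omega) {
  stopifnot(inherits(load, "load_params"))
  if (any(omega <= 0)) stop("omega must be positive (Z_L has a pole at zero)")
  complex(real = load$b, imaginary = load$M * omega - load$k / omega)
}

#' Steady-state periodic response of the load by Fourier division
#'
#' For a periodic force with finitely many harmonics
#' `F(t) = Re sum_h F_h exp(j h w t)` (h = 0 .. H), the steady-state velocity
#' is `V_h = F_h / Z_L(j h w)` per harmonic, the displacement
#' `X_h = V_h / (j h w)`, and the mean power delivered is
#' `sum_h 0.5 Re(F_h conj(V_h))`, which equals the damper dissipation
#' `b <v^2>`. The h = 0 term is static (`x = F_0/k`, no power).
#'
#' @param load A [load_params()].
#' @param forcing Complex vector of harmonic coefficients; `forcing[i]` is the
#'   coefficient of harmonic `h = i - 1` (so `forcing[1]` is the DC term).
#'   Real amplitudes may be given for cosine phases.
#' @param omega Fundamental angular frequency (rad/s), `> 0`.
#' @return A list with tibble `harmonics` (`h`, `F`, `V`, `X` complex
#'   columns) and scalars `mean_power_W`, `omega`.
#' @export
steady_state_periodic_response <- function(load, forcing, omega) {
  stopifnot(inherits(load, "load_params"), omega > 0)
  forcing <- as.complex(forcing)
  h <- seq_along(forcing) - 1
  ac <- h > 0 & Mod(forcing) > 0
  if (load$b == 0) {
    wn <- sqrt(load$k / load$M)
    if (any(abs(h[ac] * omega - wn) < 1e-9 * wn))
      stop("undamped load forced at resonance: response unbounded")
  }
  V <- X <- complex(length.out = length(forcing))
  if (any(ac)) {
    Z <- load_impedance(load, h[ac] * omega)
    V[ac] <- forcing[ac] / Z
    X[ac] <- V[ac] / (1i * h[ac] * omega)
  }
  if (length(forcing) >= 1) X[1] <- forcing[1] / load$k
  power <- sum(0.5 * Re(forcing[ac] * Conj(V[ac])))
  list(harmonics = tibble::tibble(h = h, F = forcing, V = V, X = X),
       mean_power_W = as.numeric(power), omega = omega)
}
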