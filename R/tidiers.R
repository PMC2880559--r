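# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ml_ocp_solution <- function(x, ...) x$trajectory

#' @exportS3Method generics::glance
glance.ml_ocp_solution <- function(x, ...) {
  tibble::tibble(
    freq_Hz = x$problem$freq, work_J = x$work_J,
    mean_power_W = x$mean_power_W, power_W_kg = x$power_W_kg,
    converged = x$converged, trivial = x$trivial,
    possibly_singular = x$possibly_singular,
    residual_state = unname(x$residuals["state"]),
    residual_costate = unname(x$residuals["costate"]),
    H_rel_variation = x$H_rel_variation,
    interior_fraction = x$interior_fraction,
    beta_final = x$beta_final)
}

#' @exportS3Method generics::tidy
tidy.ml_bilinear_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 selected = names(x$coefficients) %in% x$terms)
}

#' @exportS3Method generics::glance
glance.ml_bilinear_fit <- function(x, ...) {
  tibble::tibble(var_explained = x$var_explained, in_sample = x$in_sample,
                 n = length(stats::fitted(x$fit)))
}

#' @exportS3Method generics::tidy
tidy.ml_protocol <- function(x, ...) x$measurements

#' @exportS3Method generics::glance
glance.ml_protocol <- function(x, ...) {
  if (x$hypothesis == "H1") {
    t1 <- x$tests$opt_vs_1
    tibble::tibble(hypothesis = "H1", statistic = t1$t, p.value = t1$p,
                   mean = t1$mean, n = t1$n, stars = t1$stars)
  } else {
    s <- x$tests$S_vs_2
    tibble::tibble(hypothesis = "H2", statistic = s$t, p.value = s$p,
                   mean = s$mean, n = s$n, stars = s$stars)
  }
}

#' Plot a workloop
#'
#' Force-displacement loops per cycle; counter-clockwise loops enclose
#' positive (power-producing) area.
#' @param object An `ml_workloop`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ml_workloop <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_m * 1e3, y = .data$F_N,
                               colour = factor(.data$cycle))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "displacement (mm)", y = "force (N)",
                  colour = "cycle") +
    ggplot2::theme_minimal()
}

#' Plot a power sweep
#'
#' Mean optimal power against oscillation frequency, with the power-optimal
#' frequency marked.
#' @param object An `ml_power_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ml_power_sweep <- function(object, ...) {
  ok <- object$converged & !object$trivial
  p <- ggplot2::ggplot(object[ok, ],
                       ggplot2::aes(x = .data$freq_Hz, y = .data$mean_power_W)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "oscillation frequency (Hz)", y = "mean power (W)") +
    ggplot2::theme_minimal()
  fs <- attr(object, "f_star")
  if (is.finite(fs))
    p <- p + ggplot2::geom_vline(xintercept = fs, linetype = "dashed")
  p
}

#' Plot an optimal-control solution
#'
#' Facetted traces of controls, activations, forces and load motion over one
#' cycle.
#' @param object An `ml_ocp_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ml_ocp_solution <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr[, c("time_s", "u1", "u2", "a1", "a2", "F1_N", "F2_N",
           "x_m", "v_m_s")],
    -"time_s", names_to = "signal", values_to = "value")
  long$panel <- dplyr::case_match(long$signal,
    c("u1", "u2") ~ "control", c("a1", "a2") ~ "activation",
    c("F1_N", "F2_N") ~ "force (N)", "x_m" ~ "x (m)", "v_m_s" ~ "v (m/s)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
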