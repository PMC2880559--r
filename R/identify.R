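#' Term sets of the generalised muscle impedance model
#'
#' The generalised model regresses measured contractile force on
#' `offset` (A), `length` (B l), `activation` (C a),
#' `activation_length` (D a l), `velocity` (B_v v) and
#' `activation_velocity` (D_v a v). The bilinear reduction keeps only
#' `{length, activation, activation_length}`: the remaining terms can be
#' dropped with minimal loss of variance explained for cyclic, bursting
#' contractions.
#' @export
bilinear_terms <- c("length", "activation", "activation_length")

#' @rdname bilinear_terms
#' @export
impedance_terms <- c("offset", "length", "activation", "activation_length",
                     "velocity", "activation_velocity")

#' Identify the bilinear muscle force model by least squares
#'
#' Fits the selected terms of the generalised impedance model to an
#' identification dataset of simultaneous length, velocity, activation and
#' force samples. The regression is linear in the coefficients, so ordinary
#' least squares applies; variance explained is computed on held-out rows
#' when a split is provided, in-sample otherwise.
#'
#' @param data A data frame with columns `length_m`, `velocity_m_s`,
#'   `activation_est`, `force_N` (e.g. from
#'   [generate_identification_dataset()] or [read_identification_dataset()]).
#' @param terms Character subset of [impedance_terms].
#' @param holdout Optional logical vector (or fraction in (0,1)) marking rows
#'   used only for validation.
#' @param l0,tau_c,tau_a,... Muscle constants carried into the returned
#'   [muscle_params()] (they are not identified by this regression).
#' @return An `ml_bilinear_fit`: list with `coefficients` (named numeric over
#'   `A, B, C, D, B_v, D_v`; non-selected terms are 0), `params` (a
#'   [muscle_params()] when the selected terms permit one), `var_explained`,
#'   `in_sample`, `fit` (the underlying `lm`), `se` (standard errors).
#' @export
identify_bilinear_model <- function(data, terms = bilinear_terms,
                                    holdout = NULL, l0 = 0.03,
                                    tau_c = 0.125, tau_a = 0.125, ...) {
  stopifnot(all(c("length_m", "velocity_m_s", "activation_est", "force_N")
                %in% names(data)))
  terms <- match.arg(terms, impedance_terms, several.ok = TRUE)
  X_all <- cbind(
    offset = rep(1, nrow(data)),
    length = data$length_m,
    activation = data$activation_est,
    activation_length = data$activation_est * data$length_m,
    velocity = data$velocity_m_s,
    activation_velocity = data$activation_est * data$velocity_m_s)
  X <- X_all[, terms, drop = FALSE]
  if (nrow(X) < ncol(X) + 1)
    stop("need at least as many samples as free parameters")
  if (is.numeric(holdout) && length(holdout) == 1 && holdout > 0 && holdout < 1) {
    n_hold <- floor(holdout * nrow(X))
    holdout <- seq_len(nrow(X)) > nrow(X) - n_hold
  }
  use <- if (is.null(holdout)) rep(TRUE, nrow(X)) else !holdout
  qrX <- qr(X[use, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf(paste0("rank-deficient identification design: term(s) %s are ",
                        "not excited. Impose motions spanning more distinct ",
                        "lengths/velocities and stimulation phases."),
                 paste(dropped, collapse = ", ")))
  }
  df <- data.frame(force_N = data$force_N[use], X[use, , drop = FALSE])
  fit <- stats::lm(force_N ~ . - 1, data = df)
  coefs <- stats::setNames(numeric(6),
                           c("offset", "length", "activation",
                             "activation_length", "velocity",
                             "activation_velocity"))
  coefs[terms] <- stats::coef(fit)
  se <- stats::setNames(rep(NA_real_, 6), names(coefs))
  se[terms] <- sqrt(diag(stats::vcov(fit)))
  eval_rows <- if (is.null(holdout)) use else holdout
  pred <- as.numeric(X_all[eval_rows, names(coefs), drop = FALSE] %*% coefs)
  y <- data$force_N[eval_rows]
  var_explained <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  params <- tryCatch(
    muscle_params(A = coefs[["offset"]], B = max(coefs[["length"]], 0),
                  C = coefs[["activation"]],
                  D = max(coefs[["activation_length"]], 0),
                  l0 = l0, tau_c = tau_c, tau_a = tau_a, ...),
    error = function(e) NULL, warning = function(w) NULL)
  structure(list(coefficients = coefs, se = se, params = params,
                 var_explained = var_explained,
                 in_sample = is.null(holdout), fit = fit, terms = terms),
            class = "ml_bilinear_fit")
}

#' @export
print.ml_bilinear_fit <- function(x, ...) {
  cat("<ml_bilinear_fit>\n  coefficients:\n")
  co <- x$coefficients[x$terms]
  for (nm in names(co)) cat(sprintf("    %-20s %12.6g\n", nm, co[nm]))
  cat(sprintf("  variance explained (%s): %.4f\n",
              if (x$in_sample) "in-sample" else "held-out", x$var_explained))
  invisible(x)
}

#' Write / read an identification dataset as CSV
#'
#' Columns: `time_s, length_m, velocity_m_s, activation_est, force_N`.
#' @param data The dataset tibble.
#' @param path File path.
#' @export
write_identification_dataset <- function(data, path) {
  cols <- c("time_s", "length_m", "velocity_m_s", "activation_est", "force_N")
  readr::write_csv(as.data.frame(data)[, cols], path)
  invisible(path)
}

#' @rdname write_identification_dataset
#' @export
read_identification_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
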