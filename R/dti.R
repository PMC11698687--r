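#' Conventional diffusion tensor fit (log-linear least squares)
#'
#' Fits log(S) = log(S0) - b g' D g by ordinary least squares and reports
#' the tensor and its mean diffusivity (ADC, um^2/ms). Non-positive
#' signals are clamped to a small positive floor before the log, with a
#' warning.
#'
#' @param signal numeric vector, one entry per scheme measurement.
#' @param scheme a `gradient_scheme` with at least 6 non-collinear
#'   weighted directions plus b0.
#' @return list with `tensor` (3x3 symmetric, um^2/ms), `adc` (mean of
#'   eigenvalues), `s0`.
#' @export
dti_fit <- function(signal, scheme) {
  if (length(signal) != n_measurements(scheme))
    stop("signal length does not match scheme", call. = FALSE)
  dwi <- scheme$bvals >= b0_threshold()
  if (sum(dwi) < 6L)
    stop("tensor fit needs at least 6 weighted directions", call. = FALSE)
  if (any(signal <= 0)) {
    warning("non-positive signals clamped before log-linear tensor fit")
    signal <- pmax(signal, 1e-8 * max(signal, 1e-12))
  }
  be <- b_eff(scheme$bvals)
  g <- scheme$bvecs
  X <- cbind(1,
             -be * g[1, ]^2, -be * g[2, ]^2, -be * g[3, ]^2,
             -2 * be * g[1, ] * g[2, ],
             -2 * be * g[1, ] * g[3, ],
             -2 * be * g[2, ] * g[3, ])
  qx <- qr(X)
  if (qx$rank < 7L)
    stop("gradient directions are too collinear for a tensor fit",
         call. = FALSE)
  beta <- qr.coef(qx, log(signal))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  list(tensor = D, adc = mean(diag(D)), s0 = exp(beta[1]))
}

#' ADC from a log-linear fit of signal decay vs b
#'
#' Direction-averaged scalar fit: regress log(S) on b over all
#' measurements. Used for the single-compartment summaries (e.g. the
#' restricted-sphere ADC).
#'
#' @param signal numeric vector.
#' @param bvals b-values, s/mm^2.
#' @return ADC in um^2/ms.
#' @export
adc_loglinear <- function(signal, bvals) {
  if (any(signal <= 0)) {
    warning("non-positive signals clamped before log fit")
    signal <- pmax(signal, 1e-12)
  }
  be <- b_eff(bvals)
  fit <- stats::lm.fit(cbind(1, -be), log(signal))
  unname(fit$coefficients[2])
}
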