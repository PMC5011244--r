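#' Signal-to-noise ratio of a reconstruction
#'
#' \eqn{SNR = 10 \log_{10}( \sum y^2 / \sum (\tilde y - y)^2 )} in dB,
#' where `y` is the clean signal and `yhat` the reconstruction.
#'
#' @param y clean reference signal.
#' @param yhat reconstructed signal of equal length.
#' @return SNR in dB; `Inf` (with a message attribute-free signal via
#'   `warning`) when the reconstruction is exact.
#' @export
snr_db <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  err <- sum((yhat - y)^2)
  if (err == 0) {
    warning("reconstruction is exact; SNR is infinite", call. = FALSE)
    return(Inf)
  }
  10 * log10(sum(y^2) / err)
}

#' Root-mean-square error of a reconstruction
#'
#' @inheritParams snr_db
#' @return `sqrt(mean((yhat - y)^2))` in signal units.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sqrt(mean((yhat - y)^2))
}

#' Calibration correlation coefficient R
#'
#' \eqn{R = \sqrt{1 - \sum(\hat y_i - y_i)^2 / \sum(\bar{\hat y} - y_i)^2}},
#' clipped at 0 when the residual sum exceeds the total sum. By default the
#' centring term \eqn{\bar{\hat y}} is the mean *prediction*; set
#' `center = "truth"` to centre on the mean of the true values instead (the
#' more common R2-style convention).
#'
#' @param y true values (length >= 2).
#' @param yhat predicted values.
#' @param center `"predictions"` (default) or `"truth"`.
#' @return R in \[0, 1\].
#' @export
r_coefficient <- function(y, yhat, center = c("predictions", "truth")) {
  center <- match.arg(center)
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  m <- if (center == "predictions") mean(yhat) else mean(y)
  ss_tot <- sum((m - y)^2)
  if (ss_tot == 0) stop("R undefined: zero total sum of squares", call. = FALSE)
  ss_res <- sum((yhat - y)^2)
  sqrt(max(0, 1 - ss_res / ss_tot))
}

#' Root-mean-square error of prediction
#'
#' \eqn{RMSEP = \sqrt{\sum(\hat y_i - y_i)^2 / (n - 1)}}. Note the `n - 1`
#' denominator (rather than the more common `n`), kept as the field's
#' prediction-error convention for cross-validated calibration sets.
#'
#' @inheritParams r_coefficient
#' @return RMSEP in the units of `y` (mg/dL for concentration models).
#' @export
rmsep <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sqrt(sum((yhat - y)^2) / (length(y) - 1))
}
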