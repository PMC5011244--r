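#' Correlative coefficient between two signals
#'
#' The Pearson product-moment correlation used to judge how much of the
#' measured signal a mode carries; dimensionless, in \[-1, 1\].
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return The correlation coefficient.
#' @export
#' @examples
#' correlative_coefficient(1:10, (1:10)^2)
correlative_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant signal (zero denominator)",
         call. = FALSE)
  cor(x, y)
}

#' Sensitive-mode selection threshold
#'
#' Given the per-mode (non-negative) correlative coefficients, the threshold
#' separating sensitive modes from false components is
#' \deqn{\mu_h = \frac{\max \mu_i}{10 \max \mu_i - 3}.}
#' The rule is only defined when `max(mu) > 0.3` (otherwise the denominator
#' is not positive); in that degenerate case keep the single mode of maximum
#' correlation instead.
#'
#' @param mu_used numeric vector of non-negative correlation magnitudes.
#' @return The threshold, a single number.
#' @export
#' @examples
#' selection_threshold(c(0.01, 0.1, 0.5))  # 0.25
selection_threshold <- function(mu_used) {
  stopifnot(is.numeric(mu_used), length(mu_used) >= 1)
  if (any(mu_used < 0)) stop("mu_used must be non-negative", call. = FALSE)
  m <- max(mu_used)
  if (m <= 0.3)
    stop("threshold undefined for max correlation <= 0.3; ",
         "keep the single mode with maximum correlation instead",
         call. = FALSE)
  m / (10 * m - 3)
}

.new_selection <- function(criterion, values, threshold, forced_drop, kept,
                           decomp, mu = NULL, mu_used = NULL) {
  rec <- if (length(kept) > 0)
    rowSums(decomp$imfs[, kept, drop = FALSE])
  else numeric(decomp$source_length)
  structure(list(criterion = criterion, mu = mu, mu_used = mu_used,
                 values = values, threshold = threshold,
                 forced_drop = forced_drop, kept = as.integer(kept),
                 nimf = decomp$nimf, reconstructed = rec,
                 residue = decomp$residue),
            class = "imf_selection")
}

#' @export
print.imf_selection <- function(x, ...) {
  cat(sprintf("IMF selection (%s): kept {%s} of %d modes\n",
              x$criterion, paste(x$kept, collapse = ", "), x$nimf))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold %.5f, forced leading drop %d\n",
                x$threshold, x$forced_drop))
  if (!is.null(x$values))
    cat("  criterion values:", paste(signif(x$values, 4), collapse = " "), "\n")
  invisible(x)
}

#' Select sensitive modes by correlative coefficient
#'
#' Computes the correlative coefficient between each IMF and the reference
#' (usually the measured, noisy signal), takes magnitudes so that strongly
#' anti-correlated modes count as correlated, derives the threshold with
#' [selection_threshold()] over *all* modes, and keeps the modes beyond the
#' first `forced_drop` whose magnitude exceeds the threshold. The leading
#' modes are dropped unconditionally because measurement noise concentrates
#' in the highest-frequency modes.
#'
#' @param decomp a `"mode_decomp"`.
#' @param reference numeric signal of matching length.
#' @param forced_drop number of leading modes excluded no matter their
#'   correlation (default 3).
#' @return An object of class `"imf_selection"` with fields `mu`, `mu_used`,
#'   `threshold`, `kept` and `reconstructed` (the exact sum of kept IMFs).
#' @export
select_sensitive <- function(decomp, reference, forced_drop = 3L) {
  stopifnot(inherits(decomp, "mode_decomp"), decomp$nimf >= 1)
  reference <- .check_signal(reference)
  if (length(reference) != decomp$source_length)
    stop("reference length must match the decomposed signal", call. = FALSE)
  mu <- apply(decomp$imfs, 2L, correlative_coefficient, y = reference)
  mu_used <- abs(mu)
  thr <- selection_threshold(mu_used)
  kept <- which(mu_used > thr)
  kept <- kept[kept > forced_drop]
  if (length(kept) == 0L)
    stop("no mode passes the threshold beyond the forced drop; ",
         "consider lowering forced_drop", call. = FALSE)
  .new_selection("corr", mu_used, thr, as.integer(forced_drop), kept, decomp,
                 mu = mu, mu_used = mu_used)
}

#' Select modes by the consecutive-mean-squared-error criterion
#'
#' A literature comparison criterion (not part of the correlative-coefficient
#' method): with partial reconstructions \eqn{\tilde x_k = \sum_{i=k}^K
#' IMF_i + residue}, the consecutive MSE between \eqn{\tilde x_k} and
#' \eqn{\tilde x_{k+1}} reduces to the mean power of mode `k`. The signal is
#' rebuilt from the mode `j*` at the *first* local minimum of this profile
#' (the demarcation where the decaying noise energy meets the signal modes;
#' the global minimum would degenerate to the vanishing trailing modes)
#' through the last mode.
#'
#' @inheritParams select_sensitive
#' @return An `"imf_selection"` with `criterion = "cmse"`.
#' @export
select_cmse <- function(decomp, reference = NULL) {
  stopifnot(inherits(decomp, "mode_decomp"))
  if (decomp$nimf < 2L)
    stop("CMSE selection needs at least 2 modes", call. = FALSE)
  cmse <- colMeans(decomp$imfs[, -decomp$nimf, drop = FALSE]^2)
  jstar <- length(cmse)                  # falls back to the last candidate
  for (k in seq_along(cmse)) {
    if (k == length(cmse) || cmse[k] <= cmse[k + 1]) { jstar <- k; break }
  }
  .new_selection("cmse", cmse, NULL, 0L, jstar:decomp$nimf, decomp)
}

# Normalized-histogram density of z on given breaks.
.hist_density <- function(z, breaks) {
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  list(mids = h$mids, p = p)
}

.fd_breaks <- function(reference, lo, hi) {
  nb <- max(8L, grDevices::nclass.FD(reference))
  seq(lo, hi, length.out = nb + 1L)
}

#' Select modes by Hausdorff distance between densities
#'
#' A literature comparison criterion: the probability density of each mode
#' (normalized histogram, Freedman-Diaconis bin count taken from the
#' reference) is compared with the density of the reference by the Hausdorff
#' distance between the two density curves, both axes scaled to \[0, 1\].
#' Modes cluster into signal-like (small distance) and noise-like (large
#' distance); the cut is placed at the largest gap in the sorted distances
#' and the small-distance group is kept.
#'
#' @inheritParams select_sensitive
#' @return An `"imf_selection"` with `criterion = "hd"`.
#' @export
select_hd <- function(decomp, reference) {
  stopifnot(inherits(decomp, "mode_decomp"), decomp$nimf >= 2L)
  reference <- .check_signal(reference)
  all_vals <- c(decomp$imfs, reference)
  lo <- min(all_vals); hi <- max(all_vals)
  if (hi <= lo) stop("degenerate densities", call. = FALSE)
  breaks <- .fd_breaks(reference, lo, hi)
  ref_d <- .hist_density(reference, breaks)
  xs <- (ref_d$mids - lo) / (hi - lo)    # support scaled to [0, 1]

  hausdorff <- function(pa, pb) {
    pm <- max(pa, pb)                    # scale the density axis jointly
    a <- cbind(xs, pa / pm)
    b <- cbind(xs, pb / pm)
    dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
    max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  }
  hd <- apply(decomp$imfs, 2L, function(m) {
    d <- .hist_density(m, breaks)
    hausdorff(d$p, ref_d$p)
  })
  ord <- order(hd)
  gaps <- diff(hd[ord])
  cut_at <- which.max(gaps)             # keep the low-distance cluster
  kept <- sort(ord[seq_len(cut_at)])
  .new_selection("hd", hd, hd[ord][cut_at], 0L, kept, decomp)
}

#' Select modes by mutual information with the reference
#'
#' A literature comparison criterion: histogram-estimated mutual information
#' between each mode and the reference; modes with above-average information
#' are kept.
#'
#' @inheritParams select_sensitive
#' @return An `"imf_selection"` with `criterion = "mi"`.
#' @export
select_mi <- function(decomp, reference) {
  stopifnot(inherits(decomp, "mode_decomp"), decomp$nimf >= 2L)
  reference <- .check_signal(reference)
  nb <- max(8L, grDevices::nclass.FD(reference))
  ry <- cut(reference, breaks = nb, labels = FALSE)
  mi <- apply(decomp$imfs, 2L, function(m) {
    if (max(m) <= min(m)) return(0)
    rx <- cut(m, breaks = nb, labels = FALSE)
    pj <- table(rx, ry) / length(rx)
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
  })
  thr <- mean(mi)
  kept <- which(mi > thr)
  if (length(kept) == 0L) kept <- which.max(mi)
  .new_selection("mi", mi, thr, 0L, kept, decomp)
}

#' Select modes by a named criterion
#'
#' @inheritParams select_sensitive
#' @param criterion `"corr"`, `"cmse"`, `"hd"` or `"mi"`.
#' @return An `"imf_selection"`.
#' @export
select_modes <- function(decomp, reference,
                         criterion = c("corr", "cmse", "hd", "mi"),
                         forced_drop = 3L) {
  criterion <- match.arg(criterion)
  switch(criterion,
         corr = select_sensitive(decomp, reference, forced_drop),
         cmse = select_cmse(decomp, reference),
         hd = select_hd(decomp, reference),
         mi = select_mi(decomp, reference))
}
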