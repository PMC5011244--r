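#' Sifting configuration
#'
#' Controls for the EMD inner loop shared by every decomposition variant.
#'
#' Two stopping rules are available for the sifting loop. The default
#' S-number rule (`criterion = "snumber"`) stops once the numbers of
#' extrema and zero crossings of the candidate differ by at most one and
#' have stayed unchanged over `s_number` consecutive passes; this is the
#' rule under which white noise splits into the classical dyadic filter
#' bank (each successive mode carrying roughly half the mean frequency of
#' its predecessor). The alternative Cauchy rule (`criterion = "sd"`) stops
#' when \eqn{\sum (h_{prev} - h)^2 / \sum h_{prev}^2 < }`stop_threshold`;
#' it sifts more shallowly and yields fewer, broader-band modes.
#' `max_siftings` caps either loop.
#'
#' Envelopes are natural cubic splines through the local extrema;
#' `boundary` chooses how they are anchored at the signal edges:
#' `"mirror"` reflects the two extrema nearest each edge across the end
#' points (suppresses edge swings), `"clamp"` adds the end samples
#' themselves to both envelopes.
#'
#' @param max_siftings maximum sifting passes per mode (default 100).
#' @param criterion `"snumber"` (default) or `"sd"`.
#' @param s_number consecutive stable passes required by the S-number rule
#'   (default 2; larger values sift deeper, sharpening the scale ladder but
#'   risking splitting one oscillation across neighbouring modes).
#' @param stop_threshold tolerance of the Cauchy rule (default 0.2).
#' @param max_imfs maximum number of modes to extract (`Inf` = until the
#'   residue has at most one interior extremum).
#' @param boundary `"mirror"` (default) or `"clamp"`.
#' @return An object of class `"sift_config"`.
#' @export
#' @examples
#' cfg <- sift_config(s_number = 6)
sift_config <- function(max_siftings = 100L,
                        criterion = c("snumber", "sd"),
                        s_number = 2L, stop_threshold = 0.2,
                        max_imfs = Inf, boundary = c("mirror", "clamp")) {
  boundary <- match.arg(boundary)
  criterion <- match.arg(criterion)
  stopifnot(stop_threshold > 0, max_siftings >= 1, max_imfs >= 1,
            s_number >= 1)
  structure(list(max_siftings = as.integer(max_siftings),
                 criterion = criterion,
                 s_number = as.integer(s_number),
                 stop_threshold = stop_threshold,
                 max_imfs = max_imfs,
                 boundary = boundary),
            class = "sift_config")
}

.boundary_code <- function(cfg) if (cfg$boundary == "clamp") 1L else 0L
.criterion_code <- function(cfg) if (cfg$criterion == "sd") 0L else 1L
.max_imfs_int <- function(cfg) {
  if (is.finite(cfg$max_imfs)) as.integer(cfg$max_imfs) else .Machine$integer.max
}

.check_signal <- function(x, min_len = 4L) {
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) < min_len)
    stop(sprintf("signal must have at least %d samples", min_len), call. = FALSE)
  if (any(!is.finite(x)))
    stop("signal contains non-finite samples", call. = FALSE)
  x
}

#' Locate strict local extrema
#'
#' Finds the interior local maxima and minima of a sampled signal. Plateaus
#' (runs of equal samples flanked by strictly lower/higher neighbours) are
#' resolved to a single representative sample at the plateau midpoint.
#'
#' @param x numeric vector, at least 4 finite samples.
#' @return A list with components `maxima` and `minima`, each a list with
#'   integer `idx` (1-based sample index) and numeric `val`.
#' @export
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))
find_extrema <- function(x) {
  x <- .check_signal(x)
  ex <- cpp_find_extrema(x)
  list(maxima = list(idx = as.integer(ex$max_idx) + 1L, val = ex$max_val),
       minima = list(idx = as.integer(ex$min_idx) + 1L, val = ex$min_val))
}

#' Local mean of a signal
#'
#' The mean of the upper and lower envelopes: natural cubic splines through
#' the local maxima and minima respectively, extended past the signal edges
#' according to `cfg$boundary`. This is the operator \eqn{M(\cdot)} used by
#' the improved-CEEMDAN recursion, and subtracting it is one sifting pass.
#'
#' @param x numeric signal.
#' @param cfg a [sift_config()].
#' @return Numeric vector the same length as `x`, or `NULL` when the signal
#'   has no interior maximum or no interior minimum (the residue condition;
#'   callers treat the signal as its own trend).
#' @export
#' @examples
#' t <- (0:511) / 512
#' m <- local_mean(cos(4 * pi * t) + sin(15 * pi * t))
local_mean <- function(x, cfg = sift_config()) {
  x <- .check_signal(x)
  m <- cpp_local_mean(x, .boundary_code(cfg))
  if (length(m) == 0L) return(NULL)
  m
}

#' Extract one candidate intrinsic mode function by sifting
#'
#' Repeatedly subtracts the local mean from the signal until the stopping
#' rule selected in `cfg` (S-number by default, Cauchy standard-deviation
#' otherwise) is met or `cfg$max_siftings` passes are spent.
#'
#' @inheritParams local_mean
#' @return A list with `imf` (numeric vector), `converged` (logical) and
#'   `n_siftings`. A degenerate input (no interior extrema) is returned
#'   unchanged with `converged = FALSE`.
#' @export
sift_imf <- function(x, cfg = sift_config()) {
  x <- .check_signal(x)
  s <- cpp_sift(x, .criterion_code(cfg), cfg$stop_threshold, cfg$s_number,
                cfg$max_siftings, .boundary_code(cfg))
  list(imf = s$imf, converged = s$converged, n_siftings = s$n_siftings)
}

.new_decomposition <- function(imfs, residue, method, source) {
  structure(list(imfs = imfs, residue = as.numeric(residue),
                 method = method, source_length = length(residue),
                 nimf = ncol(imfs), source = as.numeric(source)),
            class = "mode_decomp")
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs), ordered from
#' highest to lowest frequency, plus a residue with at most one interior
#' extremum. The sum of all IMFs and the residue reproduces the input exactly
#' (to numerical round-off).
#'
#' @inheritParams local_mean
#' @return An object of class `"mode_decomp"`: a list with `imfs` (matrix,
#'   one column per IMF), `residue`, `method`, `nimf`, `source_length` and
#'   the input `source`.
#' @seealso [eemd()], [ceemd()], [ceemdan()], [iceemdan()]
#' @export
#' @examples
#' t <- (0:1023) / 1024
#' d <- emd(cos(4 * pi * t) + sin(15 * pi * t))
#' d$nimf
emd <- function(x, cfg = sift_config()) {
  x <- .check_signal(x)
  res <- cpp_emd(x, .criterion_code(cfg), cfg$stop_threshold, cfg$s_number,
                 cfg$max_siftings, .max_imfs_int(cfg), .boundary_code(cfg))
  .new_decomposition(res$imfs, res$residue, "EMD", x)
}

#' j-th EMD mode of a signal
#'
#' The operator returning the j-th intrinsic mode function of the plain EMD
#' of its argument; a zero vector when fewer than `j` modes exist.
#'
#' @inheritParams local_mean
#' @param j mode index, >= 1.
#' @export
emd_mode <- function(x, j, cfg = sift_config()) {
  stopifnot(j >= 1)
  d <- emd(x, cfg)
  if (d$nimf < j) return(numeric(length(x)))
  d$imfs[, j]
}

#' Count sign changes of a sampled signal
#'
#' Zero samples are skipped so that a touch of zero between samples of equal
#' sign does not count as two crossings.
#'
#' @param x numeric vector.
#' @return Integer crossing count.
#' @export
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' @export
print.mode_decomp <- function(x, ...) {
  cat(sprintf("%s decomposition: %d IMF(s) + residue, signal length %d\n",
              x$method, x$nimf, x$source_length))
  if (x$nimf > 0) {
    en <- colMeans(x$imfs^2)
    cat("  IMF mean power:", paste(signif(en, 3), collapse = " "), "\n")
  }
  cat("  residue range:", paste(signif(range(x$residue), 3), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
plot.mode_decomp <- function(x, ...) {
  k <- x$nimf
  op <- graphics::par(mfrow = c(k + 2L, 1L), mar = c(1.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(x$source, type = "l", ylab = "signal", xlab = "", ...)
  if (k > 0)
    for (j in seq_len(k))
      graphics::plot(x$imfs[, j], type = "l", ylab = paste0("IMF", j), xlab = "")
  graphics::plot(x$residue, type = "l", ylab = "residue", xlab = "")
  invisible(x)
}

#' Reconstruct the input from a decomposition
#'
#' @param d a `"mode_decomp"`.
#' @param modes which IMFs to include (default all).
#' @param residue include the residue (default TRUE).
#' @return Numeric vector.
#' @export
reconstruct <- function(d, modes = seq_len(d$nimf), residue = TRUE) {
  stopifnot(inherits(d, "mode_decomp"))
  out <- if (residue) d$residue else numeric(d$source_length)
  if (length(modes) > 0 && d$nimf > 0)
    out <- out + rowSums(d$imfs[, modes, drop = FALSE])
  out
}
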