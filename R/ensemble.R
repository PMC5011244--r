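#' Ensemble decomposition configuration
#'
#' @param ensemble_size number of white-noise realizations `I` (default 100).
#' @param noise_strength amplitude of the added noise as a fraction of the
#'   signal standard deviation (default 0.2).
#' @param seed integer seed for the noise bank; decompositions are
#'   bit-reproducible given the same seed.
#' @param sift a [sift_config()] passed to every inner EMD.
#' @return Object of class `"ensemble_config"`.
#' @export
ensemble_config <- function(ensemble_size = 100L, noise_strength = 0.2,
                            seed = 1L, sift = sift_config()) {
  stopifnot(ensemble_size >= 1, noise_strength > 0)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_strength = noise_strength,
                 seed = as.integer(seed),
                 sift = sift),
            class = "ensemble_config")
}

# Evaluate expr under a local RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Bank of white-noise realizations
#'
#' Draws `I` independent standard-Gaussian vectors used by the ensemble
#' decompositions. Realizations are zero-mean unit-variance in expectation
#' (raw draws, not re-standardized) and fully reproducible from the seed.
#'
#' @param n signal length.
#' @param ensemble_size number of realizations.
#' @param seed integer seed.
#' @return `n` x `ensemble_size` numeric matrix, one realization per column.
#' @export
noise_bank <- function(n, ensemble_size, seed) {
  with_seed(seed, matrix(rnorm(n * ensemble_size), nrow = n))
}

# Average a list of IMF matrices (n x k_i) into a single n x max(k_i) matrix,
# zero-padding realizations that produced fewer modes.
.average_modes <- function(mode_list, n) {
  kmax <- max(vapply(mode_list, ncol, integer(1)))
  acc <- matrix(0, n, kmax)
  for (m in mode_list) {
    k <- ncol(m)
    if (k > 0) acc[, seq_len(k)] <- acc[, seq_len(k)] + m
  }
  acc / length(mode_list)
}

#' Ensemble empirical mode decomposition (EEMD)
#'
#' Decomposes `x + eps0 * sd(x) * w_i` with plain EMD for each of `I`
#' independent white-noise realizations `w_i` and averages the k-th modes
#' across realizations (realizations with fewer modes contribute zeros to
#' the missing ones). The residue is the average of the per-realization
#' residues, so the sum of modes plus residue reproduces the input only up
#' to the averaged noise, i.e. completeness is *not* exact.
#'
#' @param x numeric signal.
#' @param cfg an [ensemble_config()].
#' @return A `"mode_decomp"` with `method = "EEMD"`.
#' @export
eemd <- function(x, cfg = ensemble_config()) {
  x <- .check_signal(x)
  n <- length(x)
  amp <- cfg$noise_strength * sd(x)
  w <- noise_bank(n, cfg$ensemble_size, cfg$seed)
  runs <- vector("list", cfg$ensemble_size)
  resid <- matrix(0, n, cfg$ensemble_size)
  for (i in seq_len(cfg$ensemble_size)) {
    d <- emd(x + amp * w[, i], cfg$sift)
    runs[[i]] <- d$imfs
    resid[, i] <- d$residue
  }
  .new_decomposition(.average_modes(runs, n), rowMeans(resid), "EEMD", x)
}

#' Complementary ensemble empirical mode decomposition (CEEMD)
#'
#' Adds each white-noise realization with positive and negative sign,
#' decomposes both mixtures by EMD, and averages the modes over all
#' `2 * (I/2)` decompositions so that the added noise cancels in pairs.
#'
#' @inheritParams eemd
#' @return A `"mode_decomp"` with `method = "CEEMD"`.
#' @export
ceemd <- function(x, cfg = ensemble_config()) {
  x <- .check_signal(x)
  if (cfg$ensemble_size %% 2L != 0L)
    stop("CEEMD requires an even ensemble size (noise is added in +/- pairs)",
         call. = FALSE)
  n <- length(x)
  npairs <- cfg$ensemble_size %/% 2L
  amp <- cfg$noise_strength * sd(x)
  w <- noise_bank(n, npairs, cfg$seed)
  runs <- vector("list", 2L * npairs)
  resid <- matrix(0, n, 2L * npairs)
  for (i in seq_len(npairs)) {
    dp <- emd(x + amp * w[, i], cfg$sift)
    dm <- emd(x - amp * w[, i], cfg$sift)
    runs[[2L * i - 1L]] <- dp$imfs
    runs[[2L * i]] <- dm$imfs
    resid[, 2L * i - 1L] <- dp$residue
    resid[, 2L * i] <- dm$residue
  }
  .new_decomposition(.average_modes(runs, n), rowMeans(resid), "CEEMD", x)
}

# Full EMD of every noise realization, computed once and reused across
# stages (CEEMDAN needs E_k(w_i) for all k).
.noise_modes <- function(w, sift) {
  lapply(seq_len(ncol(w)), function(i) emd(w[, i], sift)$imfs)
}

.noise_mode_k <- function(noise_imfs, i, k, n) {
  m <- noise_imfs[[i]]
  if (ncol(m) >= k) m[, k] else numeric(n)
}

#' Complete ensemble empirical mode decomposition with adaptive noise
#'
#' CEEMDAN extracts one mode at a time: the first mode is the average first
#' EMD mode of `x + eps0 * sd(x) * w_i`; thereafter mode `k+1` is the average
#' first EMD mode of `r_k + eps_k * E_k(w_i)`, where `E_k` is the k-th EMD
#' mode operator and `r_k` the running residue. The noise scale at stage `k`
#' is `eps_k = eps0 * sd(r_k)` (adaptive, mirroring the definition of the
#' first-stage scale). Because each mode is subtracted from the residue as it
#' is extracted, the sum of modes plus final residue equals the input
#' exactly.
#'
#' @inheritParams eemd
#' @return A `"mode_decomp"` with `method = "CEEMDAN"`.
#' @export
ceemdan <- function(x, cfg = ensemble_config()) {
  x <- .check_signal(x)
  n <- length(x)
  I <- cfg$ensemble_size
  w <- noise_bank(n, I, cfg$seed)
  noise_imfs <- .noise_modes(w, cfg$sift)
  kmax <- .max_imfs_int(cfg$sift)
  bcode <- .boundary_code(cfg$sift)

  # stage 1: average first mode of x + eps0*sd(x)*w_i
  amp <- cfg$noise_strength * sd(x)
  imf1 <- rowMeans(vapply(seq_len(I), function(i) {
    cpp_sift(x + amp * w[, i], .criterion_code(cfg$sift),
             cfg$sift$stop_threshold, cfg$sift$s_number,
             cfg$sift$max_siftings, bcode)$imf
  }, numeric(n)))
  imfs <- list(imf1)
  r <- x - imf1

  k <- 1L
  tiny <- 1e-12 * sd(x)
  while (length(imfs) < kmax && cpp_n_interior_extrema(r) >= 2L) {
    eps_k <- cfg$noise_strength * sd(r)
    nxt <- rowMeans(vapply(seq_len(I), function(i) {
      ek <- .noise_mode_k(noise_imfs, i, k, n)
      s <- sd(ek)
      mix <- if (s > 0) r + (eps_k / s) * ek else r
      cpp_sift(mix, .criterion_code(cfg$sift), cfg$sift$stop_threshold,
               cfg$sift$s_number, cfg$sift$max_siftings, bcode)$imf
    }, numeric(n)))
    if (sd(nxt) <= tiny) break          # no extractable oscillation left
    imfs <- c(imfs, list(nxt))
    r <- r - nxt
    k <- k + 1L
  }
  .new_decomposition(do.call(cbind, imfs), r, "CEEMDAN", x)
}

#' Improved CEEMDAN
#'
#' The improved variant estimates each residue as the average *local mean*
#' (envelope mean) of noise-perturbed copies, and defines each mode as the
#' difference of successive residues, which removes much of the residual
#' noise and the spurious early modes of plain CEEMDAN:
#' \itemize{
#'   \item `r_1 = <M(x + beta0_i * E_1(w_i))>` with
#'     `beta0_i = eps0 * sd(x) / sd(E_1(w_i))`, and `IMF_1 = x - r_1`;
#'   \item `r_k = <M(r_(k-1) + beta_(k-1) * E_k(w_i))>` with
#'     `beta_k = eps0 * sd(r_k)`, and `IMF_k = r_(k-1) - r_k`.
#' }
#' `M` is the local-mean operator ([local_mean()]) and `E_k` the k-th EMD
#' mode operator. Completeness is exact by construction.
#'
#' @inheritParams eemd
#' @return A `"mode_decomp"` with `method = "ICEEMDAN"`.
#' @export
iceemdan <- function(x, cfg = ensemble_config()) {
  x <- .check_signal(x)
  n <- length(x)
  I <- cfg$ensemble_size
  w <- noise_bank(n, I, cfg$seed)
  noise_imfs <- .noise_modes(w, cfg$sift)
  kmax <- .max_imfs_int(cfg$sift)
  bcode <- .boundary_code(cfg$sift)

  # M(s) = s - E_1(s): the local mean left after removing the fully sifted
  # first mode (consistent with the operator identity E_1 = id - M)
  mean_of_local_means <- function(base, scale_fun, k) {
    acc <- numeric(n)
    for (i in seq_len(I)) {
      ek <- .noise_mode_k(noise_imfs, i, k, n)
      mix <- base + scale_fun(i, ek) * ek
      if (cpp_n_interior_extrema(mix) >= 2L) {
        e1 <- cpp_sift(mix, .criterion_code(cfg$sift),
                       cfg$sift$stop_threshold, cfg$sift$s_number,
                       cfg$sift$max_siftings, bcode)$imf
        acc <- acc + (mix - e1)
      } else acc <- acc + mix          # no extrema: signal is its own trend
    }
    acc / I
  }

  sdx <- sd(x)
  r <- mean_of_local_means(x, function(i, ek) {
    s <- sd(ek)
    if (s > 0) cfg$noise_strength * sdx / s else 0
  }, k = 1L)
  imfs <- list(x - r)

  # the decomposition cannot probe scales beyond those present in the noise
  # realizations themselves, so the noise mode count bounds the stage count
  kcap <- max(vapply(noise_imfs, ncol, integer(1)))
  k <- 2L
  tiny <- 1e-12 * sdx
  while (length(imfs) < kmax && k <= kcap &&
         cpp_n_interior_extrema(r) >= 2L) {
    beta <- cfg$noise_strength * sd(r)
    r_next <- mean_of_local_means(r, function(i, ek) {
      s <- sd(ek)
      if (s > 0) beta / s else 0
    }, k = k)
    mode_k <- r - r_next
    if (sd(mode_k) <= tiny) break       # local-mean fixed point reached
    imfs <- c(imfs, list(mode_k))
    r <- r_next
    k <- k + 1L
  }
  .new_decomposition(do.call(cbind, imfs), r, "ICEEMDAN", x)
}

#' Decompose a signal by name
#'
#' Dispatch helper used by the benchmark drivers.
#'
#' @param x numeric signal.
#' @param method one of `"emd"`, `"eemd"`, `"ceemd"`, `"ceemdan"`,
#'   `"iceemdan"`.
#' @param cfg an [ensemble_config()] (its `sift` component is used for plain
#'   EMD).
#' @return A `"mode_decomp"`.
#' @export
decompose <- function(x, method = c("iceemdan", "emd", "eemd", "ceemd",
                                    "ceemdan"),
                      cfg = ensemble_config()) {
  method <- match.arg(method)
  switch(method,
         emd = emd(x, cfg$sift),
         eemd = eemd(x, cfg),
         ceemd = ceemd(x, cfg),
         ceemdan = ceemdan(x, cfg),
         iceemdan = iceemdan(x, cfg))
}
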