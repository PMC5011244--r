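#' Two-tone benchmark signal
#'
#' The benchmark signal \eqn{y(t) = \cos(4\pi t) + \sin(15\pi t)} sampled at
#' \eqn{t_k = k/N}, \eqn{k = 0, \dots, N-1} (2 and 7.5 cycles of the slow
#' and fast tone over the record).
#'
#' @param N number of samples (default 1024).
#' @return Numeric vector of length `N`.
#' @export
#' @examples
#' y <- simulated_signal()
#' length(y)
simulated_signal <- function(N = 1024L) {
  stopifnot(N >= 8)
  t <- (seq_len(N) - 1L) / N
  cos(4 * pi * t) + sin(15 * pi * t)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' Draws standard Gaussian noise and rescales it deterministically so that
#' \eqn{10\log_{10}(\sum y^2 / \sum e^2)} equals `snr_db` exactly.
#'
#' @param y clean signal.
#' @param snr_db target SNR in dB (finite; use the clean signal directly for
#'   a noiseless run).
#' @param seed integer seed.
#' @return `y` plus scaled noise.
#' @export
add_noise_snr <- function(y, snr_db = 5, seed = 1L) {
  stopifnot(is.finite(snr_db))
  e <- with_seed(seed, rnorm(length(y)))
  alpha <- sqrt(sum(y^2) / (sum(e^2) * 10^(snr_db / 10)))
  y + alpha * e
}

#' Synthetic spectra generator configuration
#'
#' Defaults emulate a glucose-solution transmission experiment: 15 samples
#' with concentrations evenly spanning 50-1000 mg/dL, spectra over
#' 833-2630 nm on 500 channels, each sample measured 5 times and averaged.
#' Absorbance follows a Beer-Lambert response: concentration-proportional
#' Gaussian analyte bands (near the first-overtone and combination regions)
#' overlaid on concentration-independent interferent bands, a smooth
#' low-order polynomial baseline drift per sample, and iid Gaussian noise
#' per replicate.
#'
#' @param n_samples number of solution samples (default 15).
#' @param conc_range concentration range in mg/dL (default `c(50, 1000)`,
#'   spanned evenly by `n_samples` levels).
#' @param wl_range wavelength range in nm (default `c(833, 2630)`).
#' @param n_channels number of wavelength channels (default 500).
#' @param band_centers,band_widths,band_strengths analyte band parameters
#'   (nm, nm, absorbance units at 1000 mg/dL; overtone/combination analyte
#'   bands are weak next to the water background, a few hundredths of an
#'   absorbance unit at the top concentration).
#' @param interferent_centers,interferent_widths,interferent_strengths
#'   concentration-independent bands (e.g. water absorption).
#' @param baseline_amplitude scale of the random per-sample polynomial
#'   drift (absorbance units, default 0.02).
#' @param n_replicates measurements averaged per sample (default 5).
#' @param noise_sd per-replicate Gaussian noise standard deviation
#'   (absorbance units, default 0.005).
#' @param seed integer seed.
#' @return Object of class `"spectra_gen_config"`.
#' @export
spectra_gen_config <- function(n_samples = 15L,
                               conc_range = c(50, 1000),
                               wl_range = c(833, 2630),
                               n_channels = 500L,
                               band_centers = c(1600, 2100, 2270),
                               band_widths = c(70, 110, 60),
                               band_strengths = c(0.04, 0.05, 0.03),
                               interferent_centers = c(1450, 1940),
                               interferent_widths = c(90, 120),
                               interferent_strengths = c(0.5, 0.7),
                               baseline_amplitude = 0.02,
                               n_replicates = 5L,
                               noise_sd = 0.005,
                               seed = 1L) {
  stopifnot(n_samples >= 3, n_channels >= 16, n_replicates >= 1,
            noise_sd >= 0, baseline_amplitude >= 0,
            all(band_strengths >= 0), all(interferent_strengths >= 0),
            length(band_centers) == length(band_widths),
            length(band_centers) == length(band_strengths))
  structure(as.list(environment()), class = "spectra_gen_config")
}

#' Generate synthetic glucose-solution NIR spectra
#'
#' See [spectra_gen_config()] for the generative model. The returned
#' dataset holds the replicate-averaged spectra (the calibration inputs);
#' the raw replicates and the noiseless clean spectra are attached for
#' testing the averaging and identifiability properties.
#'
#' @param cfg a [spectra_gen_config()].
#' @return A [spectra_dataset()] with extra fields `replicates` (a list of
#'   per-sample replicate matrices) and `clean` (the noiseless absorbance
#'   matrix).
#' @export
synthetic_spectra <- function(cfg = spectra_gen_config()) {
  stopifnot(inherits(cfg, "spectra_gen_config"))
  wl <- seq(cfg$wl_range[1], cfg$wl_range[2], length.out = cfg$n_channels)
  conc <- seq(cfg$conc_range[1], cfg$conc_range[2],
              length.out = cfg$n_samples)
  gauss <- function(center, width) exp(-(wl - center)^2 / (2 * width^2))
  analyte_shape <- numeric(cfg$n_channels)
  for (b in seq_along(cfg$band_centers))
    analyte_shape <- analyte_shape +
      cfg$band_strengths[b] * gauss(cfg$band_centers[b], cfg$band_widths[b])
  interf <- numeric(cfg$n_channels)
  for (b in seq_along(cfg$interferent_centers))
    interf <- interf + cfg$interferent_strengths[b] *
      gauss(cfg$interferent_centers[b], cfg$interferent_widths[b])

  with_seed(cfg$seed, {
    u <- (wl - mean(wl)) / (diff(range(wl)) / 2)    # wavelength in [-1, 1]
    clean <- matrix(0, cfg$n_samples, cfg$n_channels)
    avg <- matrix(0, cfg$n_samples, cfg$n_channels)
    reps <- vector("list", cfg$n_samples)
    for (s in seq_len(cfg$n_samples)) {
      baseline <- if (cfg$baseline_amplitude > 0) {
        co <- rnorm(3L, sd = cfg$baseline_amplitude)
        co[1] + co[2] * u + co[3] * u^2
      } else numeric(cfg$n_channels)
      clean[s, ] <- conc[s] / 1000 * analyte_shape + interf + baseline
      R <- matrix(0, cfg$n_replicates, cfg$n_channels)
      for (r in seq_len(cfg$n_replicates))
        R[r, ] <- clean[s, ] + rnorm(cfg$n_channels, sd = cfg$noise_sd)
      reps[[s]] <- R
      avg[s, ] <- colMeans(R)
    }
    ds <- spectra_dataset(wl, avg, conc)
    ds$replicates <- reps
    ds$clean <- clean
    ds
  })
}
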