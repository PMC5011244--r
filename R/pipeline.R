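#' Denoising benchmark on the two-tone signal
#'
#' For every combination of decomposition method, selection criterion and
#' noise seed: generate the clean benchmark signal ([simulated_signal()]),
#' add white Gaussian noise at `snr_db` ([add_noise_snr()]), decompose,
#' select modes against the noisy signal, reconstruct from the kept modes,
#' and score the reconstruction against the *clean* signal with
#' [snr_db()], [rmse()] and [correlative_coefficient()]. Cells where a stage
#' fails are recorded and the run continues.
#'
#' @param seeds integer vector of noise seeds.
#' @param methods decomposition methods (subset of
#'   `c("emd","eemd","ceemd","ceemdan","iceemdan")`).
#' @param criteria selection criteria (subset of
#'   `c("corr","cmse","hd","mi")`).
#' @param noise_snr_db input SNR of the added noise in dB (default 5).
#' @param N signal length (default 1024).
#' @param ensemble_size ensemble size for the noise-assisted methods
#'   (default 100).
#' @param noise_strength ensemble noise strength (default 0.2).
#' @param forced_drop leading modes always removed by the correlative
#'   criterion (default 3).
#' @param reference which signal the selection correlates modes against:
#'   `"clean"` (default; the known noise-free benchmark signal, the
#'   "original signal" of the simulation study) or `"noisy"` (the measured
#'   signal, as one would do when no clean version exists).
#' @param sift a [sift_config()].
#' @return A list of class `"denoise_benchmark"`: `runs` (one row per
#'   (method, criterion, seed) with snr/rmse/rho) and `summary` (mean and sd
#'   per cell).
#' @export
run_benchmark <- function(seeds = 1:10,
                          methods = c("emd", "eemd", "ceemd", "ceemdan",
                                      "iceemdan"),
                          criteria = "corr",
                          noise_snr_db = 5, N = 1024L,
                          ensemble_size = 100L, noise_strength = 0.2,
                          forced_drop = 3L,
                          reference = c("clean", "noisy"),
                          sift = sift_config()) {
  reference <- match.arg(reference)
  stopifnot(length(seeds) >= 1, length(methods) >= 1, length(criteria) >= 1)
  clean <- simulated_signal(N)
  rows <- list()
  for (seed in seeds) {
    noisy <- add_noise_snr(clean, noise_snr_db, seed = seed)
    for (method in methods) {
      cfg <- ensemble_config(ensemble_size = ensemble_size,
                             noise_strength = noise_strength,
                             seed = seed, sift = sift)
      d <- decompose(noisy, method, cfg)
      for (crit in criteria) {
        row <- data.frame(method = method, criterion = crit, seed = seed,
                          nimf = d$nimf, snr = NA_real_, rmse = NA_real_,
                          rho = NA_real_, kept = NA_character_,
                          error = NA_character_,
                          stringsAsFactors = FALSE)
        ref <- if (reference == "clean") clean else noisy
        sel <- tryCatch(select_modes(d, ref, crit,
                                     forced_drop = forced_drop),
                        error = function(e) conditionMessage(e))
        if (is.character(sel)) {
          row$error <- sel
        } else {
          rec <- sel$reconstructed
          row$snr <- snr_db(clean, rec)
          row$rmse <- rmse(clean, rec)
          row$rho <- correlative_coefficient(clean, rec)
          row$kept <- paste(sel$kept, collapse = ",")
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  runs <- do.call(rbind, rows)
  ok <- stats::aggregate(cbind(snr, rmse, rho) ~ method + criterion,
                         data = runs,
                         FUN = function(v) c(mean = mean(v), sd = sd(v)),
                         na.action = stats::na.omit)
  structure(list(runs = runs, summary = ok), class = "denoise_benchmark")
}

#' @export
print.denoise_benchmark <- function(x, ...) {
  cat("Denoising benchmark (mean over seeds):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %-5s SNR %7.4f dB  RMSE %6.4f  rho %6.4f\n",
                s$method[i], s$criterion[i],
                s$snr[i, "mean"], s$rmse[i, "mean"], s$rho[i, "mean"]))
  invisible(x)
}

#' Calibration study on a spectra dataset
#'
#' Mirrors the four-way model comparison of the glucose experiment on one
#' dataset: PLS and PSO-SVR, each on the raw spectra and on the
#' improved-CEEMDAN-denoised spectra, all assessed by leave-one-out
#' cross-validation. Hyperparameters (the PLS component count, the PSO-SVR
#' (epsilon, C, gamma)) are tuned once on the full dataset by internal
#' cross-validation, then held fixed across the outer LOO folds.
#'
#' @param dataset a [spectra_dataset()].
#' @param seed integer seed driving the denoising noise bank and the PSO.
#' @param pso a [pso_config()] (its seed is overridden by `seed`).
#' @param denoise_cfg [ensemble_config()] for the spectrum denoising (its
#'   seed is overridden by `seed`).
#' @param forced_drop leading modes dropped in the per-spectrum selection.
#' @param max_pls_components upper bound for the PLS component search.
#' @return A list of class `"calibration_study"` with a 4-row `summary`
#'   data frame (method, R, RMSEP) and the per-method
#'   `"calibration_report"`s in `reports`.
#' @export
run_calibration_study <- function(dataset, seed = 1L,
                                  pso = pso_config(),
                                  denoise_cfg = ensemble_config(),
                                  forced_drop = 3L,
                                  max_pls_components = 10L) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  pso$seed <- as.integer(seed)
  denoise_cfg$seed <- as.integer(seed)
  den <- denoise_spectra(dataset, denoise_cfg, forced_drop = forced_drop)

  fit_pls <- function(X, y) {
    k <- pls_select_ncomp(X, y, max_components = max_pls_components)
    function(Xt, yt) pls_fit(Xt, yt, n_components = min(k, nrow(Xt) - 1L,
                                                        ncol(Xt)))
  }
  fit_svr <- function(X, y) {
    tuned <- pso_svr(X, y, pso = pso)
    function(Xt, yt) {
      sc <- .column_scaler(Xt)
      ym <- mean(yt); ys <- sd(yt)
      m <- svr_train(sc$transform(Xt), (yt - ym) / ys, tuned$hyper)
      structure(list(model = m, scaler = sc, y_mean = ym, y_sd = ys,
                     hyper = tuned$hyper, trace = tuned$trace,
                     cv_rmse = NA_real_, model_kind = "SVR"),
                class = "pso_svr")
    }
  }

  variants <- list(
    `PLS` = list(data = dataset, maker = fit_pls),
    `ICEEMDAN-PLS` = list(data = den, maker = fit_pls),
    `PSO-SVR` = list(data = dataset, maker = fit_svr),
    `ICEEMDAN-PSO-SVR` = list(data = den, maker = fit_svr))

  reports <- lapply(variants, function(v) {
    X <- v$data$absorbance
    y <- v$data$concentrations
    loocv(X, y, v$maker(X, y))
  })
  summary <- data.frame(method = names(reports),
                        R = vapply(reports, function(r) r$R, numeric(1)),
                        RMSEP = vapply(reports, function(r) r$RMSEP,
                                       numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, reports = reports, seed = seed),
            class = "calibration_study")
}

#' @export
print.calibration_study <- function(x, ...) {
  cat("Calibration study (LOOCV):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s R %.7f  RMSEP %8.4f\n", s$method[i], s$R[i],
                s$RMSEP[i]))
  invisible(x)
}
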