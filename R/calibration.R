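#' Spectra dataset container
#'
#' Bundles a wavelength grid, an absorbance matrix and the reference
#' concentrations of a transmission-spectroscopy calibration set.
#'
#' @param wavelengths strictly increasing numeric vector (nm).
#' @param absorbance samples x channels numeric matrix.
#' @param concentrations reference concentrations (mg/dL), one per row of
#'   `absorbance`.
#' @param ids optional sample identifiers.
#' @return Object of class `"spectra_dataset"`.
#' @export
spectra_dataset <- function(wavelengths, absorbance, concentrations,
                            ids = NULL) {
  absorbance <- as.matrix(absorbance)
  stopifnot(is.numeric(wavelengths), all(diff(wavelengths) > 0),
            ncol(absorbance) == length(wavelengths),
            nrow(absorbance) == length(concentrations),
            all(is.finite(absorbance)), all(is.finite(concentrations)))
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(absorbance)))
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance,
                 concentrations = as.numeric(concentrations),
                 ids = as.character(ids)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(paste0("Spectra dataset: %d samples x %d channels, ",
                     "%g-%g nm, concentrations %g-%g mg/dL\n"),
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelengths), max(x$wavelengths),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Denoise every spectrum of a dataset by improved CEEMDAN reconstruction
#'
#' Each sample's spectrum is decomposed independently with [iceemdan()] and
#' rebuilt by [denoise_signal()]: the leading `forced_drop` modes (where
#' broadband instrument noise concentrates) are discarded and the remaining
#' modes plus the residue — the smooth trend that carries most of the
#' absorbance signal — are summed.
#'
#' Per-sample noise seeds are derived deterministically from `cfg$seed`, so
#' the whole preprocessing step is reproducible.
#'
#' @param dataset a [spectra_dataset()].
#' @param cfg an [ensemble_config()]; its seed controls the noise bank.
#' @param forced_drop leading (highest-frequency) modes always removed
#'   (default 3).
#' @param use_threshold see [denoise_signal()] (default FALSE).
#' @return A new `"spectra_dataset"` with denoised absorbances.
#' @export
denoise_spectra <- function(dataset, cfg = ensemble_config(),
                            forced_drop = 3L, use_threshold = FALSE) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  A <- dataset$absorbance
  out <- A
  for (s in seq_len(nrow(A))) {
    cfg_s <- cfg
    cfg_s$seed <- cfg$seed + s
    out[s, ] <- denoise_signal(A[s, ], cfg_s, forced_drop = forced_drop,
                               use_threshold = use_threshold)
  }
  spectra_dataset(dataset$wavelengths, out, dataset$concentrations,
                  dataset$ids)
}

#' Denoise one signal by improved CEEMDAN reconstruction
#'
#' Decomposes the signal with [iceemdan()] and rebuilds it from the modes
#' beyond the first `forced_drop` (where broadband measurement noise
#' concentrates) plus the residue. With `use_threshold = TRUE` the
#' correlative-coefficient threshold of [select_sensitive()] additionally
#' prunes the remaining oscillatory modes; this is appropriate when the
#' reference is dominated by the structure of interest, but on absorbance
#' spectra — whose correlation budget is taken up by the large interferent
#' bands — it can misclassify weak analyte-band modes, so it is off by
#' default.
#'
#' @param x numeric signal.
#' @param cfg an [ensemble_config()].
#' @param forced_drop leading modes always removed.
#' @param use_threshold apply the correlative threshold on top of the
#'   forced drop (default FALSE).
#' @return The denoised signal (kept modes + residue).
#' @export
denoise_signal <- function(x, cfg = ensemble_config(), forced_drop = 3L,
                           use_threshold = FALSE) {
  d <- iceemdan(x, cfg)
  if (d$nimf <= forced_drop) return(d$residue)
  if (use_threshold) {
    sel <- tryCatch(select_sensitive(d, x, forced_drop = forced_drop),
                    error = function(e) NULL)
    if (!is.null(sel)) return(sel$reconstructed + d$residue)
  }
  reconstruct(d, modes = (forced_drop + 1L):d$nimf, residue = TRUE)
}

# Fold assignment for internal cross-validation: LOO when n <= 20, else
# seeded 5-fold.
.cv_folds <- function(n, seed) {
  if (n <= 20L) return(seq_len(n))
  with_seed(seed, sample(rep_len(seq_len(5L), n)))
}

# Cross-validated root-mean-square prediction error of an SVR at `hyper`.
.svr_cv_rmse <- function(X, y, hyper, folds) {
  pred <- numeric(length(y))
  for (f in unique(folds)) {
    hold <- folds == f
    fit <- tryCatch(svr_train(X[!hold, , drop = FALSE], y[!hold], hyper),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Fit an SVR with particle-swarm-optimized hyperparameters
#'
#' Searches (epsilon, C, gamma) by [pso_optimize()] with the cross-validated
#' root-mean-square prediction error as fitness, then retrains on all
#' samples at the best hyperparameters. Particles move over
#' `epsilon in [0, 0.2]` (on the standardized response scale), `C in
#' [1, 1e8]` (searched in log10 space, since the range spans 8 decades) and
#' `gamma in [0.01, 2]`. The response is standardized internally so that the
#' epsilon tube bound is meaningful across concentration scales; predictions
#' are returned on the original scale. Feature columns are mean-centred
#' only: centring leaves the pairwise distances that enter the RBF kernel
#' unchanged, whereas variance scaling would inflate them past the searched
#' gamma range.
#'
#' The internal fitness cross-validation is leave-one-out for `n <= 20`
#' samples and seeded 5-fold otherwise.
#'
#' @param X predictor matrix (rows = samples) or a [spectra_dataset()].
#' @param y response (ignored when `X` is a dataset).
#' @param pso a [pso_config()].
#' @return Object of class `"pso_svr"` wrapping the final `"svr_model"`,
#'   with `hyper`, `trace` (global best fitness per iteration) and the
#'   scaling used.
#' @export
pso_svr <- function(X, y = NULL, pso = pso_config()) {
  if (inherits(X, "spectra_dataset")) {
    y <- X$concentrations
    X <- X$absorbance
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) >= 3, nrow(X) == length(y))
  sc <- .column_scaler(X)
  Xs <- sc$transform(X)
  ym <- mean(y); ys <- sd(y)
  if (ys == 0) stop("constant response", call. = FALSE)
  yn <- (y - ym) / ys
  folds <- .cv_folds(length(y), pso$seed)

  # The RBF kernel sees X only through pairwise distances, and n samples
  # span at most an n-dimensional subspace: projecting onto the SVD basis
  # preserves every distance exactly while shrinking the matrices the
  # solver handles during the search.
  sv <- svd(Xs, nu = 0)
  r <- max(1L, sum(sv$d > sv$d[1] * 1e-12))
  Z <- Xs %*% sv$v[, seq_len(r), drop = FALSE]

  fitness <- function(p) {
    hyper <- svr_hyper(epsilon = p[1], C = 10^p[2], gamma = p[3])
    .svr_cv_rmse(Z, yn, hyper, folds)
  }
  opt <- pso_optimize(fitness, lower = c(0, 0, 0.01), upper = c(0.2, 8, 2),
                      cfg = pso)
  if (!is.finite(opt$value))
    stop("PSO-SVR failed: no particle produced a finite fitness", call. = FALSE)
  hyper <- svr_hyper(epsilon = opt$par[1], C = 10^opt$par[2],
                     gamma = opt$par[3])
  fit <- svr_train(Xs, yn, hyper)
  structure(list(model = fit, hyper = hyper, trace = opt$trace,
                 scaler = sc, y_mean = ym, y_sd = ys,
                 cv_rmse = opt$value * ys, model_kind = "SVR"),
            class = "pso_svr")
}

# Column centring only: centring leaves pairwise distances (and hence the
# RBF kernel) unchanged, while variance scaling would inflate distances to
# O(sqrt(channels)) and push them outside the searched gamma range.
.column_scaler <- function(X) {
  mu <- colMeans(X)
  list(transform = function(M) sweep(as.matrix(M), 2L, mu), mean = mu)
}

#' @export
predict.pso_svr <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_dataset")) newdata <- newdata$absorbance
  p <- predict(object$model, object$scaler$transform(newdata))
  p * object$y_sd + object$y_mean
}

#' @export
print.pso_svr <- function(x, ...) {
  cat(sprintf(paste0("PSO-SVR: epsilon = %.4g, C = %.4g, gamma = %.4g ",
                     "(CV RMSE %.4g)\n"),
              x$hyper$epsilon, x$hyper$C, x$hyper$gamma, x$cv_rmse))
  invisible(x)
}

#' Leave-one-out cross-validation of a calibration method
#'
#' Each sample in turn is predicted by a model trained on all the others;
#' the held-out predictions are aggregated into the calibration correlation
#' coefficient [r_coefficient()] and [rmsep()]. A fold whose fit fails is
#' recorded and its prediction set to `NA` (and excluded from the
#' aggregates).
#'
#' @param X predictor matrix or [spectra_dataset()].
#' @param y response (ignored when `X` is a dataset).
#' @param fit_fn function(X_train, y_train) returning a model.
#' @param predict_fn function(model, X_test) returning predictions
#'   (default calls [predict()]).
#' @return Object of class `"calibration_report"`: `R`, `RMSEP`,
#'   `predictions`, `truth`, `failed` (fold indices).
#' @export
loocv <- function(X, y = NULL, fit_fn, predict_fn = function(m, Xt) predict(m, Xt)) {
  if (inherits(X, "spectra_dataset")) {
    y <- X$concentrations
    X <- X$absorbance
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n >= 3, nrow(X) == n)
  pred <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    m <- tryCatch(fit_fn(X[-i, , drop = FALSE], y[-i]),
                  error = function(e) NULL)
    if (is.null(m)) { failed <- c(failed, i); next }
    p <- tryCatch(predict_fn(m, X[i, , drop = FALSE]),
                  error = function(e) NA_real_)
    pred[i] <- as.numeric(p)[1]
  }
  ok <- is.finite(pred)
  structure(list(R = if (sum(ok) >= 2) r_coefficient(y[ok], pred[ok])
                     else NA_real_,
                 RMSEP = if (sum(ok) >= 2) rmsep(y[ok], pred[ok])
                         else NA_real_,
                 predictions = pred, truth = y, failed = failed,
                 n_folds = n),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("LOOCV calibration report: R = %.7f, RMSEP = %.4f (%d folds%s)\n",
              x$R, x$RMSEP, x$n_folds,
              if (length(x$failed)) paste0(", ", length(x$failed), " failed")
              else ""))
  invisible(x)
}

#' Choose the PLS component count by leave-one-out RMSEP
#'
#' @param X predictor matrix.
#' @param y response.
#' @param max_components largest count to try (capped by the data rank
#'   bound `min(n - 2, p)` so that every LOO fold can fit it).
#' @return The component count with the smallest LOO RMSEP.
#' @export
pls_select_ncomp <- function(X, y, max_components = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  sv <- svd(sweep(X, 2L, colMeans(X)), nu = 0, nv = 0)
  rank_x <- max(1L, sum(sv$d > sv$d[1] * 1e-10))
  kmax <- min(max_components, n - 2L, ncol(X), rank_x)
  errs <- vapply(seq_len(kmax), function(k) {
    rep <- loocv(X, y, function(Xt, yt) pls_fit(Xt, yt, n_components = k))
    rep$RMSEP
  }, numeric(1))
  which.min(errs)
}
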