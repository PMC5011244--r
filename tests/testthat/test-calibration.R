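test_that("RBF kernel follows the 2 gamma^2 convention and is symmetric", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, gamma = 0.5), 1)
  a <- c(0, 0); b <- c(1, 1)           # ||a-b|| = sqrt(2) = gamma*sqrt(2)
  expect_equal(rbf_kernel(a, b, gamma = 1), exp(-1))
  for (i in 1:20) {
    u <- with_seed(i, rnorm(5)); v <- with_seed(100 + i, rnorm(5))
    expect_equal(rbf_kernel(u, v, 0.7), rbf_kernel(v, u, 0.7))
  }
})

test_that("SVR fits a flat function inside the tube and respects the box constraint", {
  X <- matrix(with_seed(1, rnorm(20)), ncol = 1)
  m <- svr_train(X, rep(3, 20), svr_hyper(epsilon = 0.1, C = 10, gamma = 1))
  expect_true(all(abs(predict(m, X) - 3) <= 0.1 + 1e-6))
  expect_true(all(abs(m$dual_coef) <= 10 + 1e-9))

  # interpolation regime on a line
  X2 <- matrix(seq(0, 1, length.out = 25), ncol = 1)
  y2 <- as.numeric(X2)
  m2 <- svr_train(X2, y2, svr_hyper(epsilon = 0.01, C = 1e4, gamma = 2))
  expect_lt(rmse(y2, predict(m2, X2)), 2 * 0.01)
  expect_true(all(abs(m2$dual_coef) <= 1e4 + 1e-9))
})

test_that("the explicit dual prediction path matches the solver's own predictions", {
  X <- matrix(with_seed(2, rnorm(60)), ncol = 3)
  y <- X[, 1] - 2 * X[, 2] + with_seed(3, rnorm(20, sd = 0.1))
  hy <- svr_hyper(epsilon = 0.05, C = 50, gamma = 1.2)
  m <- svr_train(X, y, hy)
  ref <- e1071::svm(x = X, y = y, scale = FALSE, type = "eps-regression",
                    kernel = "radial", cost = hy$C, epsilon = hy$epsilon,
                    gamma = 1 / (2 * hy$gamma^2))
  expect_equal(predict(m, X), as.numeric(predict(ref, X)), tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 2, 5)), "dimension")
  # all-zero dual coefficients predict the constant bias
  m0 <- m; m0$dual_coef[] <- 0
  expect_equal(predict(m0, X), rep(m$bias, 20))
})

test_that("PLS1 saturates to least squares and tolerates redundant columns", {
  X <- matrix(with_seed(4, rnorm(20 * 8)), 20)
  beta <- with_seed(5, rnorm(8))
  y <- as.numeric(X %*% beta)
  full <- pls_fit(X, y, n_components = 8)
  ls <- stats::lm.fit(cbind(1, X), y)
  expect_lt(max(abs(predict(full, X) - y)), 1e-6)

  # one component suffices for a rank-one predictor matrix
  X1 <- outer(with_seed(6, rnorm(15)), c(1, 2, 3))
  y1 <- as.numeric(X1 %*% c(1, 0, 0))
  m1 <- pls_fit(X1, y1, n_components = 1)
  expect_lt(max(abs(predict(m1, X1) - y1)), 1e-8)

  # adding a constant column does not change predictions
  m <- pls_fit(X, y, 3)
  mc <- pls_fit(cbind(X, 5), y, 3)
  expect_equal(predict(m, X), predict(mc, cbind(X, 5)), tolerance = 1e-8)

  expect_error(pls_fit(X, y, n_components = 50), "n_components")
  expect_warning(pls_fit(cbind(X1, X1), y1, 4), "rank")
})

test_that("LOOCV accounts folds correctly and scores stub models", {
  X <- matrix(with_seed(7, rnorm(15 * 4)), 15)
  y <- seq(50, 1000, length.out = 15)
  oracle <- loocv(X, y,
                  fit_fn = function(Xt, yt) list(),
                  predict_fn = function(m, Xt) NA_real_)
  expect_equal(length(oracle$predictions), 15)

  perfect <- loocv(cbind(y), y,
                   fit_fn = function(Xt, yt) "oracle",
                   predict_fn = function(m, Xt) Xt[, 1])
  expect_equal(perfect$R, 1)
  expect_equal(perfect$RMSEP, 0)
  expect_equal(perfect$n_folds, 15)

  mean_pred <- loocv(X, y,
                     fit_fn = function(Xt, yt) mean(yt),
                     predict_fn = function(m, Xt) m)
  expect_lt(mean_pred$R, 0.3)
})

test_that("PSO-SVR recovers a noiseless linear relationship and honours the bounds", {
  X <- matrix(with_seed(8, runif(20 * 3)), 20)
  y <- as.numeric(X %*% c(2, -1, 0.5))
  fit <- pso_svr(X, y, pso = pso_config(iter_max = 25, seed = 2))
  expect_gt(r_coefficient(y, predict(fit, X)), 0.999)
  expect_true(fit$hyper$epsilon >= 0 && fit$hyper$epsilon <= 0.2)
  expect_true(fit$hyper$C >= 1 && fit$hyper$C <= 1e8)
  expect_true(fit$hyper$gamma >= 0.01 && fit$hyper$gamma <= 2)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("spectrum denoising reduces the error against the known clean spectrum", {
  ds <- synthetic_spectra(spectra_gen_config(seed = 31))
  s <- 8
  den <- denoise_signal(ds$absorbance[s, ], ensemble_config(seed = 17))
  raw_err <- sd(ds$absorbance[s, ] - ds$clean[s, ])
  den_err <- sd(den - ds$clean[s, ])
  expect_lt(den_err, raw_err)
})

test_that("PLS component choice by LOO picks a workable count", {
  ds <- synthetic_spectra(spectra_gen_config(seed = 23))
  k <- pls_select_ncomp(ds$absorbance, ds$concentrations, max_components = 8)
  expect_true(k >= 1 && k <= 8)
  rep <- loocv(ds$absorbance, ds$concentrations,
               function(Xt, yt) pls_fit(Xt, yt, n_components = k))
  expect_gt(rep$R, 0.99)
})
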