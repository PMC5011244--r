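test_that("correlative coefficient matches its defining cases and errors on constants", {
  x <- with_seed(1, rnorm(50))
  expect_equal(correlative_coefficient(x, x), 1)
  expect_equal(correlative_coefficient(x, -x), -1)
  expect_equal(correlative_coefficient(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_error(correlative_coefficient(rep(1, 10), x[1:10]), "constant")
  expect_error(correlative_coefficient(1:5, 1:6), "equal length")
})

test_that("the selection threshold follows mu/(10 mu - 3) and rejects weak maxima", {
  expect_equal(selection_threshold(c(0.1, 0.5)), 0.25)
  expect_equal(selection_threshold(1), 1 / 7)
  expect_equal(selection_threshold(0.7429), 0.7429 / (10 * 0.7429 - 3))
  expect_true(abs(selection_threshold(0.7429) - 0.16773) < 5e-4)
  expect_error(selection_threshold(c(0.05, 0.29)), "0.3")
  expect_error(selection_threshold(c(-0.1, 0.5)), "non-negative")
})

test_that("threshold is strictly decreasing in the maximum correlation", {
  mu <- seq(0.31, 1, by = 0.01)
  th <- vapply(mu, selection_threshold, numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("sensitive-mode selection keeps the tone of a noiseless signal", {
  t <- (0:511) / 512
  tone <- sin(15 * pi * t)
  d <- emd(tone)
  sel <- select_sensitive(d, tone, forced_drop = 0L)
  expect_equal(sel$kept[1], 1L)
  expect_gt(cor(sel$reconstructed, tone), 0.999)
})

test_that("reconstruction is the exact sum of kept modes and forced_drop only shrinks the kept set", {
  y <- add_noise_snr(simulated_signal(512), 5, seed = 3)
  d <- iceemdan(y, ensemble_config(ensemble_size = 20L, seed = 3))
  sel <- select_sensitive(d, y, forced_drop = 3L)
  expect_equal(sel$reconstructed,
               rowSums(d$imfs[, sel$kept, drop = FALSE]),
               tolerance = 1e-12)
  expect_true(all(sel$mu_used >= 0 & sel$mu_used <= 1))
  expect_true(all(sel$kept > sel$forced_drop))
  for (fd in 0:3) {
    k1 <- tryCatch(select_sensitive(d, y, forced_drop = fd)$kept,
                   error = function(e) integer(0))
    k2 <- tryCatch(select_sensitive(d, y, forced_drop = fd + 1L)$kept,
                   error = function(e) integer(0))
    expect_true(all(k2 %in% k1))
  }
})

test_that("CMSE selection handles tiny and clean decompositions", {
  # two-mode decomposition: candidate index can only be 1
  y <- simulated_signal(512)
  d <- emd(y)
  sel <- select_cmse(d)
  expect_true(sel$kept[1] %in% c(1L, 2L))
  # pure signal, no noise: reconstruction starts at the first mode
  expect_equal(sel$kept[1], 1L)
  expect_equal(sel$kept[length(sel$kept)], d$nimf)
  expect_error(select_cmse(emd(seq(0, 1, length.out = 64))), "2 modes")
})

test_that("HD and MI rank an identical mode as most signal-like", {
  y <- add_noise_snr(simulated_signal(512), 5, seed = 4)
  d <- iceemdan(y, ensemble_config(ensemble_size = 20L, seed = 4))
  # append the reference itself as an extra "mode"
  d2 <- d
  d2$imfs <- cbind(d$imfs, y)
  d2$nimf <- d$nimf + 1L
  hd <- select_hd(d2, y)
  expect_equal(unname(which.min(hd$values)), d2$nimf)
  expect_lt(min(hd$values), 1e-12)
  mi <- select_mi(d2, y)
  expect_equal(unname(which.max(mi$values)), d2$nimf)
  expect_true(d2$nimf %in% mi$kept)
})

test_that("select_modes dispatches on the criterion name", {
  y <- add_noise_snr(simulated_signal(512), 5, seed = 5)
  d <- iceemdan(y, ensemble_config(ensemble_size = 20L, seed = 5))
  for (crit in c("corr", "cmse", "hd", "mi")) {
    sel <- select_modes(d, y, crit)
    expect_s3_class(sel, "imf_selection")
    expect_identical(sel$criterion, crit)
  }
})
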