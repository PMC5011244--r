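small_cfg <- function(I = 8L, eps = 0.2, seed = 1L)
  ensemble_config(ensemble_size = I, noise_strength = eps, seed = seed)

test_that("noise bank realizations are standard Gaussian and reproducible", {
  w <- noise_bank(1024, 10, seed = 3)
  expect_equal(dim(w), c(1024L, 10L))
  expect_true(all(abs(colMeans(w)) < 0.1))
  expect_true(all(abs(apply(w, 2, sd) - 1) < 0.1))
  expect_identical(w, noise_bank(1024, 10, seed = 3))
  expect_false(identical(w, noise_bank(1024, 10, seed = 4)))
})

test_that("all ensemble variants collapse to plain EMD as the noise vanishes", {
  x <- simulated_signal(256)
  base <- emd(x)
  tiny <- ensemble_config(ensemble_size = 1L, noise_strength = 1e-12, seed = 1)
  tiny2 <- ensemble_config(ensemble_size = 2L, noise_strength = 1e-12, seed = 1)
  for (d in list(eemd(x, tiny), ceemd(x, tiny2), ceemdan(x, tiny),
                 iceemdan(x, tiny))) {
    expect_equal(d$nimf, base$nimf)
    expect_lt(max(abs(d$imfs - base$imfs)), 1e-6)
  }
})

test_that("CEEMD requires an even ensemble and cancels paired noise", {
  x <- simulated_signal(256)
  expect_error(ceemd(x, ensemble_config(ensemble_size = 3L)), "even")
  # noise small enough not to add extrema of its own, so each mixture's
  # first mode is still the fast tone and the pair average matches EMD's
  d <- ceemd(x, small_cfg(I = 2L, eps = 0.002))
  e <- emd(x)
  expect_gt(abs(cor(d$imfs[, 1], e$imfs[, 1])), 0.9)
})

test_that("CEEMDAN and improved CEEMDAN are exactly complete; EEMD is not", {
  for (seed in 1:5) {
    x <- with_seed(seed, cumsum(rnorm(200)))
    scale_ref <- 1 + max(abs(x))
    dc <- ceemdan(x, small_cfg(seed = seed))
    expect_lt(max(abs(reconstruct(dc) - x)), 1e-10 * scale_ref)
    di <- iceemdan(x, small_cfg(seed = seed))
    expect_lt(max(abs(reconstruct(di) - x)), 1e-10 * scale_ref)
  }
  y <- add_noise_snr(simulated_signal(256), 5, seed = 1)
  de <- eemd(y, small_cfg(seed = 1))
  expect_gt(max(abs(reconstruct(de) - y)), 1e-8)
})

test_that("ensemble decompositions are bit-identical under a fixed seed", {
  x <- add_noise_snr(simulated_signal(256), 5, seed = 2)
  for (method in c("eemd", "ceemd", "ceemdan", "iceemdan")) {
    a <- decompose(x, method, small_cfg(seed = 9))
    b <- decompose(x, method, small_cfg(seed = 9))
    expect_identical(a$imfs, b$imfs)
    expect_identical(a$residue, b$residue)
  }
})

test_that("EEMD mode count is the maximum across realizations", {
  x <- add_noise_snr(simulated_signal(256), 5, seed = 1)
  cfg <- small_cfg(I = 6L, seed = 5)
  d <- eemd(x, cfg)
  amp <- cfg$noise_strength * sd(x)
  w <- noise_bank(length(x), 6L, 5)
  counts <- vapply(1:6, function(i) emd(x + amp * w[, i])$nimf, integer(1))
  expect_equal(d$nimf, max(counts))
})

test_that("the noisy benchmark decomposes into about eight modes", {
  y <- simulated_signal()
  counts <- vapply(1:3, function(seed) {
    noisy <- add_noise_snr(y, 5, seed = seed)
    iceemdan(noisy, ensemble_config(seed = seed))$nimf
  }, integer(1))
  expect_true(all(counts >= 7 & counts <= 9))
})

test_that("improved CEEMDAN's first mode carries less low-frequency energy than EEMD's", {
  y <- simulated_signal(512)
  lowfreq_power <- function(v) {
    sp <- Mod(stats::fft(v))^2
    sum(sp[2:11])                        # below 10 cycles per record
  }
  wins <- vapply(1:10, function(seed) {
    noisy <- add_noise_snr(y, 5, seed = seed)
    cfg <- ensemble_config(ensemble_size = 30L, seed = seed)
    lowfreq_power(iceemdan(noisy, cfg)$imfs[, 1]) <
      lowfreq_power(eemd(noisy, cfg)$imfs[, 1])
  }, logical(1))
  expect_true(mean(wins) > 0.5)
  expect_lt(mean(vapply(1:10, function(seed) {
    noisy <- add_noise_snr(y, 5, seed = seed)
    cfg <- ensemble_config(ensemble_size = 30L, seed = seed)
    lowfreq_power(iceemdan(noisy, cfg)$imfs[, 1])
  }, numeric(1))),
  mean(vapply(1:10, function(seed) {
    noisy <- add_noise_snr(y, 5, seed = seed)
    cfg <- ensemble_config(ensemble_size = 30L, seed = seed)
    lowfreq_power(eemd(noisy, cfg)$imfs[, 1])
  }, numeric(1))))
})
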