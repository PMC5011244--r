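test_that("extrema detection handles single oscillations, monotone runs and plateaus", {
  ex <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(ex$maxima$idx, 2L)
  expect_equal(ex$minima$idx, 4L)

  mono <- find_extrema(c(1, 2, 3, 4, 5))
  expect_length(mono$maxima$idx, 0)
  expect_length(mono$minima$idx, 0)

  # plateau resolved to the midpoint
  pl <- find_extrema(c(0, 2, 2, 2, 0, -1, 0))
  expect_equal(pl$maxima$idx, 3L)
  expect_equal(pl$minima$idx, 6L)

  # cos(4*pi*t) on [0,1): the t = 0 maximum sits on the boundary, so the
  # interior holds one maximum (t = 1/2) and two minima (t = 1/4, 3/4)
  t <- (0:1023) / 1024
  cx <- find_extrema(cos(4 * pi * t))
  expect_length(cx$maxima$idx, 1)
  expect_length(cx$minima$idx, 2)

  expect_error(find_extrema(c(1, 2, 3)), "at least 4")
  expect_error(find_extrema(c(1, 2, NA, 4)), "finite")
})

test_that("local mean recovers the slow component and respects offsets", {
  t <- (0:1023) / 1024
  tone <- sin(15 * pi * t)

  m0 <- local_mean(tone)
  interior <- 103:921                     # central 80%
  expect_lt(max(abs(m0[interior])), 0.05)

  m5 <- local_mean(tone + 5)
  expect_lt(max(abs(m5[interior] - 5)), 0.05)

  y <- cos(4 * pi * t) + tone
  my <- local_mean(y)
  expect_lt(sqrt(mean((my[interior] - cos(4 * pi * t)[interior])^2)), 0.1)

  expect_null(local_mean(seq_len(32) * 1.0))   # monotone: no envelopes
})

test_that("sifting returns pure tones unchanged and flags degenerate input", {
  t <- (0:1023) / 1024
  tone <- sin(15 * pi * t)
  s <- sift_imf(tone)
  expect_gt(cor(s$imf, tone), 0.999)

  flat <- sift_imf(rep(1, 64))
  expect_equal(flat$imf, rep(1, 64))
  expect_false(flat$converged)
})

test_that("EMD separates well-spaced tones and is exactly complete", {
  y <- simulated_signal()
  d <- emd(y)
  expect_s3_class(d, "mode_decomp")
  expect_gte(d$nimf, 2)
  t <- (0:1023) / 1024
  expect_gt(abs(cor(d$imfs[, 1], sin(15 * pi * t))), 0.95)
  expect_gt(abs(cor(d$imfs[, 2], cos(4 * pi * t))), 0.95)
  expect_lt(max(abs(reconstruct(d) - y)), 1e-10 * max(abs(y)))

  ramp <- emd(seq(0, 1, length.out = 256))
  expect_equal(ramp$nimf, 0)
  expect_equal(ramp$residue, seq(0, 1, length.out = 256))
})

test_that("emd_mode follows the out-of-range zero convention", {
  t <- (0:511) / 512
  tone <- sin(15 * pi * t)
  expect_gt(cor(emd_mode(tone, 1), tone), 0.999)

  y <- simulated_signal(512)
  d <- emd(y)
  expect_equal(emd_mode(y, d$nimf + 5L), numeric(512))

  # the first mode of white noise has strictly smaller variance than the noise
  w <- with_seed(7, rnorm(1024))
  expect_lt(var(emd_mode(w, 1)), var(w))
})

test_that("completeness, zero-crossing ordering and offset equivariance hold on random signals", {
  for (seed in 1:20) {
    x <- with_seed(seed, cumsum(rnorm(256)))
    d <- emd(x)
    expect_lt(max(abs(reconstruct(d) - x)), 1e-10 * (1 + max(abs(x))))
    if (d$nimf >= 2) {
      zc <- apply(d$imfs, 2, zero_crossings)
      expect_true(all(diff(zc) <= 0))
    }
    dc <- emd(x + 10)
    expect_equal(dc$nimf, d$nimf)
    if (d$nimf > 0)
      expect_lt(max(abs(dc$imfs - d$imfs)), 1e-6 * (1 + max(abs(x))))
  }
})

test_that("compiled EMD agrees with an independent plain-R implementation", {
  for (seed in 1:20) {
    x <- with_seed(100 + seed, rnorm(256))
    d <- emd(x)
    r <- ref_emd(x)
    expect_equal(d$nimf, ncol(r$imfs))
    for (k in seq_len(min(d$nimf, ncol(r$imfs))))
      expect_gte(cor(d$imfs[, k], r$imfs[, k]), 0.99)
  }
})

test_that("the compiled envelope mean matches stats::spline natural interpolation", {
  x <- with_seed(5, cumsum(rnorm(300)))
  expect_equal(local_mean(x), ref_local_mean(x), tolerance = 1e-12)
})
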