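test_that("the benchmark signal matches its closed form", {
  y <- simulated_signal()
  expect_length(y, 1024)
  expect_equal(y[1], 1)                  # cos(0) + sin(0)
  expect_lte(max(abs(y)), 2)
  t <- (0:1023) / 1024
  expect_equal(y, cos(4 * pi * t) + sin(15 * pi * t))
  expect_error(simulated_signal(4), "N >= 8")
})

test_that("noise injection hits the requested SNR exactly and is seed-deterministic", {
  y <- simulated_signal(512)
  for (snr in c(0, 5, 20)) {
    noisy <- add_noise_snr(y, snr, seed = 7)
    measured <- 10 * log10(sum(y^2) / sum((noisy - y)^2))
    expect_equal(measured, snr, tolerance = 1e-9)
  }
  expect_identical(add_noise_snr(y, 5, seed = 1), add_noise_snr(y, 5, seed = 1))
  expect_false(identical(add_noise_snr(y, 5, 1), add_noise_snr(y, 5, 2)))
  expect_error(add_noise_snr(y, Inf), "finite")
})

test_that("synthetic spectra obey the shape contract and dataset invariants", {
  ds <- synthetic_spectra()
  expect_s3_class(ds, "spectra_dataset")
  expect_equal(dim(ds$absorbance), c(15L, 500L))
  expect_equal(range(ds$concentrations), c(50, 1000))
  expect_true(all(diff(ds$wavelengths) > 0))
  expect_equal(length(ds$replicates), 15L)
  expect_identical(synthetic_spectra()$absorbance, ds$absorbance)
})

test_that("absorbance at a band center is exactly linear in concentration without noise", {
  cfg <- spectra_gen_config(noise_sd = 0, baseline_amplitude = 0,
                            band_centers = 1600, band_widths = 70,
                            band_strengths = 0.05,
                            interferent_strengths = c(0, 0), seed = 1)
  ds <- synthetic_spectra(cfg)
  ch <- which.min(abs(ds$wavelengths - 1600))
  expect_gt(cor(ds$absorbance[, ch], ds$concentrations)^2, 1 - 1e-12)
})

test_that("averaging five replicates shrinks the noise by about sqrt(5)", {
  ratios <- vapply(1:5, function(seed) {
    ds <- synthetic_spectra(spectra_gen_config(seed = seed))
    rep_sd <- mean(vapply(seq_len(15), function(s)
      sd(ds$replicates[[s]][1, ] - ds$clean[s, ]), numeric(1)))
    avg_sd <- mean(vapply(seq_len(15), function(s)
      sd(ds$absorbance[s, ] - ds$clean[s, ]), numeric(1)))
    rep_sd / avg_sd
  }, numeric(1))
  expect_true(all(abs(ratios - sqrt(5)) < 0.15 * sqrt(5)))
})

test_that("a PLS1 fit on noiseless spectra is exact (identifiability)", {
  ds <- synthetic_spectra(spectra_gen_config(noise_sd = 0,
                                             baseline_amplitude = 0,
                                             seed = 2))
  m <- pls_fit(ds$absorbance, ds$concentrations, n_components = 1)
  expect_gt(r_coefficient(ds$concentrations, predict(m, ds$absorbance)),
            1 - 1e-6)
})
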