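# specmode

Adaptive signal reconstruction and chemometric calibration for 1-D signals
and near-infrared (NIR) transmission spectra.

Quantifying an analyte such as glucose from NIR spectra of aqueous
solutions is hard because the analyte's overtone and combination bands are
weak (hundredths of an absorbance unit) compared with water absorption,
baseline drift and instrument noise. `specmode` addresses this with a
two-stage pipeline:

1. **Mode-selective denoising.** A signal `x(n)` is decomposed into
   intrinsic mode functions (IMFs) by empirical mode decomposition (EMD)
   or its noise-assisted variants — EEMD, CEEMD, CEEMDAN and the improved
   CEEMDAN with adaptive noise, which estimates each residue as the
   ensemble-averaged local mean `r_k = <M(r_{k-1} + beta_{k-1} E_k(w_i))>`
   and is exactly complete. Sensitive modes are the IMFs whose correlative
   coefficient `mu_i` with the reference signal exceeds

   ```
   mu_h = max(mu_i) / (10 * max(mu_i) - 3)
   ```

   after unconditionally dropping the leading (noise-dominated) modes; the
   reconstruction is the sum of the kept modes. Consecutive-MSE, Hausdorff
   distance and mutual-information selection rules are included for
   comparison.

2. **Calibration.** Concentration is regressed on the (denoised) spectra
   by epsilon-SVR with an RBF kernel `K(xi, xj) = exp(-||xi-xj||^2 /
   (2 gamma^2))`, with `(epsilon, C, gamma)` selected by particle swarm
   optimization over `[0, 0.2] x [1, 1e8] x [0.01, 2]` using
   cross-validated RMSE as fitness, or by univariate PLS (NIPALS) as a
   baseline. Models are assessed by leave-one-out cross-validation with
   `R = sqrt(1 - SSres/SStot)` and `RMSEP = sqrt(sum(err^2)/(n-1))`.

Reconstruction quality is scored by `SNR = 10 log10(sum(y^2) /
sum((yhat-y)^2))`, RMSE and the correlation coefficient. Because no
instrument spectra are distributed, the package ships a seeded generator
for the standard two-tone benchmark signal and for synthetic
glucose-solution spectra with a Beer-Lambert concentration response.

## Worked example

Denoise the noisy two-tone benchmark signal and score the reconstruction:

```r
library(specmode)

y     <- simulated_signal()                 # cos(4*pi*t) + sin(15*pi*t), N = 1024
noisy <- add_noise_snr(y, snr_db = 5, seed = 1)

dec <- iceemdan(noisy, ensemble_config(ensemble_size = 100, seed = 1))
dec
#> ICEEMDAN decomposition: 9 IMF(s) + residue, signal length 1024
#>   IMF mean power: 0.201 0.0514 0.024 0.0129 0.133 0.174 0.443 0.0026 0.00132
#>   residue range: -0.0555 .. -0.0524

sel <- select_sensitive(dec, y, forced_drop = 3)
sel
#> IMF selection (corr): kept {5, 6, 7, 8} of 9 modes
#>   threshold 0.16758, forced leading drop 3
#>   criterion values: 0.006573 0.0005929 0.02016 0.1047 0.6817 0.7439 0.7383 0.3349 0.001842

snr_db(y, sel$reconstructed)
#> [1] 17.52628
rmse(y, sel$reconstructed)
#> [1] 0.13889
correlative_coefficient(y, sel$reconstructed)
#> [1] 0.9929352
```

The decomposition places the fast and slow tones in modes 6 and 7 (their
correlation magnitudes with the clean signal, about 0.74-0.75, dominate
all other modes), the threshold rule evaluates near 0.167, and the
reconstruction recovers the clean signal to about 17.5 dB — the added
5 dB noise is almost entirely removed.

A full calibration study on synthetic glucose spectra:

```r
ds <- synthetic_spectra(spectra_gen_config(seed = 101))
st <- run_calibration_study(ds, seed = 1, pso = pso_config(iter_max = 30))
st
#> Calibration study (LOOCV):
#>   PLS                R 0.9983624  RMSEP  17.3602
#>   ICEEMDAN-PLS       R 0.9992477  RMSEP  11.7693
#>   PSO-SVR            R 0.9963758  RMSEP  25.8134
#>   ICEEMDAN-PSO-SVR   R 0.9988832  RMSEP  14.3379
```

`R` is the leave-one-out calibration correlation (1 = perfect), `RMSEP`
the prediction error in mg/dL on this synthetic fixture; denoising the
spectra with improved CEEMDAN lowers the prediction error for both model
families.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "specmode", load_package = "installed")'
```

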