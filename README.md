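# carsdenoise

Deep-learning noise reduction as an imaging-**rate** improvement for
low-SNR scanned laser (CARS) nerve imaging.

Label-free nerve visualization with a CARS rigid endoscope — built for
nerve-sparing surgery — is photon-starved: acquiring an image with a
usable signal-to-noise ratio takes on the order of a minute, because an
image at each position is the average of many repeated short frames,

```
rate [images/min] = 60 / (frame exposure [s] × frames averaged).
```

A denoiser that restores fast, noisy acquisitions to the quality of the
long-exposure reference therefore directly buys imaging speed. This
package implements that whole measurement loop for researchers working on
denoising for scanned/photon-counting microscopy:

* **Simulator** — fibrous nerve-like phantoms and a per-frame acquisition
  model (scaled Poisson shot noise + Gaussian read noise + sparse impulse
  events), frame averaging, and paired dataset generation with either
  clean (100-frame) targets or independent noisy pairs
  (Noise2Noise-style training needs no clean image).
* **Denoisers** — three convolutional families built from an
  (F, K, L) hyperparameter triple: `W5` (shallow chain, one global
  residual skip), `DN` (per-layer residual projections summed onto the
  input) and `N2N` (U-Net-style encoder–decoder, 5 pooling stages,
  leaky ReLU). Forward/backward passes are compiled in the package — no
  deep-learning framework required.
* **Training pipeline** — random-crop patch augmentation (no flips or
  rotations: raster-scanned detectors are directional), MSE + Adam,
  pre-train → fine-tune transfer, and 4-model output-averaging ensembles.
* **Metrics** — PSNR, SSIM (canonical Gaussian-window parameters,
  validated against scikit-image), and the **equivalent imaging rate**:
  fit monotone metric-vs-rate curves, find the rates `a`, `b` where they
  cross PSNR = 30 dB and SSIM = 0.8, and report

  ```
  EIR = 2ab / (a + b)        (harmonic mean, images/min)
  ```

* **Evaluation harness** — exhaustive 3:1:1 nested cross-validation
  (20 plans for 5 positions) with a programmatic leakage audit, (F, K, L)
  grid search, Friedman rank test, two-tailed paired t-test and
  Bonferroni–Holm correction.
* **I/O + CLI** — multi-frame float TIFF stacks with YAML sidecars, tidy
  CSV/JSON outputs, per-run JSON manifests, and a `carsdenoise` command
  line (`simulate`, `train`, `finetune`, `denoise`, `evaluate`, `eir`).

## Worked example

Train a small shallow-residual denoiser on simulated endoscopy-like data
and score a held-out position:

```r
library(carsdenoise)

spec  <- phantom_spec(height_px = 96, width_px = 96, n_fibers = 3, n_blobs = 2)
noise <- noise_spec()     # calibrated: 3-frame average ~ 20 dB vs ground truth

train_data <- simulate_dataset(spec, acq_levels = 3, noise, seed = 1,
                               pairing = "clean", n_positions = 4)
patches <- extract_patches(train_data,
                           patch_config(patch_px = 64, n_patches_per_image = 50),
                           seed = 1)
model <- train_denoiser(patches, arch_spec("W5", n_filters_F = 8, n_layers_L = 4),
                        train_config(max_epochs = 10, seed = 1))
model
#> <denoiser W5 (F=8, K=3, L=4): 6 convolutions, 2,489 parameters>

test_data <- simulate_dataset(spec, 3, noise, seed = 42,
                              pairing = "clean", n_positions = 1)
noisy <- test_data$input[[1]];  truth <- test_data$target[[1]]
cat(sprintf("raw:      %.2f dB / SSIM %.3f\n", psnr(noisy, truth), ssim(noisy, truth)))
#> raw:      18.79 dB / SSIM 0.499
den <- denoise(model, noisy)
cat(sprintf("denoised: %.2f dB / SSIM %.3f\n", psnr(den, truth), ssim(den, truth)))
#> denoised: 23.61 dB / SSIM 0.689
```

Ten epochs of a 2,489-parameter model already buy ~5 dB and +0.19 SSIM on
a held-out position — the image taken at 12.5 images/min now scores like a
considerably slower acquisition, which is the point.

The EIR combines the criterion-crossing rates of the PSNR and SSIM
curves; with known crossings it is one call:

```r
eir_from_rates(12.5, 4.8)
#> Equivalent imaging rate (criteria: PSNR 30 dB, SSIM 0.8)
#>   EIR_PSNR: 12.5 images/min
#>   EIR_SSIM: 4.8 images/min
#>   EIR:      6.9 images/min (harmonic mean)
```

From measured curves, use `rate_sweep()` →
`fit_metric_curve()`/`eir_from_sweep()` → `compute_eir()`;
`autoplot()` draws the fitted curves with their criteria, and
`tidy()`/`glance()` return results as tibbles.

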