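# ecarecon

Simulation and reconstruction toolkit for highly accelerated breast
DCE-MRI, built around **enhancement-constrained acceleration (ECA)**: a
reconstruction that re-partitions a time-tagged k-space stream into
short intervals and solves, per image series `X = (X_1, ..., X_T)`,

```
minimize   sum_v w_v sum_t |Δ X_v(t)|^2  +  λ ||X||^2
subject to X̃_t[k] = y_{t,k}   for every k-space entry measured in interval t
```

— the smoothest enhancement curves exactly consistent with the measured
data. With `V` voxels, `T` reconstructed frames and `N` samples the
acceleration factor is `α = V·T/N`; a 3.5 s Nyquist sweep reconstructed
at 0.25 s gives `α = 14`. The package is aimed at MR physicists and
image-reconstruction researchers who want a controlled, fully synthetic
test bed for sub-sweep temporal resolution in contrast-enhanced imaging.

It provides, as composable tidyverse-style functions:

* **Digital phantoms** (`phantom_config()`, `build_phantom()`,
  `evaluate_phantom()`): static background plus additive enhancement —
  Parker population AIF in vessel voxels, truncated-exponential uptake
  `A(1 − e^{−α(t−t0)})` in lesion voxels — rendered through a spoiled
  gradient-echo signal model, evaluable at any continuous time.
* **UnWRAP trajectories** (`unwrap_trajectory()`,
  `partition_trajectory()`, `spectral_uniformity()`): Cartesian ordering
  that splits the phase-encode plane into `f` sections × `f` sheaves and
  interleaves them so every `sweep/f` interval samples a uniform spread
  of frequency bands.
* **A virtual scanner** (`acquire()`, `add_noise()`, `psnr()`,
  `calibrate_noise()`): 50 ms phantom re-evaluation with linear
  interpolation in between, complex Gaussian k-space noise calibrated to
  a target image-domain PSNR (37 dB by default).
* **Reconstructions** (`eca_reconstruct()`, `ifft_reconstruct()`):
  conjugate-gradient ECA with hard data-fidelity constraints (measured
  entries honored bit-exactly) and the sweep-by-sweep IFFT baseline.
* **Kinetic analysis** (`bat_analysis()`, `fit_emm_pse()`,
  `initial_slope_vessel()`, `paired_error_ratio()`,
  `voxel_error_stats()`): bolus arrival time (time-of-peak in vessels,
  20%-of-maximum in lesions), initial enhancement slope (modified Akima
  maximum derivative; `A·α` from the empirical model fit), and paired
  error-ratio statistics with confidence intervals.

`run_pipeline()` chains the stages end to end and writes NIfTI/CSV/JSON
artifacts with a checksummed manifest; `inst/cli/eca-pipeline.R` exposes
the same stages as shell subcommands.

## Worked example

```r
library(ecarecon)

# 32 x 32 x 8 phantom: ~480 lesion voxels (A = 1.56 ± 0.45 mM,
# α = 0.14 ± 0.13 /s, t0 = 15 ± 2.2 s), two vessels with a 4 s arrival
# gradient; 16 UnWRAP sweeps of 3.5 s; noise calibrated to 37 dB;
# ECA at 0.25 s vs IFFT at 3.5 s.  Runs in ~15 s.
res <- run_pipeline(run_config(seed = 1))

res$psnr_db
#> [1] 37.00618

res$improvement
#> # A tibble: 2 × 7
#>   tissue median      se   mad improvement     n n_zero_denom
#>   <chr>   <dbl>   <dbl> <dbl>       <dbl> <int>        <int>
#> 1 lesion  0.128 0.00942 0.138        7.81   480            2
#> 2 vessel  0.498 0.0221  0.458        2.01   576            0
```

`median` is the per-voxel error ratio (ECA BAT error / IFFT BAT error)
against the estimator applied to dense ground truth; `improvement` is
its reciprocal: here ECA estimates lesion bolus arrival ≈ 7.8× more
accurately than the 3.5 s baseline, at the same k-space budget. Vessel
time-of-peak improvement is structurally limited on smooth desk-scale
phantoms (see the methods vignette, section "What the synthetic
experiments do and do not show").

Per-voxel detail and fidelity:

```r
res$bat            # tibble: voxel, tissue, bat_ref, bat_eca, bat_ifft, errors
res$fidelity$eca$summary
#> # A tibble: 3 × 4
#>   tissue     median_pct mad_pct     n
#> 1 background       4.24   0.870  7134
#> 2 lesion           3.86   0.360   482
#> 3 vessel           3.78   0.272   576
autoplot(res$eca, frame = 80)                 # reconstructed volume slice
plot_enhancement_curves(
  extract_curves(res$eca, res$phantom$lesion_params$voxel[1:20]))
```

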