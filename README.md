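# swetools

Shear-wave elastography (SWE) measures tissue stiffness by pushing the
tissue with an acoustic-radiation-force impulse and tracking the transverse
shear wave that radiates from the push: in a soft elastic solid the wave
travels at c = √(μ/ρ), so its speed encodes the shear modulus μ, reported
clinically as a Young's modulus E = 3ρc². How that speed is estimated from
noisy, coarsely sampled displacement traces determines the bias and random
error of every stiffness reading downstream.

`swetools` is an R toolkit for studying exactly that question at desk scale,
for people developing or validating SWE speed estimators. It provides:

* a **displacement-field simulator** for virtual tissue-mimicking phantoms
  (homogeneous, layered, stiff-inclusion, and a graded stiffness series
  emulating a polyvinyl-alcohol cryogel freeze–thaw ladder), with a
  kinematic moveout mode for heterogeneous media and a Fourier-synthesis
  Voigt-viscoelastic mode with true dispersion, plus seeded Gaussian noise
  at a prescribed (optionally depth-indexed) SNR;
* **four speed estimators**: sample-resolution time-to-peak (SPM),
  sub-sample time-to-peak with spline upsampling and parabolic refinement
  (TDPM), cross-correlation time-shift (TSPM), and a Radon-sum
  group-velocity search — all feeding a position-on-time regression whose
  slope is the speed and whose R² is the goodness of fit;
* **Voigt-model mechanics**: complex wavenumber
  k(ω) = ω√(ρ/(μ + iωη)), phase-velocity dispersion
  c(ω) = √(2(μ² + ω²η²) / (ρ(μ + √(μ² + ω²η²)))), bounded
  Levenberg–Marquardt parameter fitting, and E = 3ρc² conversion;
* a seeded **Monte-Carlo benchmark** of estimator bias, random error, RMSE,
  mean R² and across-depth stability;
* the **reader-study statistics** used around SWE: ICC(2,1) interobserver
  agreement, repeated-measure summaries, ROC/AUC by Mann–Whitney pair
  counting, Youden-optimal thresholds, and 2×2 diagnostic metrics;
* HDF5 field containers, JSON scenario configs, CSV tables, a fixture
  generator, and a thin `swe` command-line interface
  (`inst/cli/swe`: `simulate`, `estimate`, `bench`, `voigt-fit`, `stats`,
  `fixtures`).

## Worked example

```r
library(swetools)

phantom <- build_phantom("homogeneous", shear_modulus_kpa = 4)   # c = 2 m/s
push    <- push_pulse(attenuation = 50)
grid    <- acquisition_grid()                                    # PRF 10 kHz
field   <- simulate_displacement(phantom, push, grid)
noisy   <- add_noise(field, snr_db = 20, seed = 42)

for (m in c("spm", "tdpm", "tspm", "radon")) print(estimate_sws(noisy, m))
#> <swe_estimate> SPM: 2.015 m/s (R^2 0.9991, 15 channels)
#> <swe_estimate> TDPM: 2.002 m/s (R^2 0.9996, 15 channels)
#> <swe_estimate> TSPM: 2.004 m/s (R^2 1.0000, 15 channels)
#> <swe_estimate> RADON: 2 m/s (R^2 0.9855, 15 channels)

est <- estimate_sws(noisy, "tdpm")
young_modulus_from_speed(est$speed)
#> 12.03  (kPa; the phantom's true E = 3 rho c^2 is 12)
```

All four estimators recover the 2 m/s ground truth; SPM is the least exact
because its arrival times are quantised to the 0.1 ms sampling interval,
and the Radon search is exact here because 2 m/s lies on its speed grid.
The conversion turns the estimated speed into the clinical stiffness figure.

Comparing estimators under noise:

```r
sc <- scenario_config(
  phantom = list(kind = "homogeneous", shear_modulus_kpa = 4),
  push = list(attenuation = 50), acquisition = list(),
  noise = list(snr_db = 20), seed = 7)
benchmark_methods(sc, c("spm", "tdpm"), n_trials = 200, seed = 7)
#>  method true_speed      bias    std   rmse mean_r_squared
#>     SPM          2 -0.000215 0.0157 0.0157          0.999
#>    TDPM          2 -0.000432 0.0127 0.0128          0.999
```

Both methods are essentially unbiased; TDPM's sub-sample peak detection
removes the time-quantisation component of the error, cutting the random
error (std) by roughly a quarter at this SNR and leaving a higher mean R².

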