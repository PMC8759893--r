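---
title: "Simulating shear waves and comparing speed estimators"
author: "swetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating shear waves and comparing speed estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swetools)
```

## The problem

Shear-wave elastography (SWE) quantifies tissue stiffness by pushing the
tissue with a focused acoustic-radiation-force impulse and imaging the
transverse (shear) wave that radiates away from the push. In a purely elastic
soft solid the shear-wave speed is $c = \sqrt{\mu/\rho}$, so an estimate of
$c$ is an estimate of the shear modulus $\mu$, conventionally reported in the
clinic as a Young's modulus $E = 3\rho c^2$ (incompressibility, Poisson ratio
0.5). Everything downstream of the scanner — lesion stiffness readings,
reader agreement, diagnostic thresholds — rides on how well $c$ is estimated
from noisy, coarsely sampled displacement traces.

This package provides the full desk-scale loop: a displacement-field
simulator standing in for tissue-mimicking phantoms, four speed estimators
of the kind used on clinical systems, Voigt-model viscoelasticity, and the
agreement/diagnostic statistics used in reader studies.

## The simulator and what it emulates

`simulate_displacement()` samples particle displacement $u(x, z, t)$ on a
tracking grid, in two modes.

**Kinematic mode** transports the Gaussian push profile along the lateral
ray: $u(x,t) = A(x)\, g(t - \tau(x))$, with the arrival time
$\tau(x) = \int \mathrm{d}s / c(s)$ integrated through the (possibly
laterally heterogeneous) speed map, and an exponential lateral amplitude
decay $A(x) = A_0 e^{-\alpha |x - x_0|}$. This is deliberately not a wave
solver: it reproduces exactly the feature the time-to-peak estimator family
measures — arrival-time moveout — with a closed-form ground truth, so
estimator error can be attributed entirely to the estimator.

**Viscoelastic mode** propagates the push through a homogeneous Voigt medium
per depth row by Fourier synthesis,
$u(x,t) = \mathrm{Re}\,\mathcal{F}^{-1}\!\left[G(\omega)
e^{-i k(\omega) |x-x_0|}\right]$, with the complex wavenumber
$k(\omega) = \omega\sqrt{\rho/(\mu + i\omega\eta)}$ taken on the principal
branch ($\mathrm{Re}\,k > 0$, $\mathrm{Im}\,k \le 0$), which paired with the
$e^{+i\omega t}$ reconstruction gives an outgoing, decaying wave. The time
window is zero-padded to at least four times its length before the FFT to
suppress wrap-around. This mode produces genuine dispersion and frequency-
dependent attenuation; a test verifies that the phase delay measured between
two simulated channels reproduces the analytic Voigt phase velocity to
better than 1% across the pulse band.

Depth is a batch axis: each tracked depth propagates independently, matching
how per-depth speed readings are taken in practice. Depth-dependent signal
quality is modelled as a depth-indexed SNR map in `add_noise()` rather than
as wave physics, because the quantity of interest downstream is only the
stability of the per-depth estimates.

What the simulator does **not** emulate: reflections and guided-wave
artefacts, push-beam diffraction, speckle tracking noise correlated in time,
and axial coupling between depths. Passing tests therefore demonstrate
correctness of the estimators under idealised moveout plus white Gaussian
noise, not performance on raw scanner RF data.

### Study conditions

The generator defaults are fixed once and used everywhere, including the
acceptance script: density 1000 kg/m³, push at $x_0 = 0$ with Gaussian
width 0.3 ms, amplitude 10 µm, lateral attenuation 50 /m; 15 tracked
channels from 3 to 10 mm at 0.5 mm pitch; tracking PRF 10 kHz
($\Delta t = 0.1$ ms); 15 ms observation window. The graded stiffness
series uses presets of 3, 9, 18 and 30 kPa ($c \approx 1.73$–5.48 m/s).
These presets emulate a polyvinyl-alcohol cryogel series stiffened by
successive freeze–thaw cycles; no measured values exist for such a series,
so the presets are synthetic stand-ins chosen to span the soft-tissue range,
and they are labelled as such wherever they appear.

## The four estimators

All four operate on one depth row of a `DisplacementField`.

* **SPM** (`detect_arrivals_spm`): per channel, the arrival time is the time
  sample of the maximum displacement — resolution is one sampling interval
  (1/PRF). Ties break to the earliest sample; peaks on a window boundary are
  flagged invalid.
* **TDPM** (`detect_arrivals_tdpm`): the discrete peak is refined to
  sub-sample precision by cubic-spline upsampling (default factor 8)
  followed by a three-point parabolic fit, constrained to one original
  sample around the discrete peak. The parabolic step is exact on quadratic
  data; the spline method (`"fmm"`) reproduces cubics exactly, which the
  parabola-vertex test exploits.
* **TSPM** (`estimate_tspm`): adjacent-channel delays from the integer-lag
  cross-correlation maximum, refined by the same spline-plus-parabola recipe
  applied to the correlation function; cumulative delays versus position go
  through the same regression as the time-to-peak methods. Pairs whose
  correlation peak sits on the $\pm$`max_lag` boundary are dropped. The
  acronym mapping (SPM = sample-resolution peak, TDPM = sub-sample peak,
  TSPM = time-shift cross-correlation) is this package's interpretation of
  an estimator family whose names are used inconsistently across vendors;
  it is consistent with the sub-sample variant having "improved sampling
  resolution", but other constructions exist.
* **Radon-sum** (`estimate_radon`): exhaustive search over straight
  space–time trajectories $t = t_0 + (x - x_1)/c$ for the one maximising
  integrated absolute displacement; 201 log-spaced candidate speeds by
  default, intercepts at the sampling step. Resolution is one speed-grid
  step, and a maximiser on the range boundary is an error rather than a
  clipped estimate.

Speed comes from `fit_speed_regression()`: ordinary least squares of
*position on arrival time*, so the slope is the speed directly (the
reciprocal orientation — time on position, speed as 1/slope — is the common
alternative; regressing position on time avoids the division and keeps
"slope = velocity"). $R^2$ of this fit is the goodness-of-fit figure
reported alongside every estimate. A single-pass 3σ residual trim is
available but off by default, so differences between SPM and TDPM are
attributable to peak detection alone.

## Numerical choices

* Ties at equal maxima break to the earliest time, deterministically.
* TDPM/TSPM refinements are clamped to ±1 original sample of the discrete
  peak, so a pathological spline excursion can never move an arrival far.
* The Levenberg–Marquardt Voigt fit (`fit_voigt`) bounds $\mu > 0$,
  $\eta \ge 0$, caps iterations at 500, and starts from
  $\mu_0 = \rho c^2_{\min\omega}$, $\eta_0 = 0.5$ Pa·s. Because the model
  depends on $\eta$ only through $(\omega\eta)^2$, the objective's gradient
  vanishes at the $\eta = 0$ boundary and the optimiser can stall just off
  it; the fit therefore also evaluates the elastic submodel in closed form
  and returns the boundary solution when it is at least as good.
* `add_noise()` sets the noise variance from the mean signal power of the
  whole field (or per depth row for a depth-indexed SNR map), saves and
  restores the caller's RNG state, and records its seed in the field, so a
  stored field is bit-reproducible.
* Seeds are explicit arguments everywhere; per-trial seeds in
  `benchmark_methods()` are derived from the base seed and stay below
  $2^{31}$.

## The Monte-Carlo benchmark

`benchmark_methods()` simulates the noiseless field once, then draws
independent noise realisations per trial and re-estimates. It reports bias,
random error (population standard deviation, so that
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{std}^2$ holds exactly), RMSE,
mean $R^2$, and — with several tracked depths — the across-depth spread
(max − min) of per-depth mean estimates. A method that fails on more than
half the trials is marked failed with its failure count rather than
silently dropped.

Two benchmark experiments are fixed as the package's reference comparisons:

* **Random error at 20 dB** — homogeneous 4 kPa phantom, PRF 10 kHz,
  SNR 20 dB, 200 trials. TDPM's sub-sample detection removes the
  quantisation component of SPM's error, so its trial-to-trial standard
  deviation is lower and its mean $R^2$ at least as high.
* **Depth robustness** — 9 kPa phantom tracked at five depths (1–5 cm) with
  SNR degrading linearly from 25 dB to 10 dB, 400 trials. 400 was chosen so
  that the Monte-Carlo standard error of each per-depth mean
  ($\mathrm{std}/\sqrt{n} \approx 0.003$ m/s at the worst depth) sits well
  below the depth-to-depth bias structure (~0.02 m/s); with far fewer
  trials the spread statistic measures mostly Monte-Carlo noise and the
  comparison between methods is uninformative.

The clinically reported goodness-of-fit pair for these estimators (mean
$R^2$ of 0.94 vs 0.87 on ex-vivo tissue) depends on tissue data that cannot
be regenerated from a simulator; only the ordering (TDPM $\ge$ SPM under
noise) is claimed and tested here. The same applies to published reader ICCs
and clinical ROC figures: the statistics module implements the estimators
(ICC(2,1), Mann–Whitney AUC, Youden threshold, 2×2 ratios), and the fixture
generator provides synthetic reader/cohort tables, but no attempt is made to
reproduce numbers whose raw data were never deposited.

## Agreement and diagnostic statistics

`icc_agreement()` is the two-way random-effects, absolute-agreement,
single-measure ICC(2,1) from the mean squares of the subject × rater layout
(the form most reader studies mean by "the ICC"; consistency ICC(3,1) and
average-measure ICC(2,k) are exposed for sensitivity analysis). Complete
cases are required — pairwise deletion in a two-way layout silently changes
the estimand. `roc_auc()` counts ranked pairs with ties at one half;
`youden_threshold()` scans thresholds under the rule score ≥ threshold ⇒
positive, breaks ties toward higher specificity, and flags (rather than
re-orients) a marker whose best Youden index is zero — silent re-orientation
hides inverted inputs. Metrics with a zero denominator in the 2×2 table are
`NA`, not 0.

## Design decisions that were genuinely open

* **Modulus convention**: clinical machines report kPa without stating
  whether the figure is a shear or Young's modulus; this package fixes
  $E = 3\rho c^2$ (Young's, incompressible) and provides the exact inverse.
* **Regression orientation**: position-on-time (slope = speed), as above.
* **TSPM construction**: adjacent-pair correlation with parabolic
  refinement and regression on cumulative lags, as above — an
  interpretation, not a vendor specification.
* **ICC form**: fixed to ICC(2,1), with alternatives behind a parameter.
* **Branch of the complex square root**: principal branch
  ($\mathrm{Re}\,k > 0$, $\mathrm{Im}\,k \le 0$) with $e^{-ikd}$
  propagation; the opposite sign convention is equivalent under conjugate
  Fourier kernels.
* **One-sided tracking**: channels sit on one side of the push by default
  (matching acoustic-radiation-force imaging geometry), with a `two_sided`
  switch.

## Known limitations

Estimates from fields whose pulse is only ~3 samples wide carry a residual
sub-sample detection error of order 0.1 µs per channel even without noise,
so noiseless $R^2$ from simulated fields is 1 only to about $10^{-7}$, not
machine precision. The Radon method's resolution is bounded by its speed
grid, and its normalised peak-sharpness figure is a heuristic, not a
calibrated $R^2$. The simulator's noise is white and Gaussian; correlated
speckle-tracking noise would degrade all methods further and differently.
The problem sizes used in the tests and the acceptance script (15 channels,
151 time samples, 200–400 trials) were chosen as the smallest at which the
Monte-Carlo comparisons are statistically meaningful.
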