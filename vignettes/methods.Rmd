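---
title: "Retinal vessel pulse-amplitude mapping: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vessel pulse-amplitude mapping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`retppg` implements an analysis pipeline for cardiac-gated retinal vessel
photoplethysmography (PPG): fundus video is recorded while a graded
ophthalmodynamometric force (ODF) raises intraocular pressure (IOP), the
green-channel intensity at small vessel loci is modelled with harmonic
regression, and the resulting pulse-amplitude maps are reduced to
per-vessel observations that feed linear mixed-effects group comparisons.
A synthetic fundus-video generator with known ground truth closes the loop
for validation. This vignette records the model, the main numerical
choices, and the known limitations.

## 1. Signal model at a locus

The analysis unit is a **locus**: a 5x5-pixel cluster lying on a segmented
artery or vein. For each recording (one ODF level), the mean green-channel
intensity of the locus over frames $y_t$, sampled at the frame rate over
$C$ complete cardiac cycles (default $C = 3$), is modelled as

$$
y_t = \underbrace{\tau(t)}_{\text{drift}}
  + \sum_{k=1}^{2} \Big[ a_k \cos(2\pi k t / P) + b_k \sin(2\pi k t / P) \Big]
  + \varepsilon_t,
\qquad \varepsilon_t \sim \mathrm{AR}(1)(\phi, \sigma),
$$

where

* $P$ is the cardiac period, estimated as the mean spacing of the audio
  beep markers (`estimate_period()`);
* $\tau(t)$ is a linear spline with interior knots at the cycle boundaries
  ($C - 1$ knots; two for three cycles), absorbing slow drift from tonus,
  tear film, and residual motion while staying orthogonal-ish to the
  cardiac harmonics;
* two Fourier harmonics at the cardiac fundamental capture the
  non-sinusoidal pulse shape;
* errors follow a first-order autoregression to reflect frame-to-frame
  correlation of densitometric noise.

### Estimation

`fit_harmonic()` uses **iterated Cochrane–Orcutt** with a
**Prais–Winsten** first row: given $\phi$, the model is whitened
($y_t - \phi y_{t-1}$, first observation scaled by $\sqrt{1-\phi^2}$) and
fitted by OLS, then $\phi$ is re-estimated from the lag-1 autocorrelation
of the raw-scale residuals; iterate to convergence (`tol = 1e-6`). With
the Prais–Winsten row the fixed-$\phi$ fit equals exact AR(1) GLS — the
test suite verifies agreement with a direct
$(X^\top \Sigma^{-1} X)^{-1} X^\top \Sigma^{-1} y$ oracle to `1e-8`.

Two caveats are deliberate and documented rather than patched:

* The lag-1 residual autocorrelation from a short series ($n = 75$) with
  an 8-parameter design is biased low (mean $\hat\phi \approx 0.31$ when
  the generating $\phi = 0.5$). This is intrinsic to the chosen estimator.
* Consequently, coefficient standard errors computed at $\hat\phi$ are
  slightly understated, and nominal 95% intervals cover at roughly
  0.85 rather than 0.95. With $\phi$ known they are nominal.

### Amplitude

The **pulse amplitude** is the peak-to-trough range of the fitted
two-harmonic waveform over one period (`periodic_range()`: coarse grid
plus local optimisation; checked against a dense-grid oracle). The
per-locus response is `log_amplitude` $= \log(\max(\text{amp},
10^{-3}))$ — the floor keeps near-silent loci finite; floored values are
flagged.

### Range-inflation bias correction

The range of an *estimated* waveform is upward-biased: coefficient noise
adds spurious wiggles, and a max-minus-min is a convex functional, so the
plug-in amplitude overshoots by a term first-order proportional to the
coefficient-noise SD (not variance — this is a non-smooth functional, so
the bias does not vanish at rate $\sigma^2$). At the default noise level
the inflation is a few percent and would flatten every recovered
attenuation slope by a small but systematic amount.

`fit_harmonic(bias_correct = TRUE)` (the default) removes it with a
plug-in estimate: perturb the fitted harmonic coefficients with a *fixed*,
whitened, antithetic set of 128 draws scaled by the estimated coefficient
covariance $\hat V$, and measure the mean increase of the (cheap,
240-point grid) range. Because this probe is evaluated at the already-noisy
estimate $\hat\beta$ rather than at the truth, and independent noise adds
in quadrature, the measured gap recovers only $(\sqrt{2}-1)$ of the true
inflation; the estimate is therefore rescaled by $1/(\sqrt{2}-1)$. The
correction:

* is deterministic (the draw set is frozen at load time and whitened to
  exact zero mean and identity covariance; the user's RNG state is
  untouched);
* vanishes identically for noiseless input ($\hat V = 0$), so exact
  end-to-end recovery on noiseless synthetic data is preserved;
* is clamped so amplitudes stay non-negative.

A small residual slope bias of order 0.002–0.005 log u/mm remains because
$\hat V$ itself is computed at the downward-biased $\hat\phi$; it is well
inside the simulation standard errors of 20-eye cohorts.

## 2. From videos to vessel observations

1. **Acquisition I/O** (`read_stack()`, `read_timing()`,
   `read_segmentation()`): multi-page 16-bit TIFF stacks, beep-timing
   CSVs, and indexed-PNG segmentations with a JSON legend sidecar.
   Coordinates are 1-based `(row, col)`, origin top-left — the one
   deliberate departure from 0-based pixel conventions, matching R
   indexing throughout.
2. **Alignment** (`align_frames()`, optional): integer translational
   registration of each frame to the first by cross-correlation, with a
   motion cap excluding frames that move too far; synthetic eyes are born
   aligned, so the pipeline default is off.
3. **Trim** (`trim_cycles()`): keep exactly $C$ complete cycles after the
   first beep.
4. **Loci** (`assemble_loci()`): tile the frame into 5x5 clusters; a
   locus is *valid* when at least 60% of its pixels carry one vessel
   label (the "60% rule" — guards against mixed vessel/background series
   while keeping thin-vessel coverage).
5. **Harmonic fits** (`fit_loci()`): one `fit_harmonic()` per valid
   locus.
6. **Polar mapping** (`amplitude_map()`, `to_polar()`): locus centres in
   disc-centred polar coordinates — radial distance in mm (via microns
   per pixel) and angle; hemifield by sign of the vertical offset (ties
   to superior).
7. **Annulus** (`annulus_filter()`): restrict to the **closed** interval
   0.25–1.0 mm from the disc centre; closed bounds make the boundary
   behaviour testable and deterministic.
8. **Vessel summaries** (`summarize_vessels()`): per vessel and ODF
   level, the mean and maximum locus log amplitude, and the
   **attenuation slope** — the OLS slope of locus log amplitude on radial
   distance (log u/mm), requiring at least 5 loci spanning at least
   0.2 mm (degenerate vessels yield `NA`).

The induced IOP at ODF $f$ (Meditron units, 1 mu = 3.33 g force) is
$0.89 f + \text{baseline}$ (`induced_iop()`).

## 3. Cohort statistics

`fit_lmm()` models a chosen response (e.g. `mean_logamp`) for one vessel
type with fixed effects for study group and induced IOP and random
intercepts for participant and eye:

$$
y_{ijk} = \alpha_{g(i)} + \gamma \,\mathrm{IOP}_{k}
  + u_{\text{participant}(i)} + v_{\text{eye}(i)} + e_{ijk}.
$$

Marginal group means are obtained by G-computation (averaging model
predictions over the observed covariate distribution) with delta-method
standard errors. `pairwise_contrasts()` compares every group to the
reference with Bonferroni-corrected significance
(`bonferroni_alpha(0.05, 5) = 0.01` for six groups). Singular fits drop
the participant intercept with a warning; in the synthetic cohorts
participants map 1:1 to eyes, so the participant variance is
unidentifiable and this fallback is the *normal* path there. Degenerate
(zero residual variance) fits return `NA` uncertainty but keep the
estimates. `qq_points()` provides residual normal-QQ positions
$(i - 0.5)/n$ for diagnostics.

## 4. The synthetic generator

`sim_config()` fixes the acquisition: 200x200 frames at 12 µm/pixel
(default; validation uses up to 400x400 at 6 µm/pixel), 25 Hz, 1 s
cardiac period, 5 cycles recorded / 3 analysed, ODF levels 0/20/40 mu,
baseline IOP 15 mmHg. `group_presets()` carries the six study groups —
normal (N1_N1) through central retinal vein occlusion (CRVO_CRVO), with
hemifield-vein-occlusion (HVO) groups split by hemifield — each with a
venous and arterial mean log amplitude, attenuation slope, and
between-eye SD.

An eye is built in layers:

* **Vessel tree** (`make_vessel_tree()`): radial arteries and veins with
  geometric rejection so vessels stay separated; deterministic given the
  seed.
* **Truth field** (`amplitude_field()`): log-linear amplitude along each
  vessel, $\log A = \text{intercept} + \text{slope}\, d$. The intercept
  is calibrated **at the locus level**: the observable is the log of the
  cluster-mean amplitude over a locus's labelled pixels, so calibrating
  on cluster-level values makes the annulus locus mean reproduce the
  preset mean *exactly* at zero eye offset (pixel-level calibration would
  leave a ~1e-5 Jensen gap). A per-eye intercept offset
  $\sim N(0, \text{between\_eye\_sd})$ shifts venous and arterial fields
  jointly.
* **Rendering** (`render_video()`): each vessel pixel pulses with a
  two-harmonic cardiac waveform scaled to its truth amplitude, over a
  piecewise-linear drift with breaks at cycle boundaries (exactly
  representable by the analysis spline — so noiseless recovery is exact
  to machine precision), plus AR(1) sensor noise.

**Scope.** True amplitude is held constant across ODF levels — the force
sweep supplies repeated-measures structure, not an amplitude-IOP dose
response, because no such quantitative model is part of the design.
Motion, illumination drift across the field, and optic-media effects are
not emulated. Fellow-eye pairing exists only for the HVO groups (the two
hemifield groups share physical eyes); all other participants contribute
one eye.

**Layering for statistical validation.** Type-I-error calibration of the
group comparison (hundreds of replicate cohorts) runs on
`simulate_observations()`, a fast observation-level layer that draws
vessel summaries directly from the preset model — rendering and
re-analysing 200 video cohorts would be computationally absurd and would
test the same statistics through a slower path. The full video path is
validated separately by seeded end-to-end cohorts
(`run_cohort()`), whose recovered means and slopes are checked against
the presets within simulation standard error.

## 5. Problem sizes and reproducibility

A 20-eye cohort at the default configuration (200x200, 3 ODF levels)
renders, fits (~1,500 locus regressions per eye), and summarises in a few
minutes on one core with flat memory (`run_cohort()` streams eye by eye).
All stochastic steps are seeded; `derive_seeds()` expands one master seed
into per-eye seeds so cohorts are bit-reproducible. `write_cohort()` /
the readers round-trip an entire cohort through 16-bit TIFF within one
quantisation step.

```{r example}
library(retppg)
res <- run_cohort(group_presets("N1_N1"), n_eyes_per_group = 2, seed = 1)
cohort_summary(res$observations)
```
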