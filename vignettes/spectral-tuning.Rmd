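---
title: "Methods: from ERG flashes and skin reflectance to spectral tuning"
author: "ergtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ERG flashes and skin reflectance to spectral tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergtune)
```

## The problem

Diurnal poison frogs differ enormously in skin coloration — from bright
aposematic morphs to cryptic brown species — and a natural question in
sensory ecology is whether the retina of each morph is tuned to the
light its own skin reflects (the matched-filter hypothesis). Answering
it requires three quantitative strands: (i) spectrometer reflectance
curves reduced to comparable summary metrics, (ii) whole-body
coloration scores from calibrated photographs, and (iii) retinal
spectral sensitivity measured by electroretinogram (ERG) flash series.
`ergtune` implements all three strands plus the statistical layer that
compares them, and ships seeded synthetic-data generators so that every
stage can be validated against known ground truth without laboratory
recordings.

## The V-log(I) model

The core estimator is `fit_boltzmann()`. For one animal and one
stimulus wavelength, the b-wave amplitude of the flash-evoked ERG grows
sigmoidally with flash strength. After normalizing amplitudes to their
maximum, the relative amplitude as a function of the log10 flash
intensity $f$ is modeled by the fixed-asymptote Boltzmann sigmoid

$$V(f) = \frac{A_1 - A_2}{1 + e^{(f - f_0)/\tau}} + A_2,
  \qquad A_1 = 0,\; A_2 = 1,$$

with two free parameters: $f_0$ (`flash0`), the log intensity at
half-maximal response, and the slope $\tau > 0$. The spectral
*threshold* is the intensity at which the fitted curve reaches 10% of
maximum; inverting the sigmoid gives the closed form

$$f_{thr} = f_0 - \tau\,\ln 9,$$

so the threshold is always below the half-max intensity and shifts
one-for-one with `flash0`. A tuning curve is the group mean (± SE) of
these thresholds across stimulus wavelengths; lower threshold means
higher sensitivity.

```{r}
f <- seq(-5, 0, by = 0.5)
fit <- fit_boltzmann(f, boltzmann_value(f, flash0 = -2, tau = 0.5))
coef(fit)
threshold_10pct(fit)
```

### Estimation and numerical choices

The two parameters are estimated by Levenberg–Marquardt least squares
(via `minpack.lm::nls.lm`) with an analytic Jacobian, $\tau$ bounded
below by $10^{-8}$, and a parameter tolerance of $10^{-10}$. Two starts
are tried and the lower-RSS solution kept:

* the point heuristic — `flash0` at the flash whose amplitude is
  nearest 0.5 and $\tau$ at one quarter of the tested range; and
* a logit linearization — regressing $\mathrm{logit}(y)$ on $f$ for
  points away from the asymptotes.

The second start matters for steep curves: when the true $\tau$ is much
smaller than the heuristic start, a single descent can collapse onto
the $\tau$ bound (a step-function local minimum) instead of the global
one. Fits need at least 4 points; a fit whose amplitudes span less than
0.3 of relative amplitude is returned but marked unusable and excluded
from tuning curves, and zero dynamic range is an error.

### Normalization scope and its saturation bias

Amplitudes are normalized by the *observed* maximum. The default unit
is (animal, wavelength): because the fit pins the upper asymptote at 1,
dividing by the within-curve maximum is the internally consistent
choice. A `per_animal` mode (dividing by the animal's global maximum
across wavelengths) is also provided, since published descriptions of
this normalization are ambiguous and the global-max reading is common.

One consequence deserves emphasis: the observed maximum equals the true
saturating amplitude only when the intensity series actually saturates
the response. If the top of the tested grid sits short of saturation,
every normalized point is inflated by $1/V(f_{max})$, the rescaled data
leave the $A_2 = 1$ family, and the fitted parameters are biased — an
intrinsic property of max-normalization, not of the optimizer. The
package's exact round-trip validations therefore use generating
parameters that saturate within the default grid; with realistic
slopes ($\tau \approx 0.45$) and the default grid the residual bias is
small relative to measurement noise but not zero.

## Trace processing

Raw flash responses are processed in three steps, each with an explicit
rule where published protocols say only "we corrected / averaged /
measured":

* **DC correction** (`dc_correct`): the averaged no-light response is
  reduced to its time-averaged mean and that scalar is subtracted from
  every trace.
* **Flash averaging** (`average_flashes`): responses are the mean of
  nominally four flashes. A trace whose pre-stimulus RMS exceeds 5× the
  median pre-stimulus RMS of its set is rejected as spurious noise; at
  most one trace may be dropped and at least three must remain,
  otherwise the step is flagged for manual review. The 5× factor is a
  deterministic stand-in for by-eye artifact rejection and is
  configurable.
* **b-wave measurement** (`measure_bwave`): the default convention is
  trough-to-peak — the a-wave trough (minimum within 0–60 ms after
  onset) to the b-wave peak (maximum within 20–200 ms after onset and
  later than the trough) — which is standard electrophysiological
  practice; a baseline-to-peak alternative is a config switch, and the
  choice is recorded in pipeline output. The search windows are
  declared defaults, not values inferred from any dataset.

## Reflectance curve metrics

`compute_metrics()` reduces a percent-reflectance curve to four
numbers: peak wavelength, FWHM, AUC and average reflectance.
Deliberate choices where definitions are open:

* the half-max reference is half of the *global maximum* (not
  peak-minus-baseline);
* FWHM crossings are located by linear interpolation of the samples
  nearest the peak on each side, and clipped to the grid boundary (with
  a flag) when a side never drops below half max — so a flat curve on a
  400 nm grid has FWHM 400 with both clip flags;
* AUC is the trapezoidal integral above 0% reflectance by default (a
  min-of-curve baseline is a config option);
* peak ties break toward the lowest wavelength, flagged.

On a 1 nm grid a Gaussian peak of amplitude $A$ and width $\sigma$
recovers the analytic $2\sigma\sqrt{2\ln 2}$ bandwidth and
$A\sigma\sqrt{2\pi}$ area to well under the package's test tolerances
(0.5 nm and 0.1%).

## Area-scaled photographic scores

A marking's total reflectance is the sum of its calibrated R, G and B
values (0–765 a.u.). A surface's score is
$\sum_m (R+G+B)_m \cdot a_m / A$, the reflectance of each marking
weighted by the *fraction* of the surface it occupies; the per-frog
score adds dorsal and lateral surfaces. Weighting by fraction (not raw
mm²) keeps the score within [0, 765] per surface and matches the
arbitrary-unit scale on which such scores are reported. Unmarked skin
contributes zero unless listed explicitly as a background marking. RGB
values are assumed already color-managed; no color calibration is
performed here.

## Statistical layer

* **PCA** (`pca_metrics`): correlation PCA (centered, unit-scaled) of
  the four curve metrics; component signs are fixed by making each
  component's dominant loading positive so score plots are
  reproducible; per-group convex hulls summarize (PC1, PC2) clouds.
* **One-way ANOVA** (`one_way_anova`): classical decomposition with
  Tukey HSD pairwise comparisons and a compact-letter display computed
  from the maximal cliques of the not-significantly-different graph,
  ties broken alphabetically.
* **Two-way ANOVA** (`two_way_anova`): wavelength × group factorial
  with interaction, Type II sums of squares for unbalanced data (on
  balanced data these equal sequential SS, so balanced validations are
  SS-type-invariant). Wavelength levels missing from some groups — the
  UV stimulus is typically tested only in a subset — are dropped with a
  warning. Pairwise group contrasts use unweighted marginal means with
  the model MSE; when the interaction is significant, within-wavelength
  simple effects are added; all contrasts are Bonferroni-corrected
  together. Zero-residual (noise-free) designs fall back to explicit
  model-comparison SS with F undefined.
* **Assumption screen** (`assumption_checks`): Levene's test on
  absolute deviations from group means, and per-group normality by the
  Lilliefors-corrected Kolmogorov–Smirnov test — the correct null when
  the normal's moments are estimated from the sample. A naive KS
  against sample moments is exposed for comparison; it is badly
  conservative and kept only because published methods are often
  ambiguous about which was used. KS-family tests have modest power
  against platykurtic alternatives at moderate n (vs a uniform sample,
  Lilliefors at $n = 200$ rejects at the 1% level in roughly three
  quarters of samples; near-certain rejection needs $n \approx 400$).
* **Matched-filter report** (`matched_filter_report`): per group, the
  stimulus wavelength of minimum mean threshold versus the wavelength
  of peak mean dorsal reflectance, and their absolute mismatch in nm.
  The sensitivity side is an argmin over tested stimuli (a 50 nm
  grid), so mismatches are bounded below by stimulus spacing; no
  significance claim is attached.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study's data with known
ground truth:

* `generate_spectrum()`: baseline + 0–2 Gaussian peaks over 300–700 nm
  with additive noise, clipped at zero — the shapes of dorsal
  reflectance curves, not their full natural complexity (no UV
  double-peaks, no measurement-geometry artifacts).
* `generate_erg_experiment()`: traces built from a negative a-wave
  bump (trough 30 ms after onset, σ 8 ms) and positive b-wave bump
  (peak 80 ms, σ 20 ms), a-wave height fixed at 25% of the b-wave,
  sampled at 1 kHz for 300 ms with flash onset at 50 ms; the noiseless
  trough-to-peak excursion is proportional to
  $V_{max}\cdot V(f; f_0, \tau)$. Only that amplitude law matters
  downstream — waveform kinetics, photoreceptor-class mixtures and
  adaptation are deliberately not modeled, so passing tests validate
  the analysis chain, not retinal biophysics. Optional artifact traces
  carry 10× noise to exercise the rejection rule.
* `generate_cohort()` / `simulate_cohort_amplitudes()`: per-animal,
  per-wavelength true parameters around a baseline tuning shape (most
  sensitive at 550–600 nm, default $\tau = 0.45$, between-animal SD
  0.1 log units), an additive per-group per-wavelength effect map, and
  observed relative amplitudes with additive Gaussian noise (default
  SD 0.05). The default intensity grid is −5.0 to 0.0 log10
  µmol·m⁻²·s⁻¹ in 0.5 steps; published protocols rarely state
  neutral-density step sizes, so this is a declared choice.
* `simulate_study()` writes a complete bundle mirroring the headline
  morph comparison: two groups of 11 animals, one group's true
  `flash0` lowered by 0.5 log units at 450 and 550 nm, and dorsal
  spectra peaking near 560 vs 642 nm.

Validation sizes are chosen so the full suite runs in a couple of
minutes on one core: 500-replicate parameter-recovery simulations,
2000-replicate type-I checks, a 100-replicate end-to-end power study,
and $10^5$-observation PCA checks.

## Known limitations

* Max-normalization bias off saturation, as discussed above.
* Thresholds below the lowest tested intensity are extrapolations of
  the fitted sigmoid; they are flagged, not suppressed.
* The matched-filter mismatch inherits the 50 nm stimulus spacing on
  the sensitivity side.
* No visual-system modeling (cone catches, receptor noise, ocular
  media) and no opsin-template fitting: the package quantifies signals
  and gross retinal sensitivity, not mechanisms.
* The compact-letter display can be non-unique for pathological
  p-value patterns; the clique ordering makes the output deterministic.
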