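# ergtune

Tools for relating **skin spectral reflectance** to **retinal spectral
sensitivity** in diurnal frogs (and similar visual-ecology study
designs). The package covers the three quantitative strands such a
study needs and the statistics that connect them:

1. **Spectrometry** — percent-reflectance curves reduced to peak
   wavelength (nm), full width at half maximum (nm), area under the
   curve (%·nm) and average reflectance (%).
2. **Calibrated photography** — per-marking RGB and area tables turned
   into area-scaled total reflectance scores,
   Σₘ (R+G+B)ₘ · areaₘ / total area, per surface and per frog.
3. **Electroretinography** — flash-evoked traces processed into
   V-log(I) curves and fitted with the fixed-asymptote Boltzmann
   sigmoid

   V(f) = (A₁ − A₂) / (1 + e^{(f − f₀)/τ}) + A₂,  A₁ = 0, A₂ = 1,

   where f is log₁₀ flash intensity, f₀ (`flash0`) the half-max
   intensity and τ the slope. The spectral threshold is the 10%-of-max
   intensity, analytically f₀ − τ·ln 9; thresholds across stimulus
   wavelengths form group tuning curves (mean ± SE).

A statistical layer provides correlation PCA of the curve metrics,
one-way ANOVA with Tukey HSD and compact letters, two-way
(wavelength × group) ANOVA with Type II sums of squares and
Bonferroni-corrected contrasts, Levene/Lilliefors assumption checks,
and a matched-filter report comparing each group's tuning-curve minimum
with its dorsal reflectance peak. Seeded synthetic-data generators
(`generate_spectrum`, `generate_erg_experiment`, `generate_cohort`,
`simulate_study`) produce all of these inputs with recorded ground
truth, so the entire pipeline is testable end to end.

## Worked example

Fit a noisy V-log(I) series and extract its threshold:

```r
library(ergtune)
set.seed(7)
f <- seq(-5, 0, by = 0.5)                       # log10 umol m-2 s-1
y <- boltzmann_value(f, flash0 = -2.6, tau = 0.45) + rnorm(11, 0, 0.05)
fit <- fit_boltzmann(f, y)
fit
#> Boltzmann V-log(I) fit (A1 = 0, A2 = 1)
#>   flash0 (half-max log I): -2.546
#>   tau (slope):             0.3855
#>   RSS 0.0301 on 11 points; converged: TRUE; usable: TRUE
threshold_10pct(fit)
#>   threshold_log_intensity extrapolated
#> 1               -3.392619        FALSE
```

The estimated half-max intensity (−2.55) and slope (0.39) sit close to
the generating values (−2.6, 0.45); the threshold −3.39 log units is
the intensity at which the fitted curve crosses 10% of maximum, and it
lies inside the tested range (not extrapolated).

Reduce a synthetic dorsal reflectance spectrum to its curve metrics:

```r
curve <- generate_spectrum(baseline_pct = 5,
                           peaks = list(c(560, 55, 45)),   # center, amp, sigma
                           noise_sd_pct = 1, grid = c(300, 700, 1), seed = 7)
compute_metrics(curve)
#> peak 562 nm | FWHM 106.59 nm | AUC 8215.2 %*nm | mean 20.50 %
```

A full synthetic study — two morph groups of 11 animals whose true
sensitivity differs by 0.5 log units at 450 and 550 nm, with matching
dorsal spectra — runs in one call each:

```r
simulate_study("study", seed = 1)
res <- run_pipeline(default_config(input_dir = "study", out_dir = "study/out",
                                   seed = 1))
res$erg_anova$table     # wavelength x group ANOVA on thresholds
res$match_report        # tuning minimum vs reflectance peak, per group
```

All output tables are written as CSV stamped with the config hash,
beside a JSON run manifest; rerunning with the same seed and config
reproduces them byte for byte.

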