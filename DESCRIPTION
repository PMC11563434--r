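Package: ergtune
Title: Spectral Tuning Curves from Electroretinogram Flash Responses and
    Skin Reflectance Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating skin spectral reflectance to retinal
    spectral sensitivity in diurnal frogs. Quantifies spectrometer
    reflectance curves (peak wavelength, full width at half maximum, area
    under the curve, average reflectance), computes area-scaled total
    reflectance scores from calibrated-photograph marking tables, and
    processes electroretinogram (ERG) flash responses into V-log(I)
    curves: DC correction against no-light flashes, artifact-aware flash
    averaging, b-wave amplitude measurement, per-animal normalization,
    least-squares Boltzmann sigmoid fits, analytic 10%-of-maximum
    threshold interpolation, and group spectral tuning curves. A
    statistical layer provides PCA of curve metrics, one-way ANOVA with
    Tukey HSD and compact-letter displays, two-way factorial ANOVA with
    Type II sums of squares and Bonferroni-corrected contrasts,
    variance-homogeneity and normality checks, and a matched-filter
    comparison of tuning curves against dorsal reflectance spectra.
    Seeded synthetic-data generators with recorded ground truth make the
    whole pipeline testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    car,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
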