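#' DC correction of ERG traces against no-light flashes
#'
#' Recording chains carry a DC shift; each experiment therefore begins
#' with no-light flashes. The averaged no-light response is reduced to
#' its time-averaged mean and that scalar is subtracted from every
#' stimulus trace.
#'
#' @param traces list of ERG traces (each a list/data frame with
#'   `time_ms` and `voltage_uv`).
#' @param no_light_traces list of at least one no-light trace with the
#'   same sampling.
#' @return The input traces with corrected `voltage_uv`, plus attribute
#'   `dc_offset_uv` giving the subtracted scalar.
#' @export
dc_correct <- function(traces, no_light_traces) {
  if (!length(no_light_traces))
    stop("at least one no-light trace is required for DC correction",
         call. = FALSE)
  t0 <- no_light_traces[[1]]$time_ms
  for (tr in c(traces, no_light_traces)) {
    if (length(tr$time_ms) != length(t0) ||
        any(abs(tr$time_ms - t0) > 1e-9))
      stop("all traces must share the same sampling for DC correction",
           call. = FALSE)
  }
  nl_avg <- rowMeans(vapply(no_light_traces, function(tr) tr$voltage_uv,
                            numeric(length(t0))))
  dc <- mean(nl_avg)
  out <- lapply(traces, function(tr) {
    tr$voltage_uv <- tr$voltage_uv - dc
    tr
  })
  attr(out, "dc_offset_uv") <- dc
  out
}

pre_stimulus_rms <- function(trace) {
  pre <- trace$voltage_uv[trace$time_ms < trace$flash_onset_ms]
  if (!length(pre)) return(NA_real_)
  sqrt(mean((pre - mean(pre))^2))
}

#' Average repeated flashes with artifact rejection
#'
#' Responses at one (wavelength, intensity) step are the average of
#' repeated flashes (nominally four). A trace whose pre-stimulus RMS
#' (about its own pre-stimulus mean) exceeds `reject_factor` times the
#' median pre-stimulus RMS of the set is rejected as a spurious-noise
#' artifact; at most one trace may be rejected and at least three must
#' remain, otherwise the step is flagged for manual review.
#'
#' @param traces list of >= 3 traces sharing sampling and
#'   `flash_onset_ms`.
#' @param reject_factor multiple of the median pre-stimulus RMS above
#'   which a trace is rejected (default 5).
#' @return A list with the point-wise `average` trace, `n_used`, and
#'   `rejected` (indices of excluded traces).
#' @export
average_flashes <- function(traces, reject_factor = 5) {
  if (length(traces) < 3L)
    stop("fewer than 3 flashes at this step: flagged for manual review",
         call. = FALSE)
  t0 <- traces[[1]]$time_ms
  for (tr in traces)
    if (length(tr$time_ms) != length(t0) || any(abs(tr$time_ms - t0) > 1e-9))
      stop("traces must share the same sampling", call. = FALSE)
  rms <- vapply(traces, pre_stimulus_rms, numeric(1))
  bad <- which(rms > reject_factor * stats::median(rms))
  if (length(bad) > 1L)
    stop("more than one trace fails the artifact criterion: ",
         "flagged for manual review", call. = FALSE)
  keep <- setdiff(seq_along(traces), bad)
  if (length(keep) < 3L)
    stop("fewer than 3 traces remain after artifact rejection: ",
         "flagged for manual review", call. = FALSE)
  v <- rowMeans(vapply(traces[keep], function(tr) tr$voltage_uv,
                       numeric(length(t0))))
  avg <- traces[[keep[1]]]
  avg$voltage_uv <- v
  list(average = avg, n_used = length(keep), rejected = bad)
}

#' Measure the b-wave amplitude of an averaged ERG trace
#'
#' The flash response shows the negative a-wave (photoreceptor
#' hyperpolarization) followed by the positive b-wave (bipolar-cell
#' depolarization). In `"trough_to_peak"` mode (default) the amplitude
#' is the voltage difference from the a-wave trough — the minimum within
#' 0-60 ms after flash onset — to the b-wave peak — the maximum within
#' 20-200 ms after onset and later than the trough. `"baseline_to_peak"`
#' measures the b-wave peak relative to 0 (a DC-corrected trace). If no
#' peak occurs later than the trough the function warns and falls back
#' to baseline-to-peak.
#'
#' @param trace DC-corrected averaged trace with `time_ms`,
#'   `voltage_uv`, `flash_onset_ms`.
#' @param mode amplitude convention.
#' @param trough_window_ms,peak_window_ms search windows after onset.
#' @return b-wave amplitude in microvolts.
#' @export
measure_bwave <- function(trace, mode = c("trough_to_peak", "baseline_to_peak"),
                          trough_window_ms = c(0, 60),
                          peak_window_ms = c(20, 200)) {
  mode <- match.arg(mode)
  rel <- trace$time_ms - trace$flash_onset_ms
  pk_sel <- rel >= peak_window_ms[1] & rel <= peak_window_ms[2]
  if (!any(pk_sel)) stop("peak search window contains no samples", call. = FALSE)
  if (mode == "baseline_to_peak")
    return(max(trace$voltage_uv[pk_sel]))
  tr_sel <- rel >= trough_window_ms[1] & rel <= trough_window_ms[2]
  if (!any(tr_sel)) stop("trough search window contains no samples", call. = FALSE)
  i_tr <- which(tr_sel)[which.min(trace$voltage_uv[tr_sel])]
  after <- pk_sel & seq_along(rel) > i_tr
  if (!any(after)) {
    warning("b-wave peak not later than a-wave trough; ",
            "falling back to baseline-to-peak")
    return(max(trace$voltage_uv[pk_sel]))
  }
  max(trace$voltage_uv[after]) - trace$voltage_uv[i_tr]
}

#' Normalize b-wave amplitudes to their maximum
#'
#' Converts absolute b-wave amplitudes into relative amplitudes by
#' dividing by the maximum within a normalization unit, so the unit
#' maximum is exactly 1. The default unit is (animal, wavelength),
#' consistent with fitting a sigmoid whose upper asymptote is fixed at
#' 1 per V-log(I) curve; `"per_animal"` divides by the animal's global
#' maximum across wavelengths instead.
#'
#' @param points data frame with columns `animal_id`, `wavelength_nm`,
#'   `log_intensity`, `bwave_uv`.
#' @param mode `"per_wavelength"` (default) or `"per_animal"`.
#' @return The input with a `relative_amplitude` column added.
#' @export
normalize_amplitudes <- function(points, mode = c("per_wavelength", "per_animal")) {
  mode <- match.arg(mode)
  need <- c("animal_id", "wavelength_nm", "log_intensity", "bwave_uv")
  if (!all(need %in% names(points)))
    stop("points must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  unit <- if (mode == "per_wavelength")
    paste(points$animal_id, points$wavelength_nm, sep = "\r")
  else as.character(points$animal_id)
  mx <- tapply(points$bwave_uv, unit, max)
  if (any(mx <= 0))
    stop("all-zero (or negative) amplitudes in normalization unit ",
         gsub("\r", "/", names(mx)[mx <= 0][1]), call. = FALSE)
  points$relative_amplitude <- points$bwave_uv / as.numeric(mx[unit])
  points
}

#' Fit V-log(I) curves and extract 10% thresholds for a whole experiment
#'
#' Convenience wrapper running, per (animal, wavelength) cell of a
#' pre-extracted amplitude table: normalization (unless the table
#' already carries `relative_amplitude`), [fit_boltzmann()], and
#' [threshold_10pct()]. Unusable fits (unconverged or dynamic range
#' below the cutoff) are kept in the fits table but excluded from the
#' thresholds table.
#'
#' @param points data frame with `animal_id`, `wavelength_nm`,
#'   `log_intensity`, and either `bwave_uv` or `relative_amplitude`.
#' @param normalization passed to [normalize_amplitudes()]; ignored when
#'   `relative_amplitude` is already present.
#' @param ... passed to [fit_boltzmann()].
#' @return A list with data frames `points`, `fits` (`animal_id`,
#'   `wavelength_nm`, `flash0`, `tau`, `rss`, `n_points`, `converged`,
#'   `usable`) and `thresholds` (`animal_id`, `wavelength_nm`,
#'   `threshold_log_intensity`, `extrapolated`), plus the list of
#'   `boltzmann_fit` objects.
#' @export
erg_thresholds <- function(points, normalization = "per_wavelength", ...) {
  if (!"relative_amplitude" %in% names(points))
    points <- normalize_amplitudes(points, mode = normalization)
  key <- interaction(points$animal_id, points$wavelength_nm, drop = TRUE)
  cells <- split(points, key)
  fits <- lapply(cells, function(d) fit_boltzmann(
    d$log_intensity, d$relative_amplitude, ...))
  fit_tab <- do.call(rbind, Map(function(d, f) data.frame(
    animal_id = d$animal_id[1], wavelength_nm = d$wavelength_nm[1],
    flash0 = f$flash0, tau = f$tau, rss = f$rss, n_points = f$n_points,
    converged = f$converged, usable = f$usable), cells, fits))
  thr_tab <- do.call(rbind, Map(function(d, f) {
    if (!f$usable) return(NULL)
    th <- threshold_10pct(f, tested_range = range(d$log_intensity))
    data.frame(animal_id = d$animal_id[1], wavelength_nm = d$wavelength_nm[1],
               threshold_log_intensity = th$threshold_log_intensity,
               extrapolated = th$extrapolated)
  }, cells, fits))
  rownames(fit_tab) <- NULL
  if (!is.null(thr_tab)) rownames(thr_tab) <- NULL
  list(points = points, fits = fit_tab, thresholds = thr_tab,
       fit_objects = fits)
}

#' Group spectral tuning curves from per-animal thresholds
#'
#' A tuning curve is the mean 10% threshold (± SE) as a function of
#' stimulus wavelength for a group of animals. Cells with no thresholds
#' are absent from the curve (some stimulus wavelengths are only tested
#' in a subset of groups); SE is `NA` when a cell holds one animal.
#'
#' @param thresholds data frame with `wavelength_nm` and
#'   `threshold_log_intensity` (e.g. from [erg_thresholds()]).
#' @param groups vector of group labels, one per row of `thresholds`,
#'   or the name of a column of `thresholds`.
#' @return A data frame of class `"tuning_curve"` with `group`,
#'   `wavelength_nm`, `mean_threshold`, `se`, `n`.
#' @export
build_tuning_curve <- function(thresholds, groups = "group") {
  if (!nrow(thresholds)) stop("no thresholds supplied", call. = FALSE)
  if (is.character(groups) && length(groups) == 1L &&
      groups %in% names(thresholds))
    groups <- thresholds[[groups]]
  if (length(groups) != nrow(thresholds))
    stop("'groups' must give one label per threshold", call. = FALSE)
  key <- paste(groups, thresholds$wavelength_nm, sep = "\r")
  agg <- function(f) tapply(thresholds$threshold_log_intensity, key, f)
  m <- agg(mean); n <- agg(length)
  s <- agg(stats::sd)
  parts <- strsplit(names(m), "\r", fixed = TRUE)
  out <- data.frame(
    group = vapply(parts, `[`, character(1), 1),
    wavelength_nm = as.numeric(vapply(parts, `[`, character(1), 2)),
    mean_threshold = as.numeric(m),
    se = ifelse(n > 1, as.numeric(s) / sqrt(as.numeric(n)), NA_real_),
    n = as.integer(n))
  out <- out[order(out$group, out$wavelength_nm), ]
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' @export
plot.tuning_curve <- function(x, ..., xlab = "Wavelength (nm)",
                              ylab = expression(Threshold~(log[10]~mu*mol/m^2/s))) {
  grp <- unique(x$group)
  cols <- grDevices::hcl.colors(max(length(grp), 2L), "Dark 3")[seq_along(grp)]
  graphics::plot(range(x$wavelength_nm),
                 range(c(x$mean_threshold - ifelse(is.na(x$se), 0, x$se),
                         x$mean_threshold + ifelse(is.na(x$se), 0, x$se))),
                 type = "n", xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(grp)) {
    d <- x[x$group == grp[i], ]
    graphics::lines(d$wavelength_nm, d$mean_threshold, col = cols[i])
    graphics::points(d$wavelength_nm, d$mean_threshold, col = cols[i], pch = 16)
    ok <- !is.na(d$se)
    if (any(ok))
      graphics::arrows(d$wavelength_nm[ok], d$mean_threshold[ok] - d$se[ok],
                       d$wavelength_nm[ok], d$mean_threshold[ok] + d$se[ok],
                       angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("topright", legend = grp, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Process raw ERG traces for one (animal, wavelength) experiment
#'
#' Runs the trace-level chain: DC correction against the no-light
#' flashes, per-intensity-step flash averaging with artifact rejection,
#' and b-wave measurement, yielding the amplitude table consumed by
#' [erg_thresholds()].
#'
#' @param experiment a list as produced by [generate_erg_experiment()]:
#'   elements `traces` (list of lists of traces, one list per intensity
#'   step, each trace carrying `stimulus` metadata), `no_light` (list of
#'   no-light traces).
#' @param bwave_mode passed to [measure_bwave()].
#' @param reject_factor passed to [average_flashes()].
#' @return Data frame `animal_id`, `wavelength_nm`, `log_intensity`,
#'   `bwave_uv`, `n_flashes_used`.
#' @export
process_erg_traces <- function(experiment, bwave_mode = "trough_to_peak",
                               reject_factor = 5) {
  steps <- experiment$traces
  out <- lapply(steps, function(step) {
    corrected <- dc_correct(step, experiment$no_light)
    avg <- average_flashes(corrected, reject_factor = reject_factor)
    st <- step[[1]]$stimulus
    data.frame(animal_id = st$animal_id, wavelength_nm = st$wavelength_nm,
               log_intensity = st$log_intensity,
               bwave_uv = measure_bwave(avg$average, mode = bwave_mode),
               n_flashes_used = avg$n_used)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
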