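#' Generate a synthetic reflectance spectrum
#'
#' Builds a smooth percent-reflectance curve as a baseline plus 0 or
#' more Gaussian peaks, with optional additive Gaussian measurement
#' noise, clipped at 0% reflectance. The generating profile is retained
#' in the curve metadata as ground truth.
#'
#' @param baseline_pct non-negative baseline reflectance.
#' @param peaks data frame (or list of length-3 vectors) with columns
#'   `center_nm`, `amplitude_pct`, `sigma_nm`; may be empty.
#' @param noise_sd_pct standard deviation of additive noise.
#' @param grid `c(start_nm, stop_nm, step_nm)` wavelength grid.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param meta extra metadata merged into the curve.
#' @return A [spectrum_curve()] whose `meta$truth` records the profile.
#' @export
generate_spectrum <- function(baseline_pct = 0, peaks = NULL,
                              noise_sd_pct = 0, grid = c(300, 700, 1),
                              seed = NULL, meta = list()) {
  if (length(grid) != 3L || grid[1] >= grid[2] || grid[3] <= 0)
    stop("'grid' must be c(start, stop, step) with start < stop and step > 0",
         call. = FALSE)
  if (baseline_pct < 0) stop("'baseline_pct' must be >= 0", call. = FALSE)
  pk <- normalize_peaks(peaks)
  if (nrow(pk) && (any(pk$sigma_nm <= 0) || any(pk$amplitude_pct < 0)))
    stop("peaks need sigma_nm > 0 and amplitude_pct >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  wl <- seq(grid[1], grid[2], by = grid[3])
  val <- rep(baseline_pct, length(wl))
  for (i in seq_len(nrow(pk)))
    val <- val + pk$amplitude_pct[i] *
      exp(-(wl - pk$center_nm[i])^2 / (2 * pk$sigma_nm[i]^2))
  if (noise_sd_pct > 0) val <- val + stats::rnorm(length(wl), 0, noise_sd_pct)
  val <- pmax(val, 0)
  meta$truth <- list(baseline_pct = baseline_pct, peaks = pk,
                     noise_sd_pct = noise_sd_pct, grid = grid, seed = seed)
  spectrum_curve(wl, val, meta = meta)
}

normalize_peaks <- function(peaks) {
  if (is.null(peaks) || (is.data.frame(peaks) && !nrow(peaks)))
    return(data.frame(center_nm = numeric(), amplitude_pct = numeric(),
                      sigma_nm = numeric()))
  if (!is.data.frame(peaks))
    peaks <- as.data.frame(do.call(rbind, lapply(peaks, function(p) {
      stats::setNames(as.numeric(p[1:3]),
                      c("center_nm", "amplitude_pct", "sigma_nm"))
    })))
  peaks
}

#' Generate a marking table for one photographed frog
#'
#' Converts per-surface marking specifications given as area fractions
#' into the marking and surface tables consumed by
#' [scaled_reflectance()]. Area fractions on one surface must sum to at
#' most 1 (unmarked skin makes up the remainder).
#'
#' @param markings data frame with columns `surface`, `marking_label`,
#'   `r`, `g`, `b`, `fraction`.
#' @param total_areas named numeric vector of total surface areas in
#'   mm2, one entry per surface appearing in `markings` (surfaces
#'   without markings may also be listed and score 0).
#' @param frog_id identifier attached to every row.
#' @return List with data frames `markings` (`frog_id`, `surface`,
#'   `marking_label`, `r`, `g`, `b`, `area_mm2`) and `surfaces`
#'   (`frog_id`, `surface`, `total_area_mm2`).
#' @export
generate_marking_table <- function(markings, total_areas, frog_id = "frog1") {
  need <- c("surface", "marking_label", "r", "g", "b", "fraction")
  if (!all(need %in% names(markings)))
    stop("markings must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(markings$fraction < 0))
    stop("area fractions must be non-negative", call. = FALSE)
  tot_frac <- tapply(markings$fraction, markings$surface, sum)
  if (any(tot_frac > 1 + 1e-12))
    stop("area fractions sum to more than 1 on surface ",
         names(tot_frac)[tot_frac > 1 + 1e-12][1], call. = FALSE)
  surf <- unique(c(markings$surface, names(total_areas)))
  missing <- setdiff(markings$surface, names(total_areas))
  if (length(missing))
    stop("no total area given for surface ", missing[1], call. = FALSE)
  mk <- data.frame(frog_id = frog_id, surface = markings$surface,
                   marking_label = markings$marking_label,
                   r = markings$r, g = markings$g, b = markings$b,
                   area_mm2 = markings$fraction *
                     as.numeric(total_areas[markings$surface]))
  sf <- data.frame(frog_id = frog_id, surface = surf,
                   total_area_mm2 = as.numeric(total_areas[surf]))
  list(markings = mk, surfaces = sf)
}

erg_trace_template <- function(time_ms, onset_ms, amplitude_uv,
                               a_frac = 0.25,
                               a_lag_ms = 30, a_sigma_ms = 8,
                               b_lag_ms = 80, b_sigma_ms = 20) {
  # a-wave and b-wave as opposite-signed Gaussian bumps; heights chosen
  # so the trough-to-peak excursion is proportional to amplitude_uv
  b_h <- amplitude_uv / (1 + a_frac)
  a_h <- a_frac * b_h
  -a_h * exp(-(time_ms - onset_ms - a_lag_ms)^2 / (2 * a_sigma_ms^2)) +
    b_h * exp(-(time_ms - onset_ms - b_lag_ms)^2 / (2 * b_sigma_ms^2))
}

#' Generate a synthetic ERG flash experiment for one animal and wavelength
#'
#' For every step of the intensity grid, produces `n_flashes` voltage
#' traces whose noiseless b-wave excursion is proportional to
#' `max_bwave_uv * boltzmann_value(flash, flash0, tau)`, shaped as a
#' negative a-wave bump followed by a positive b-wave bump, plus a DC
#' offset and Gaussian noise. Four no-light traces containing only the
#' DC offset and noise are included for DC correction. Optionally, one
#' trace per selected step carries 10x noise to exercise artifact
#' rejection.
#'
#' @param animal_id,wavelength_nm identifiers recorded on each trace.
#' @param flash0,tau,max_bwave_uv true Boltzmann parameters and
#'   saturating amplitude (uV).
#' @param intensity_grid strictly increasing log10 intensities.
#' @param noise_sd_uv,dc_offset_uv trace noise SD and DC shift.
#' @param n_flashes flashes per intensity step (default 4).
#' @param artifact_steps integer indices of steps receiving one
#'   artifact trace.
#' @param sample_rate_hz,duration_ms,flash_onset_ms trace timing.
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return List with `traces` (one list of traces per intensity step),
#'   `no_light` (4 traces) and `truth` (all generating parameters).
#' @export
generate_erg_experiment <- function(animal_id = "a1", wavelength_nm = 500,
                                    flash0 = -2.5, tau = 0.45,
                                    max_bwave_uv = 150,
                                    intensity_grid = seq(-5, 0, by = 0.5),
                                    noise_sd_uv = 0, dc_offset_uv = 0,
                                    n_flashes = 4, artifact_steps = integer(0),
                                    sample_rate_hz = 1000, duration_ms = 300,
                                    flash_onset_ms = 50, seed = NULL) {
  if (!length(intensity_grid))
    stop("intensity grid must not be empty", call. = FALSE)
  if (any(diff(intensity_grid) <= 0))
    stop("intensity grid must be strictly increasing", call. = FALSE)
  if (tau <= 0 || max_bwave_uv <= 0)
    stop("'tau' and 'max_bwave_uv' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  time_ms <- seq(0, duration_ms - 1000 / sample_rate_hz,
                 by = 1000 / sample_rate_hz)

  mk_trace <- function(amp, sd_uv, stim) {
    v <- erg_trace_template(time_ms, flash_onset_ms, amp) + dc_offset_uv
    if (sd_uv > 0) v <- v + stats::rnorm(length(v), 0, sd_uv)
    list(time_ms = time_ms, voltage_uv = v, flash_onset_ms = flash_onset_ms,
         stimulus = stim)
  }

  traces <- lapply(seq_along(intensity_grid), function(i) {
    f <- intensity_grid[i]
    amp <- max_bwave_uv * boltzmann_value(f, flash0, tau)
    stim <- list(animal_id = animal_id, wavelength_nm = wavelength_nm,
                 log_intensity = f, duration_ms = 5, no_light = FALSE)
    lapply(seq_len(n_flashes), function(j) {
      sd_j <- if (i %in% artifact_steps && j == 1L) 10 * noise_sd_uv
              else noise_sd_uv
      mk_trace(amp, sd_j, stim)
    })
  })
  no_light <- lapply(1:4, function(j) {
    v <- rep(dc_offset_uv, length(time_ms))
    if (noise_sd_uv > 0) v <- v + stats::rnorm(length(v), 0, noise_sd_uv)
    list(time_ms = time_ms, voltage_uv = v, flash_onset_ms = flash_onset_ms,
         stimulus = list(animal_id = animal_id, no_light = TRUE))
  })
  list(traces = traces, no_light = no_light,
       truth = list(animal_id = animal_id, wavelength_nm = wavelength_nm,
                    flash0 = flash0, tau = tau, max_bwave_uv = max_bwave_uv,
                    intensity_grid = intensity_grid,
                    noise_sd_uv = noise_sd_uv, dc_offset_uv = dc_offset_uv,
                    n_flashes = n_flashes, artifact_steps = artifact_steps,
                    seed = seed))
}

#' Default wavelength-dependent sensitivity used by the cohort generator
#'
#' Half-max log intensities per stimulus wavelength shaping a tuning
#' curve most sensitive in the 550-600 nm band, as seen in diurnal
#' frogs.
#' @return Named numeric vector of `flash0` values by wavelength.
#' @export
default_flash0_map <- function() {
  c(`350` = -1.8, `400` = -2.0, `450` = -2.3, `500` = -2.6,
    `550` = -2.8, `600` = -2.7, `650` = -2.0)
}

erg_wavelengths <- c(350, 400, 450, 500, 550, 600, 650)

#' Generate a synthetic study cohort with ground truth
#'
#' Builds the per-animal, per-wavelength ground-truth table for a
#' multi-group ERG study: each animal draws a random sensitivity offset
#' around the group baseline tuning, and a per-group per-wavelength
#' effect map shifts the true half-max intensities (and hence the true
#' thresholds) additively.
#'
#' @param groups data frame with columns `group`, `n_female`, `n_male`.
#' @param wavelengths_nm stimulus wavelengths, a subset of
#'   350/400/450/500/550/600/650 nm.
#' @param effect_map optional data frame `group`, `wavelength_nm`,
#'   `shift` added to `flash0_true` in matching cells.
#' @param flash0_map named baseline `flash0` per wavelength.
#' @param tau_true slope parameter shared by all cells.
#' @param animal_sd between-animal SD of a per-animal sensitivity
#'   offset applied at all wavelengths (0 for exact group means).
#' @param seed integer seed.
#' @return A data frame of class `"erg_cohort_truth"`: one row per
#'   animal x wavelength with `animal_id`, `group`, `sex`,
#'   `wavelength_nm`, `flash0_true`, `tau_true`,
#'   `threshold_true` (= flash0_true - tau_true * ln 9).
#' @export
generate_cohort <- function(groups,
                            wavelengths_nm = c(400, 450, 500, 550, 600, 650),
                            effect_map = NULL,
                            flash0_map = default_flash0_map(),
                            tau_true = 0.45, animal_sd = 0.1, seed = NULL) {
  if (!all(c("group", "n_female", "n_male") %in% names(groups)))
    stop("'groups' must have columns group, n_female, n_male", call. = FALSE)
  bad <- setdiff(wavelengths_nm, erg_wavelengths)
  if (length(bad))
    stop("unknown stimulus wavelength: ", bad[1], call. = FALSE)
  if (!is.null(effect_map)) {
    bad <- setdiff(effect_map$wavelength_nm, wavelengths_nm)
    if (length(bad))
      stop("effect map references untested wavelength: ", bad[1],
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups$group[gi]
    sexes <- c(rep("F", groups$n_female[gi]), rep("M", groups$n_male[gi]))
    for (ai in seq_along(sexes)) {
      aid <- sprintf("%s_%02d", g, ai)
      offset <- if (animal_sd > 0) stats::rnorm(1, 0, animal_sd) else 0
      f0 <- unname(flash0_map[as.character(wavelengths_nm)]) + offset
      if (!is.null(effect_map)) {
        m <- effect_map[effect_map$group == g, , drop = FALSE]
        idx <- match(wavelengths_nm, m$wavelength_nm)
        f0 <- f0 + ifelse(is.na(idx), 0, m$shift[idx])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = aid, group = g, sex = sexes[ai],
        wavelength_nm = wavelengths_nm, flash0_true = f0,
        tau_true = tau_true,
        threshold_true = f0 - tau_true * log(9))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("erg_cohort_truth", "data.frame")
  out
}

#' Simulate observed V-log(I) points for a cohort
#'
#' Draws, for every (animal, wavelength) row of a cohort truth table,
#' relative b-wave amplitudes at the given intensity grid: the true
#' Boltzmann value plus additive Gaussian amplitude noise. The table is
#' ready for [erg_thresholds()] (it carries `relative_amplitude`, so no
#' re-normalization is applied).
#'
#' @param truth a [generate_cohort()] table.
#' @param intensity_grid log10 intensities tested at each wavelength.
#' @param noise_sd_rel SD of the additive noise on relative amplitude.
#' @param seed integer seed.
#' @return Data frame `animal_id`, `group`, `sex`, `wavelength_nm`,
#'   `log_intensity`, `relative_amplitude`.
#' @export
simulate_cohort_amplitudes <- function(truth,
                                       intensity_grid = seq(-5, 0, by = 0.5),
                                       noise_sd_rel = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_i <- length(intensity_grid)
  out <- truth[rep(seq_len(nrow(truth)), each = n_i),
               c("animal_id", "group", "sex", "wavelength_nm")]
  out$log_intensity <- rep(intensity_grid, nrow(truth))
  f0 <- rep(truth$flash0_true, each = n_i)
  tv <- rep(truth$tau_true, each = n_i)
  mu <- 1 / (1 + exp(-(out$log_intensity - f0) / tv))
  out$relative_amplitude <- mu +
    if (noise_sd_rel > 0) stats::rnorm(nrow(out), 0, noise_sd_rel) else 0
  rownames(out) <- NULL
  out
}
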