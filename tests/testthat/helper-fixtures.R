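# Shared fixtures, built in code.

gaussian_curve <- function(center = 560, amplitude = 60, sigma = 20,
                           step = 1, range_nm = c(300, 700)) {
  generate_spectrum(baseline_pct = 0,
                    peaks = data.frame(center_nm = center,
                                       amplitude_pct = amplitude,
                                       sigma_nm = sigma),
                    noise_sd_pct = 0,
                    grid = c(range_nm[1], range_nm[2], step))
}

triangle_curve <- function() {
  wl <- seq(300, 700, by = 1)
  rf <- ifelse(wl >= 400 & wl <= 500, (wl - 400) / 100 * 50,
               ifelse(wl > 500 & wl <= 600, (600 - wl) / 100 * 50, 0))
  spectrum_curve(wl, rf)
}

flat_curve <- function(level = 30)
  generate_spectrum(baseline_pct = level, grid = c(300, 700, 1))

# a V-log(I) table ready for fit_boltzmann
vlogi_points <- function(flash0, tau, flash = seq(-5, 0, by = 0.5),
                         noise_sd = 0) {
  y <- boltzmann_value(flash, flash0, tau)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  data.frame(log_intensity = flash, relative_amplitude = y)
}

write_spectrum_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# hand-built trace with known trough/peak for measure_bwave
two_bump_trace <- function(trough_uv = -40, peak_uv = 120,
                           trough_ms = 30, peak_ms = 80) {
  time_ms <- seq(0, 299, by = 1)
  onset <- 50
  v <- trough_uv * exp(-(time_ms - onset - trough_ms)^2 / (2 * 4^2)) +
    peak_uv * exp(-(time_ms - onset - peak_ms)^2 / (2 * 4^2))
  list(time_ms = time_ms, voltage_uv = v, flash_onset_ms = onset)
}

flat_trace <- function(level_uv = 0) {
  time_ms <- seq(0, 299, by = 1)
  list(time_ms = time_ms, voltage_uv = rep(level_uv, length(time_ms)),
       flash_onset_ms = 50)
}
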