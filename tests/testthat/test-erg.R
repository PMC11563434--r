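test_that("DC correction subtracts the averaged no-light level", {
  tr <- flat_trace(5)
  nl <- list(flat_trace(5), flat_trace(5))
  out <- dc_correct(list(tr), nl)
  expect_lt(max(abs(out[[1]]$voltage_uv)), 1e-12)

  # zero-offset data pass through unchanged
  tr0 <- two_bump_trace()
  out0 <- dc_correct(list(tr0), list(flat_trace(0)))
  expect_equal(out0[[1]]$voltage_uv, tr0$voltage_uv)

  expect_error(dc_correct(list(tr), list()), "no-light")
  short <- list(time_ms = 0:9, voltage_uv = rep(0, 10), flash_onset_ms = 5)
  expect_error(dc_correct(list(tr), list(short)), "sampling")
})

test_that("flash averaging applies the 5x pre-stimulus RMS rejection rule", {
  set.seed(21)
  mk <- function(sd) {
    tr <- two_bump_trace()
    tr$voltage_uv <- tr$voltage_uv + rnorm(length(tr$voltage_uv), 0, sd)
    tr
  }
  four <- replicate(4, mk(1), simplify = FALSE)
  av <- average_flashes(four)
  expect_equal(av$n_used, 4)
  expect_equal(av$average$voltage_uv,
               rowMeans(sapply(four, `[[`, "voltage_uv")))

  # four identical traces average to themselves
  same <- replicate(4, two_bump_trace(), simplify = FALSE)
  expect_equal(average_flashes(same)$average$voltage_uv,
               two_bump_trace()$voltage_uv)

  noisy <- c(replicate(3, mk(1), simplify = FALSE), list(mk(10)))
  av2 <- average_flashes(noisy)
  expect_equal(av2$n_used, 3)
  expect_equal(av2$rejected, 4L)

  expect_error(average_flashes(replicate(2, mk(1), simplify = FALSE)),
               "fewer than 3")
  two_bad <- c(replicate(3, mk(1), simplify = FALSE),
               list(mk(40), mk(40)))
  expect_error(average_flashes(two_bad), "manual review")
})

test_that("b-wave amplitude follows the configured convention", {
  tr <- two_bump_trace(trough_uv = -40, peak_uv = 120)
  expect_equal(measure_bwave(tr), 160, tolerance = 1e-6)
  expect_equal(measure_bwave(tr, mode = "baseline_to_peak"), 120,
               tolerance = 1e-6)
  expect_equal(measure_bwave(flat_trace(0)), 0)

  # no candidate peak later than the trough: falls back with a warning
  late_trough <- two_bump_trace(-40, 120, trough_ms = 59, peak_ms = 30)
  expect_warning(measure_bwave(late_trough, peak_window_ms = c(20, 55)),
                 "baseline-to-peak")
})

test_that("normalization scales each unit to a maximum of exactly 1", {
  pts <- data.frame(animal_id = "a", wavelength_nm = 500,
                    log_intensity = c(-3, -2, -1),
                    bwave_uv = c(20, 50, 100))
  out <- normalize_amplitudes(pts)
  expect_equal(out$relative_amplitude, c(0.2, 0.5, 1.0))

  single <- data.frame(animal_id = "a", wavelength_nm = 500,
                       log_intensity = -1, bwave_uv = 37)
  expect_equal(normalize_amplitudes(single)$relative_amplitude, 1)

  zeros <- transform(pts, bwave_uv = 0)
  expect_error(normalize_amplitudes(zeros), "all-zero")

  # idempotence: renormalizing normalized amplitudes changes nothing
  again <- normalize_amplitudes(transform(out, bwave_uv = relative_amplitude))
  expect_equal(again$relative_amplitude, out$relative_amplitude)
})

test_that("per-animal normalization uses the global maximum", {
  pts <- data.frame(animal_id = "a",
                    wavelength_nm = rep(c(500, 650), each = 2),
                    log_intensity = c(-2, -1, -2, -1),
                    bwave_uv = c(50, 100, 10, 20))
  per_wl <- normalize_amplitudes(pts, mode = "per_wavelength")
  per_an <- normalize_amplitudes(pts, mode = "per_animal")
  expect_equal(per_wl$relative_amplitude, c(0.5, 1, 0.5, 1))
  expect_equal(per_an$relative_amplitude, c(0.5, 1, 0.1, 0.2))
})

test_that("tuning curves summarize thresholds with the n = 1 SE rule and absent cells", {
  thr <- data.frame(
    animal_id = c("a", "b", "c", "a"),
    wavelength_nm = c(500, 500, 550, 350),
    threshold_log_intensity = c(-3, -5, -4, -2),
    extrapolated = FALSE,
    group = c("G1", "G1", "G1", "G1"))
  tc <- build_tuning_curve(thr, groups = "group")
  row500 <- tc[tc$wavelength_nm == 500, ]
  expect_equal(row500$mean_threshold, -4)
  expect_equal(row500$se, 1)  # sd 1.414 / sqrt(2)
  expect_true(is.na(tc$se[tc$wavelength_nm == 550]))
  # a group without 350 nm data has no 350 nm cell
  thr2 <- thr[thr$wavelength_nm != 350, ]
  thr2$group <- "G2"
  tc2 <- build_tuning_curve(rbind(thr, thr2), groups = "group")
  expect_false(any(tc2$group == "G2" & tc2$wavelength_nm == 350))
  expect_error(build_tuning_curve(thr[0, ]), "no thresholds")
})

test_that("erg_thresholds chains normalization, fitting and thresholds per cell", {
  gr <- data.frame(group = "A", n_female = 2, n_male = 1)
  tr <- generate_cohort(gr, wavelengths_nm = c(450, 550), tau_true = 0.1,
                        animal_sd = 0.15, seed = 8)
  am <- simulate_cohort_amplitudes(tr, noise_sd_rel = 0, seed = 9)
  res <- erg_thresholds(am)
  expect_equal(nrow(res$fits), 6)
  expect_true(all(res$fits$usable))
  m <- merge(res$thresholds, tr, by = c("animal_id", "wavelength_nm"))
  expect_lt(max(abs(m$threshold_log_intensity - m$threshold_true)), 1e-6)
})
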