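test_that("Boltzmann value has the midpoint, asymptotes and monotonicity of a sigmoid", {
  expect_equal(boltzmann_value(-2, -2, 0.5), 0.5)
  expect_equal(boltzmann_value(1e6, -2, 0.5), 1)
  expect_equal(boltzmann_value(-1e6, -2, 0.5), 0)
  f <- seq(-6, 2, by = 0.01)
  expect_true(all(diff(boltzmann_value(f, -2, 0.5)) > 0))
  expect_error(boltzmann_value(0, -2, 0), "tau")
  expect_error(boltzmann_value(0, -2, -1), "tau")
})

test_that("analytic 10% threshold matches algebra and bisection", {
  # hand inversion: 0.1 at flash0 - tau*ln 9
  expect_equal(threshold_10pct(-2, tau = 0.5)$threshold_log_intensity,
               -2 - 0.5 * log(9))
  expect_equal(boltzmann_value(-2 - 0.5 * log(9), -2, 0.5), 0.1)

  bisect_root <- function(flash0, tau) {
    lo <- flash0 - 50 * tau; hi <- flash0
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (boltzmann_value(mid, flash0, tau) < 0.1) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(42)
  for (i in 1:50) {
    f0 <- runif(1, -6, 0); tv <- runif(1, 1e-3, 2)
    expect_equal(threshold_10pct(f0, tau = tv)$threshold_log_intensity,
                 bisect_root(f0, tv), tolerance = 1e-9)
  }
})

test_that("threshold limits and translation invariance hold", {
  # step-function limit: tau -> 0+ pulls the threshold onto flash0
  expect_equal(threshold_10pct(-2, tau = 1e-12)$threshold_log_intensity, -2,
               tolerance = 1e-9)
  # shifting flash0 by c shifts the threshold by c exactly
  base <- threshold_10pct(-3, tau = 0.7)$threshold_log_intensity
  shifted <- threshold_10pct(-3 + 1.25, tau = 0.7)$threshold_log_intensity
  expect_equal(shifted - base, 1.25)
  # 10% point precedes the 50% point for any positive tau
  expect_lt(threshold_10pct(-2, tau = 0.4)$threshold_log_intensity, -2)
})

test_that("noiseless V-log(I) points are fit to machine-level accuracy", {
  for (pars in list(c(-2, 0.6), c(-4, 0.2), c(-1, 1.2))) {
    d <- vlogi_points(pars[1], pars[2], flash = seq(-6, 1, by = 1))
    fit <- fit_boltzmann(d)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), pars, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("fit is flagged or rejected on degenerate amplitude ranges", {
  f <- seq(-5, 0, by = 1)
  expect_error(fit_boltzmann(f, rep(1, 6)), "dynamic range")
  expect_error(fit_boltzmann(c(-1, 0), c(0.1, 0.9)), "4 finite")
  # shallow range: fit returned but unusable for tuning curves
  y <- boltzmann_value(f, 2, 0.8)  # all amplitudes far below half max
  fit <- fit_boltzmann(f, y)
  expect_false(fit$usable)
  expect_error(threshold_10pct(structure(list(converged = FALSE),
                                         class = "boltzmann_fit")),
               "unconverged")
})

test_that("fitted curves are strictly increasing and usable fits keep threshold < flash0", {
  set.seed(7)
  for (i in 1:25) {
    d <- vlogi_points(runif(1, -4, -1), runif(1, 0.1, 1),
                      noise_sd = 0.05)
    fit <- fit_boltzmann(d)
    if (!fit$usable) next
    # strictly increasing wherever the curve is not saturated to 0/1 in
    # double precision; never decreasing anywhere
    grid <- seq(-8, 2, length.out = 300)
    expect_true(all(diff(predict(fit, grid)) >= 0))
    active <- seq(fit$flash0 - 10 * fit$tau, fit$flash0 + 10 * fit$tau,
                  length.out = 100)
    expect_true(all(diff(predict(fit, active)) > 0))
    expect_lt(threshold_10pct(fit)$threshold_log_intensity, fit$flash0)
  }
})

test_that("noisy parameter recovery stays within the frozen tolerances", {
  set.seed(11)
  f8 <- seq(-4.5, -1, by = 0.5)  # 8 steps, 0.5 log spacing
  errs <- replicate(200, {
    d <- vlogi_points(-2.5, 0.5, flash = f8, noise_sd = 0.05)
    co <- coef(fit_boltzmann(d))
    c(abs(co[["flash0"]] + 2.5), abs(co[["tau"]] - 0.5) / 0.5)
  })
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.20)
})

test_that("boltzmann_fit methods behave as a model object", {
  d <- vlogi_points(-2, 0.5, noise_sd = 0)
  fit <- fit_boltzmann(d)
  expect_named(coef(fit), c("flash0", "tau"))
  expect_equal(fitted(fit) + residuals(fit), d$relative_amplitude)
  expect_equal(predict(fit, data.frame(log_intensity = -2)), 0.5,
               tolerance = 1e-8)
  s <- summary(fit)
  expect_equal(s$threshold_10pct,
               threshold_10pct(fit)$threshold_log_intensity)
  expect_output(print(fit), "flash0")
  sims <- simulate(fit, nsim = 3, seed = 1, noise_sd = 0.05)
  expect_equal(dim(sims), c(nrow(d), 4L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("extrapolation below the tested range is flagged", {
  d <- vlogi_points(-4.8, 0.6, flash = seq(-5, 0, by = 0.5))
  fit <- fit_boltzmann(d)
  th <- threshold_10pct(fit)
  expect_true(th$extrapolated)  # -4.8 - 0.6 ln 9 < -5
  th2 <- threshold_10pct(-2, tau = 0.3, tested_range = c(-5, 0))
  expect_false(th2$extrapolated)
})
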