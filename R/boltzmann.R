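#' Boltzmann sigmoid for relative b-wave amplitude
#'
#' Evaluates the two-asymptote Boltzmann function used to describe ERG
#' V-log(I) curves,
#' \deqn{V(f) = \frac{A_1 - A_2}{1 + e^{(f - f_0)/\tau}} + A_2,}
#' with the starting amplitude \eqn{A_1 = 0} and the ending amplitude
#' \eqn{A_2 = 1} fixed, so that the value is the relative b-wave amplitude
#' in (0, 1). `flash0` is the log light intensity yielding 50% of the
#' maximum response and `tau` (> 0) is the slope parameter.
#'
#' @param flash numeric vector of log10 light intensities.
#' @param flash0 log intensity at half-maximal response.
#' @param tau slope parameter; must be strictly positive.
#' @return Numeric vector of relative amplitudes in (0, 1), strictly
#'   increasing in `flash`, equal to 0.5 at `flash = flash0`.
#' @seealso [fit_boltzmann()], [threshold_10pct()]
#' @examples
#' boltzmann_value(-2, flash0 = -2, tau = 0.5)  # 0.5 at the midpoint
#' @export
boltzmann_value <- function(flash, flash0, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
    stop("'tau' must be a single positive number", call. = FALSE)
  if (!is.numeric(flash0) || length(flash0) != 1L || is.na(flash0))
    stop("'flash0' must be a single finite number", call. = FALSE)
  (0 - 1) / (1 + exp((flash - flash0) / tau)) + 1
}

#' Fit the Boltzmann V-log(I) model to relative b-wave amplitudes
#'
#' Least-squares fit of [boltzmann_value()] to (log intensity, relative
#' amplitude) points for one animal at one stimulus wavelength. The
#' asymptotes are fixed (\eqn{A_1 = 0}, \eqn{A_2 = 1}); only `flash0`
#' (half-maximal log intensity) and `tau` (slope, constrained positive)
#' are estimated, by Levenberg-Marquardt least squares.
#'
#' Initialization: `flash0` starts at the flash of the point whose
#' amplitude is nearest 0.5, and `tau` at one quarter of the tested flash
#' range. A fit whose input amplitudes span less than 0.3 of relative
#' amplitude is returned with `usable = FALSE` and is excluded from
#' tuning curves by downstream helpers; zero dynamic range is an error.
#'
#' @param flash numeric vector of log10 light intensities, or a data frame
#'   with columns `log_intensity` and `relative_amplitude`.
#' @param relative_amplitude numeric vector of normalized b-wave
#'   amplitudes (ignored when `flash` is a data frame).
#' @param min_dynamic_range minimum spread of amplitudes for a usable fit.
#' @param ptol convergence tolerance on the parameters.
#' @return An object of class `"boltzmann_fit"`: a list with elements
#'   `flash0`, `tau`, `a1`, `a2`, `rss`, `n_points`, `converged`,
#'   `usable`, `dynamic_range`, `data`, `fitted.values`, `residuals`.
#' @examples
#' f <- seq(-5, 0, by = 0.5)
#' fit <- fit_boltzmann(f, boltzmann_value(f, -2, 0.6))
#' coef(fit)
#' threshold_10pct(fit)
#' @export
fit_boltzmann <- function(flash, relative_amplitude = NULL,
                          min_dynamic_range = 0.3, ptol = 1e-10) {
  if (is.data.frame(flash)) {
    relative_amplitude <- flash$relative_amplitude
    flash <- flash$log_intensity
  }
  if (length(flash) != length(relative_amplitude))
    stop("'flash' and 'relative_amplitude' must have equal length", call. = FALSE)
  ok <- is.finite(flash) & is.finite(relative_amplitude)
  flash <- flash[ok]; y <- relative_amplitude[ok]
  if (length(flash) < 4L)
    stop("at least 4 finite V-log(I) points are required to fit", call. = FALSE)
  dr <- diff(range(y))
  if (dr == 0)
    stop("amplitudes have no dynamic range; nothing to fit", call. = FALSE)

  start <- c(flash0 = flash[which.min(abs(y - 0.5))],
             tau = diff(range(flash)) / 4)
  if (start[["tau"]] <= 0) start[["tau"]] <- 0.25
  # second start from a logit linearization: logit(y) = (f - flash0)/tau
  starts <- list(start)
  mid <- y > 0.001 & y < 0.999
  if (sum(mid) >= 2L && stats::var(flash[mid]) > 0) {
    lg <- stats::coef(stats::lm(stats::qlogis(pmin(pmax(y[mid], 0.001), 0.999))
                                ~ flash[mid]))
    if (is.finite(lg[2]) && lg[2] > 0)
      starts <- c(starts, list(c(flash0 = unname(-lg[1] / lg[2]),
                                 tau = unname(1 / lg[2]))))
  }

  resid_fn <- function(p) y - boltzmann_value(flash, p[[1]], p[[2]])
  jac_fn <- function(p) {
    s <- (flash - p[[1]]) / p[[2]]
    b <- 1 / (1 + exp(-s))
    d <- b * (1 - b) / p[[2]]
    cbind(flash0 = d, tau = s * d)  # -dB/dpar
  }
  runs <- lapply(starts, function(s) tryCatch(
    minpack.lm::nls.lm(
      par = s, fn = resid_fn, jac = jac_fn,
      lower = c(flash0 = -Inf, tau = 1e-8),
      control = minpack.lm::nls.lm.control(
        ptol = ptol, ftol = 1e-15, gtol = 0, maxiter = 1000)),
    error = function(e) e))
  runs <- Filter(function(r) !inherits(r, "error"), runs)

  if (!length(runs)) {
    est <- start
    converged <- FALSE
  } else {
    rss_all <- vapply(runs, function(r) sum(r$fvec^2), numeric(1))
    best <- runs[[which.min(rss_all)]]
    est <- best$par
    converged <- best$info %in% 1:4
  }
  fitted_vals <- boltzmann_value(flash, est[["flash0"]], est[["tau"]])
  res <- y - fitted_vals

  structure(list(
    flash0 = unname(est[["flash0"]]),
    tau = unname(est[["tau"]]),
    a1 = 0, a2 = 1,
    rss = sum(res^2),
    n_points = length(flash),
    converged = converged,
    usable = converged && dr >= min_dynamic_range,
    dynamic_range = dr,
    data = data.frame(log_intensity = flash, relative_amplitude = y),
    fitted.values = fitted_vals,
    residuals = res),
    class = "boltzmann_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.boltzmann_fit <- function(x, digits = 4, ...) {
  cat("Boltzmann V-log(I) fit (A1 = 0, A2 = 1)\n")
  cat(sprintf("  flash0 (half-max log I): %.*g\n", digits, x$flash0))
  cat(sprintf("  tau (slope):             %.*g\n", digits, x$tau))
  cat(sprintf("  RSS %.3g on %d points; converged: %s; usable: %s\n",
              x$rss, x$n_points, x$converged, x$usable))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(flash0 = object$flash0, tau = object$tau)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    rss = object$rss,
    sigma = sqrt(object$rss / max(object$n_points - 2L, 1L)),
    n_points = object$n_points,
    converged = object$converged,
    usable = object$usable,
    threshold_10pct = object$flash0 - object$tau * log(9))
  class(out) <- "summary.boltzmann_fit"
  out
}

#' @export
print.summary.boltzmann_fit <- function(x, ...) {
  cat("Boltzmann V-log(I) fit\n")
  print(x$coefficients)
  cat(sprintf("residual sigma %.4g on %d points (RSS %.4g)\n",
              x$sigma, x$n_points, x$rss))
  cat(sprintf("10%% threshold: %.4f log units\n", x$threshold_10pct))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  flash <- if (is.null(newdata)) object$data$log_intensity
           else if (is.data.frame(newdata)) newdata$log_intensity
           else newdata
  boltzmann_value(flash, object$flash0, object$tau)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) object$residuals

#' @export
fitted.boltzmann_fit <- function(object, ...) object$fitted.values

#' @export
simulate.boltzmann_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$rss / max(object$n_points - 2L, 1L))
  mu <- object$fitted.values
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, noise_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(object$data["log_intensity"], out)
}

#' @export
plot.boltzmann_fit <- function(x, ...,
                               xlab = expression(Log~intensity~(log[10]~mu*mol/m^2/s)),
                               ylab = "Relative b-wave amplitude") {
  d <- x$data
  graphics::plot(d$log_intensity, d$relative_amplitude,
                 xlab = xlab, ylab = ylab, ylim = c(0, max(1, d$relative_amplitude)), ...)
  fg <- seq(min(d$log_intensity), max(d$log_intensity), length.out = 200)
  graphics::lines(fg, boltzmann_value(fg, x$flash0, x$tau))
  thr <- x$flash0 - x$tau * log(9)
  graphics::abline(v = thr, lty = 3)
  graphics::abline(h = 0.1, lty = 3)
  invisible(x)
}

#' 10%-of-maximum threshold from a Boltzmann fit
#'
#' The spectral threshold is the log light intensity at which the fitted
#' relative b-wave amplitude equals 0.1 of the maximum response.
#' Inverting the fixed-asymptote Boltzmann at 0.1 gives the closed form
#' \deqn{f_{thr} = f_0 - \tau \ln 9,} which always precedes the half-max
#' intensity `flash0`.
#'
#' @param fit a converged [fit_boltzmann()] object, or a numeric `flash0`
#'   (in which case `tau` must be given).
#' @param tau slope parameter when `fit` is numeric.
#' @param tested_range optional range of log intensities actually
#'   delivered; a threshold below its minimum is flagged `extrapolated`.
#' @return A one-row data frame with `threshold_log_intensity` and
#'   `extrapolated`.
#' @export
threshold_10pct <- function(fit, tau = NULL, tested_range = NULL) {
  if (inherits(fit, "boltzmann_fit")) {
    if (!fit$converged)
      stop("threshold is undefined for an unconverged fit", call. = FALSE)
    flash0 <- fit$flash0; tau <- fit$tau
    if (is.null(tested_range)) tested_range <- range(fit$data$log_intensity)
  } else {
    if (is.null(tau)) stop("'tau' is required when 'fit' is numeric", call. = FALSE)
    flash0 <- fit
  }
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  thr <- flash0 - tau * log(9)
  data.frame(
    threshold_log_intensity = thr,
    extrapolated = if (is.null(tested_range)) NA else thr < min(tested_range))
}
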