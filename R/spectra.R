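#' Construct a reflectance spectrum curve
#'
#' A `spectrum_curve` is a wavelength-indexed series of percent
#' reflectance relative to a diffuse white standard, with specimen
#' metadata (specimen id, species, morph, sex, body region, optional
#' subregion/marking label).
#'
#' @param wavelength_nm strictly increasing numeric vector.
#' @param reflectance_pct non-negative numeric vector, same length.
#' @param meta named list of metadata fields.
#' @return An object of class `"spectrum_curve"`.
#' @export
spectrum_curve <- function(wavelength_nm, reflectance_pct, meta = list()) {
  if (length(wavelength_nm) != length(reflectance_pct))
    stop("wavelength and reflectance must have equal length", call. = FALSE)
  if (length(wavelength_nm) < 3L)
    stop("a spectrum needs at least 3 points", call. = FALSE)
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(reflectance_pct)))
    stop("non-finite values in spectrum", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  neg <- which(reflectance_pct < 0)
  if (length(neg))
    stop(sprintf("negative reflectance at row %d (%.6g%%)",
                 neg[1], reflectance_pct[neg[1]]), call. = FALSE)
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 reflectance_pct = as.numeric(reflectance_pct),
                 meta = meta),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("spectrum_curve: %d points, %g-%g nm",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm)))
  if (length(x$meta)) {
    lab <- x$meta[intersect(c("specimen_id", "species", "morph", "region",
                              "subregion"), names(x$meta))]
    if (length(lab)) cat(" [", paste(unlist(lab), collapse = "/"), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.spectrum_curve <- function(x, ..., xlab = "Wavelength (nm)",
                                ylab = "Reflectance (%)", type = "l") {
  graphics::plot(x$wavelength_nm, x$reflectance_pct,
                 xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Read a two-column reflectance spectrum file
#'
#' Reads a CSV or TSV file with one header line and columns wavelength
#' (nm) and percent reflectance, in that order (column names are free).
#' Rows are sorted by wavelength and duplicate wavelengths are collapsed
#' by averaging their reflectances. Non-numeric rows, fewer than 3
#' points, or negative reflectance values are rejected with a row-level
#' message.
#'
#' @param path file path.
#' @param meta named list of specimen metadata attached to the curve.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return A [spectrum_curve()].
#' @export
read_spectrum <- function(path, meta = list(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           comment.char = "#")
  if (ncol(raw) < 2L)
    stop("expected two columns (wavelength, reflectance) in ", path, call. = FALSE)
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  rf <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(wl) | is.na(rf))
  if (length(bad))
    stop(sprintf("non-numeric value at data row %d of %s", bad[1], path),
         call. = FALSE)
  neg <- which(rf < 0)
  if (length(neg))
    stop(sprintf("negative reflectance at data row %d of %s (%.6g)",
                 neg[1], path, rf[neg[1]]), call. = FALSE)
  o <- order(wl)
  wl <- wl[o]; rf <- rf[o]
  if (anyDuplicated(wl)) {
    rf <- as.numeric(tapply(rf, wl, mean))
    wl <- sort(unique(wl))
  }
  spectrum_curve(wl, rf, meta = meta)
}

#' Summary metrics of a reflectance curve
#'
#' Computes the four curve metrics used throughout the package:
#' \describe{
#'   \item{peak_nm}{wavelength of maximum reflectance; ties are broken
#'     toward the lowest wavelength and flagged `peak_tied`.}
#'   \item{fwhm_nm}{full width at half maximum: the distance between the
#'     wavelengths on either side of the peak where half of the maximum
#'     reflectance occurs, located by linear interpolation of the
#'     half-max crossings nearest the peak. When a side never drops
#'     below half max the width is clipped to the grid boundary and
#'     `fwhm_clipped_low`/`fwhm_clipped_high` is set.}
#'   \item{auc_pct_nm}{trapezoidal integral of the curve above the
#'     baseline (0% reflectance by default).}
#'   \item{avg_pct}{arithmetic mean of all reflectance samples.}
#' }
#' An all-zero curve has an undefined peak and FWHM (`peak_undefined`
#' flag) and AUC 0.
#'
#' @param curve a [spectrum_curve()].
#' @param auc_baseline `"zero"` (default) integrates above 0%
#'   reflectance; `"min"` subtracts the curve minimum first.
#' @return An object of class `"spectrum_metrics"`: a list with
#'   `peak_nm`, `fwhm_nm`, `auc_pct_nm`, `avg_pct` and a `flags` list.
#' @export
compute_metrics <- function(curve, auc_baseline = c("zero", "min")) {
  stopifnot(inherits(curve, "spectrum_curve"))
  auc_baseline <- match.arg(auc_baseline)
  wl <- curve$wavelength_nm
  rf <- curve$reflectance_pct
  flags <- list(peak_tied = FALSE, peak_undefined = FALSE,
                fwhm_clipped_low = FALSE, fwhm_clipped_high = FALSE)

  avg <- mean(rf)
  base <- if (auc_baseline == "min") min(rf) else 0
  auc <- trapz(wl, rf - base)

  if (all(rf == 0)) {
    flags$peak_undefined <- TRUE
    return(structure(list(peak_nm = NA_real_, fwhm_nm = NA_real_,
                          auc_pct_nm = 0, avg_pct = 0, flags = flags),
                     class = "spectrum_metrics"))
  }

  mx <- max(rf)
  at_max <- which(rf == mx)
  if (length(at_max) > 1L) flags$peak_tied <- TRUE
  ipk <- at_max[1]
  peak <- wl[ipk]

  half <- mx / 2
  # left crossing: walk from the peak toward shorter wavelengths
  left <- wl[1]
  found_left <- FALSE
  if (ipk > 1L) {
    for (i in seq(ipk, 2L)) {
      if (rf[i - 1] < half) {
        left <- wl[i - 1] + (half - rf[i - 1]) / (rf[i] - rf[i - 1]) *
          (wl[i] - wl[i - 1])
        found_left <- TRUE
        break
      }
    }
  }
  if (!found_left) flags$fwhm_clipped_low <- TRUE
  right <- wl[length(wl)]
  found_right <- FALSE
  if (ipk < length(wl)) {
    for (i in seq(ipk, length(wl) - 1L)) {
      if (rf[i + 1] < half) {
        right <- wl[i] + (rf[i] - half) / (rf[i] - rf[i + 1]) *
          (wl[i + 1] - wl[i])
        found_right <- TRUE
        break
      }
    }
  }
  if (!found_right) flags$fwhm_clipped_high <- TRUE

  structure(list(peak_nm = peak, fwhm_nm = right - left,
                 auc_pct_nm = auc, avg_pct = avg, flags = flags),
            class = "spectrum_metrics")
}

#' @export
print.spectrum_metrics <- function(x, ...) {
  cat(sprintf("peak %g nm | FWHM %.2f nm | AUC %.1f %%*nm | mean %.2f %%\n",
              x$peak_nm, x$fwhm_nm, x$auc_pct_nm, x$avg_pct))
  on <- names(Filter(isTRUE, x$flags))
  if (length(on)) cat("flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum_metrics <- function(x, ...) {
  data.frame(peak_nm = x$peak_nm, fwhm_nm = x$fwhm_nm,
             auc_pct_nm = x$auc_pct_nm, avg_pct = x$avg_pct,
             peak_tied = x$flags$peak_tied,
             fwhm_clipped_low = x$flags$fwhm_clipped_low,
             fwhm_clipped_high = x$flags$fwhm_clipped_high)
}

# trapezoidal integral on an irregular grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Group mean and standard-error reflectance curves
#'
#' Averages curves per group per wavelength, reporting the mean and the
#' standard error (sd/sqrt(n); `NA` when a group has a single curve).
#' Curves on different grids are linearly re-interpolated onto the first
#' curve's grid restricted to the range common to all curves.
#'
#' @param curves list of [spectrum_curve()] objects.
#' @param group_key metadata field name(s) used as the grouping label;
#'   alternatively a vector of labels, one per curve.
#' @return A data frame with columns `group`, `wavelength_nm`,
#'   `mean_pct`, `se_pct`, `n`.
#' @export
summarize_group <- function(curves, group_key = "species") {
  if (!length(curves)) stop("no curves supplied", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, TRUE, "spectrum_curve")))
  meta_names <- Reduce(intersect, lapply(curves, function(cv) names(cv$meta)))
  labels <- if (all(group_key %in% meta_names)) {
    vapply(curves, function(cv)
      paste(unlist(cv$meta[group_key]), collapse = "/"), character(1))
  } else if (length(group_key) == length(curves)) {
    as.character(group_key)
  } else {
    stop("'group_key' must name metadata fields or give one label per curve",
         call. = FALSE)
  }

  lo <- max(vapply(curves, function(cv) min(cv$wavelength_nm), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$wavelength_nm), numeric(1)))
  if (lo >= hi) stop("curves have no common wavelength range", call. = FALSE)
  grid <- curves[[1]]$wavelength_nm
  grid <- grid[grid >= lo & grid <= hi]

  mat <- vapply(curves, function(cv)
    stats::approx(cv$wavelength_nm, cv$reflectance_pct, xout = grid)$y,
    numeric(length(grid)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(grid))

  out <- do.call(rbind, lapply(unique(labels), function(g) {
    sub <- mat[, labels == g, drop = FALSE]
    n <- ncol(sub)
    data.frame(group = g, wavelength_nm = grid,
               mean_pct = rowMeans(sub),
               se_pct = if (n > 1) apply(sub, 1, stats::sd) / sqrt(n) else NA_real_,
               n = n)
  }))
  rownames(out) <- NULL
  out
}
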