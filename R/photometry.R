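#' Total reflectance of a marking from its RGB color code
#'
#' The total reflectance of a color-calibrated marking is the sum of its
#' red, green and blue channel values (arbitrary units, 0-765). Channels
#' must lie in [0, 255]; values are assumed already color-calibrated
#' against a color-checker profile.
#'
#' @param rgb numeric vector of length 3, or a 3-column matrix/data frame
#'   (one row per marking).
#' @return Numeric total reflectance, one value per marking.
#' @export
marking_total_reflectance <- function(rgb) {
  m <- if (is.null(dim(rgb))) matrix(as.numeric(rgb), nrow = 1L)
       else as.matrix(rgb)
  if (ncol(m) != 3L) stop("'rgb' must have 3 channels", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255))
    stop("RGB channels must be finite and within [0, 255]", call. = FALSE)
  unname(rowSums(m))
}

#' Area-scaled total reflectance scores per surface and per frog
#'
#' Scores each photographed surface (dorsal, lateral) by summing, over
#' its distinct color markings, the marking's total reflectance (R+G+B)
#' weighted by the fraction of the surface it occupies
#' (area_mm2 / total surface area_mm2). The per-frog score is the sum of
#' its dorsal and lateral surface scores. Unmarked area contributes 0
#' unless listed explicitly as a background marking.
#'
#' @param markings data frame with columns `frog_id`, `surface`,
#'   `marking_label`, `r`, `g`, `b`, `area_mm2`.
#' @param surfaces data frame with columns `frog_id`, `surface`,
#'   `total_area_mm2`.
#' @param area_tolerance allowed fractional excess of summed marking
#'   areas over the surface total before rejection (default 1%).
#' @return A list of class `"surface_scores"` with data frames
#'   `surfaces` (`frog_id`, `surface`, `scaled_reflectance_au`) and
#'   `frogs` (`frog_id`, `scaled_reflectance_au`).
#' @examples
#' mk <- data.frame(frog_id = "f1", surface = "dorsal",
#'                  marking_label = c("A", "B"),
#'                  r = c(200, 10), g = c(100, 10), b = c(0, 10),
#'                  area_mm2 = c(30, 30))
#' sf <- data.frame(frog_id = "f1", surface = "dorsal", total_area_mm2 = 60)
#' scaled_reflectance(mk, sf)$surfaces$scaled_reflectance_au  # 165
#' @export
scaled_reflectance <- function(markings, surfaces, area_tolerance = 0.01) {
  need_m <- c("frog_id", "surface", "marking_label", "r", "g", "b", "area_mm2")
  need_s <- c("frog_id", "surface", "total_area_mm2")
  if (!all(need_m %in% names(markings)))
    stop("markings table must have columns: ", paste(need_m, collapse = ", "),
         call. = FALSE)
  if (!all(need_s %in% names(surfaces)))
    stop("surfaces table must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  if (any(surfaces$total_area_mm2 <= 0))
    stop("total surface areas must be positive", call. = FALSE)
  if (nrow(markings) && any(markings$area_mm2 < 0))
    stop("marking areas must be non-negative", call. = FALSE)
  if (nrow(markings))
    marking_total_reflectance(markings[, c("r", "g", "b")])  # range check

  skey <- paste(surfaces$frog_id, surfaces$surface, sep = "\r")
  if (anyDuplicated(skey))
    stop("duplicated (frog, surface) rows in surfaces table", call. = FALSE)
  if (nrow(markings)) {
    mkey <- paste(markings$frog_id, markings$surface, sep = "\r")
    missing <- setdiff(unique(mkey), skey)
    if (length(missing))
      stop("markings reference surfaces with no surface record: ",
           gsub("\r", "/", missing[1]), call. = FALSE)
    tot_marked <- tapply(markings$area_mm2, mkey, sum)
    lim <- surfaces$total_area_mm2[match(names(tot_marked), skey)]
    over <- tot_marked > lim * (1 + area_tolerance)
    if (any(over))
      stop("marking areas exceed the surface total by more than ",
           area_tolerance * 100, "% for ",
           gsub("\r", "/", names(tot_marked)[over][1]), call. = FALSE)
  }

  per_surface <- surfaces[, c("frog_id", "surface")]
  per_surface$scaled_reflectance_au <- vapply(seq_len(nrow(surfaces)), function(i) {
    if (!nrow(markings)) return(0)
    sel <- markings$frog_id == surfaces$frog_id[i] &
      markings$surface == surfaces$surface[i]
    if (!any(sel)) return(0)
    sub <- markings[sel, , drop = FALSE]
    sum(marking_total_reflectance(sub[, c("r", "g", "b")]) *
          sub$area_mm2 / surfaces$total_area_mm2[i])
  }, numeric(1))

  frogs <- stats::aggregate(scaled_reflectance_au ~ frog_id,
                            data = per_surface, FUN = sum)
  structure(list(surfaces = per_surface, frogs = frogs),
            class = "surface_scores")
}

#' @export
print.surface_scores <- function(x, ...) {
  cat("Area-scaled reflectance scores (a.u.)\n")
  print(x$surfaces, row.names = FALSE)
  invisible(x)
}

#' Mean RGB of a masked image region
#'
#' Per-channel arithmetic mean over the pixels selected by a boolean
#' mask, unrounded. Stands in for manual color sampling of a marking in
#' a calibrated photograph.
#'
#' @param pixels numeric array `height x width x 3` of channel values in
#'   [0, 255].
#' @param mask logical matrix `height x width`; must select at least one
#'   pixel.
#' @return Named numeric vector `c(r, g, b)`.
#' @export
region_mean_rgb <- function(pixels, mask) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("'pixels' must be a height x width x 3 array", call. = FALSE)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("'mask' must be a logical matrix matching the image size", call. = FALSE)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  c(r = mean(pixels[, , 1][mask]),
    g = mean(pixels[, , 2][mask]),
    b = mean(pixels[, , 3][mask]))
}
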