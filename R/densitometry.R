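# Gray-level densitometry.
#
# Gray levels are calibrated against imaging standards of known material
# density (steel/aluminum/polyester for X-ray microradiography,
# halogenated dimethacrylates for quantitative BSE-SEM): the median gray
# level of each standard region is paired with the standard's density and
# an affine gray -> density map is fit through the anchors by least
# squares.  Calibrated pixel values are summarized as relative-frequency
# histograms (16 equal intervals for microradiographic BMC, 8 for qBSE
# micromineralization density) whose cumulative distributions feed the
# percent-scaled Kolmogorov-Smirnov comparison.

#' Calibrate a gray-level image against its standard regions
#'
#' @param field a `gray_field` (see [gen_gray_field()]) or a list with
#'   `pixels` (numeric matrix) and `standard_regions` (data.frame
#'   `name, density, row0, row1, col0, col1`, 0-based half-open pixel
#'   coordinates).
#' @param min_region_px minimum pixels per standard region (default 25).
#' @return object of class `calibration_map`: `gain` and `offset` of the
#'   gray -> density map (`density = offset + gain * gray`), `anchors`
#'   (data.frame `name, density, median_gray`), and `residual` (RMS of
#'   anchor residuals; 0 for two anchors).
#' @export
calibrate_gray <- function(field, min_region_px = 25) {
  px <- field$pixels
  regs <- field$standard_regions
  check_field(is.matrix(px), "pixels", "must be a matrix")
  check_field(is.data.frame(regs) && nrow(regs) >= 2, "standard_regions",
              "calibration needs at least two standard regions")
  med <- vapply(seq_len(nrow(regs)), function(i) {
    r <- regs[i, ]
    if (r$row0 < 0 || r$col0 < 0 ||
        r$row1 > nrow(px) || r$col1 > ncol(px) ||
        r$row1 <= r$row0 || r$col1 <= r$col0) {
      stop(sprintf("standard region `%s` lies outside the raster", r$name),
           call. = FALSE)
    }
    block <- px[(r$row0 + 1L):r$row1, (r$col0 + 1L):r$col1]
    if (length(block) < min_region_px) {
      stop(sprintf("standard region `%s` has %d pixels (< %d required)",
                   r$name, length(block), min_region_px), call. = FALSE)
    }
    median(block)
  }, numeric(1))
  anchors <- data.frame(name = regs$name, density = regs$density,
                        median_gray = med)
  o <- order(anchors$density)
  if (any(diff(anchors$median_gray[o]) <= 0)) {
    stop("anchors are not strictly monotone: standard median gray levels ",
         "must increase with standard density", call. = FALSE)
  }
  fit <- lm.fit(cbind(1, anchors$median_gray), anchors$density)
  gain <- unname(fit$coefficients[2])
  offset <- unname(fit$coefficients[1])
  check_field(gain > 0, "calibration", "fitted map must be monotone")
  structure(
    list(gain = gain, offset = offset, anchors = anchors,
         residual = sqrt(mean(fit$residuals^2))),
    class = "calibration_map"
  )
}

#' Apply a calibration map to gray levels
#'
#' @param map a [calibration_map][calibrate_gray].
#' @param gray numeric vector/matrix of gray levels.
#' @return calibrated densities, same shape as `gray`.
#' @export
apply_calibration <- function(map, gray) {
  stopifnot(inherits(map, "calibration_map"))
  map$offset + map$gain * gray
}

# internal: shared histogram machinery
.density_histogram <- function(values, n_bins, range, clip = FALSE) {
  check_field(length(values) > 0, "mask", "no pixels selected")
  check_field(range[2] > range[1], "range", "histogram range is degenerate")
  n_clipped <- 0L
  if (clip) {
    n_clipped <- sum(values < range[1] | values > range[2])
    values_b <- pmin(pmax(values, range[1]), range[2])
  } else {
    values_b <- values
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(values_b, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  freq <- tabulate(idx, nbins = n_bins) / length(values)
  structure(
    list(bin_edges = edges, freq = freq, n_pixels = length(values),
         median = median(values), n_clipped = n_clipped),
    class = "density_histogram"
  )
}

#' Relative BMC summary by calibrated microradiography
#'
#' Calibrates the masked pixels and bins them into 16 equal intervals over
#' a fixed, caller-supplied range so that histograms from different
#' specimens are directly comparable; the specimen's relative BMC is the
#' median calibrated value.
#'
#' @param field a `gray_field`-like list (`pixels` matrix).
#' @param mask logical matrix selecting bone pixels (defaults to the
#'   field's own `bone_mask`).
#' @param map a [calibration_map][calibrate_gray].
#' @param n_bins number of equal intervals (default 16).
#' @param range density range for the fixed binning; defaults to the span
#'   of the calibration anchors.
#' @return a `density_histogram` (bin edges, relative frequencies summing
#'   to 1, `n_pixels`, `median`).
#' @export
bmc_summary <- function(field, mask = field$bone_mask, map,
                        n_bins = 16, range = NULL) {
  check_field(!is.null(mask) && any(mask), "mask", "mask is empty")
  vals <- apply_calibration(map, field$pixels[mask])
  if (is.null(range)) range <- base::range(map$anchors$density)
  .density_histogram(vals, n_bins, range, clip = FALSE)
}

#' Micromineralization density histogram by quantitative BSE-SEM
#'
#' As [bmc_summary()] but with 8 equal intervals spanning the two
#' bracketing standard densities; out-of-range pixels are clipped into the
#' end bins and the clip count is reported.
#'
#' @inheritParams bmc_summary
#' @param n_bins number of equal intervals (default 8).
#' @return a `density_histogram` with `n_clipped` set.
#' @export
qbse_histogram <- function(field, mask = field$bone_mask, map,
                           n_bins = 8, range = NULL) {
  check_field(!is.null(mask) && any(mask), "mask", "mask is empty")
  vals <- apply_calibration(map, field$pixels[mask])
  if (is.null(range)) range <- base::range(map$anchors$density)
  .density_histogram(vals, n_bins, range, clip = TRUE)
}
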