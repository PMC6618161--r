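# Synthetic calibrated gray-level fields.
#
# Emulates the raw material of gray-level densitometry: a raster
# containing rectangular calibration-standard regions of known material
# density and a bone region whose pixels are drawn from a configurable
# mineralization-density distribution.  Density maps to gray level through
# an affine detector model gray = gain * density + offset (nonlinearity is
# deliberately excluded: no detector model is available), with optional
# Gaussian gray-level noise, then clipping to the bit depth.

#' Generate a synthetic gray-level field with calibration standards
#'
#' The raster is laid out as one row of standard rectangles across the top
#' and a bone rectangle beneath; everything else is background (gray 0).
#' Regions use 0-based, half-open pixel coordinates
#' `(row0, row1, col0, col1)`, row-major.
#'
#' @param bone_density_mean mean bone mineralization density
#'   (mg/cm^3-equivalent units).
#' @param bone_density_sd SD of the bone density distribution.
#' @param standards data.frame with columns `name` and `density`
#'   (>= 2 rows, distinct densities).  The defaults emulate halogenated
#'   dimethacrylate standards bracketing bone mineralization density, as
#'   used for quantitative BSE-SEM; pass e.g. polyester/aluminum/steel
#'   densities to emulate a microradiography standard set.
#' @param size raster size `c(nrow, ncol)` in pixels.
#' @param gain,offset affine density-to-gray map.
#' @param noise_sd_gray SD of additive Gaussian gray-level noise.
#' @param bit_depth 8 or 16.
#' @param standard_px minimum side of each standard rectangle, pixels.
#' @param quantize round gray levels to integers (detector quantization).
#'   Set `FALSE` for an idealized continuous field: a noiseless
#'   unquantized field round-trips density per pixel exactly through
#'   [calibrate_gray()].
#' @param seed integer seed.
#' @return an object of class `gray_field`: list with `pixels` (numeric
#'   matrix of integral gray levels), `standard_regions` (data.frame
#'   `name, density, row0, row1, col0, col1`), `bone_mask` (logical
#'   matrix), `bit_depth`, and a `truth` element recording the generating
#'   distribution and map.
#' @export
gen_gray_field <- function(bone_density_mean = 1100, bone_density_sd = 66,
                           standards = data.frame(
                             name = c("dm_low", "dm_mid", "dm_high"),
                             density = c(800, 1100, 1400)),
                           size = c(64, 96),
                           gain = 10, offset = 1000,
                           noise_sd_gray = 0, bit_depth = 16,
                           standard_px = 10, quantize = TRUE, seed = 1L) {
  check_field(is.data.frame(standards) && nrow(standards) >= 2,
              "standards", "calibration needs at least two standards")
  check_field(!anyDuplicated(standards$density), "standards",
              "standard densities must be distinct")
  check_finite_positive(bone_density_sd, "bone_density_sd", allow_zero = TRUE)
  check_finite_positive(bone_density_mean, "bone_density_mean")
  check_field(bit_depth %in% c(8, 16), "bit_depth", "must be 8 or 16")
  check_field(gain != 0, "gain", "density->gray map must be monotone")
  nr <- size[1]; nc <- size[2]
  n_std <- nrow(standards)
  check_field(nc >= n_std * (standard_px + 2), "size",
              "raster too narrow for the standard regions")
  check_field(nr >= 2 * standard_px + 4, "size", "raster too short")

  gmax <- 2^bit_depth - 1
  to_gray <- function(density) gain * density + offset

  pixels <- matrix(0, nr, nc)
  # standards across the top row, evenly spaced
  col_step <- nc %/% n_std
  regions <- data.frame(
    name = standards$name, density = standards$density,
    row0 = 1L, row1 = 1L + standard_px,
    col0 = (seq_len(n_std) - 1L) * col_step + 1L,
    col1 = (seq_len(n_std) - 1L) * col_step + 1L + standard_px
  )
  # bone rectangle in the lower half
  bone_row0 <- standard_px + 3L
  bone <- c(row0 = bone_row0, row1 = nr - 2L, col0 = 2L, col1 = nc - 2L)
  n_bone <- (bone[["row1"]] - bone[["row0"]]) * (bone[["col1"]] - bone[["col0"]])

  dens <- with_seed(split_seed(seed, 0L),
                    rnorm(n_bone, bone_density_mean, bone_density_sd))
  noise <- if (noise_sd_gray > 0) {
    with_seed(split_seed(seed, 1L),
              list(std = rnorm(n_std * (standard_px + 1)^2, 0, noise_sd_gray),
                   bone = rnorm(n_bone, 0, noise_sd_gray)))
  } else {
    list(std = 0, bone = 0)
  }

  clip <- function(g) pmin(pmax(if (quantize) round(g) else g, 0), gmax)

  for (i in seq_len(n_std)) {
    rr <- (regions$row0[i] + 1L):regions$row1[i]
    cc <- (regions$col0[i] + 1L):regions$col1[i]
    np <- length(rr) * length(cc)
    nz <- if (length(noise$std) > 1) {
      noise$std[((i - 1L) * np + 1L):(i * np)]
    } else 0
    pixels[rr, cc] <- clip(to_gray(standards$density[i]) + nz)
  }
  bone_mask <- matrix(FALSE, nr, nc)
  bone_mask[(bone[["row0"]] + 1L):bone[["row1"]],
            (bone[["col0"]] + 1L):bone[["col1"]]] <- TRUE
  pixels[bone_mask] <- clip(to_gray(dens) + noise$bone)

  structure(
    list(pixels = pixels, standard_regions = regions,
         bone_mask = bone_mask, bit_depth = bit_depth,
         truth = list(bone_density_mean = bone_density_mean,
                      bone_density_sd = bone_density_sd,
                      gain = gain, offset = offset,
                      noise_sd_gray = noise_sd_gray,
                      bone_densities = dens)),
    class = "gray_field"
  )
}
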