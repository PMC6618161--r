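# ASBMR histomorphometry and growth-plate morphometry.
#
# Inputs are trace tables (segment lengths with flags, osteoid widths,
# calcein inter-label distances), mirroring manual/ImageJ tracing; image
# segmentation is out of scope.  Conventions:
#   Oc.N/B.Pm  = osteoclast count / bone perimeter            (mm^-1)
#   Oc.S/B.Pm  = 100 * osteoclast-covered length / B.Pm       (%)
#   MS         = 100 * (dL + sL/2) / B.Pm                     (%)
#   MAR        = mean inter-label distance / label interval   (um/day)
#   BFR        = (MS/100) * MAR                               (um/day)
#   OS/B.Pm    = 100 * osteoid length / B.Pm                  (%)
#   O.Th       = mean osteoid seam width                      (um)
#   ES/B.Pm    = 100 * eroded length / B.Pm                   (%)

.valid_flags <- c("osteoclast", "osteoid", "eroded", "double_label",
                  "single_label", "plain")

#' Build a histomorphometry record from a trace table
#'
#' @param segments data.frame `segment_id, length_um, flag` and optionally
#'   `width_um` (osteoid) and `interlabel_um` (double-label distances).
#' @param label_interval_days days between calcein injections (default 2).
#' @param n_osteoclasts osteoclast count on the section; defaults to the
#'   number of osteoclast-flagged segments.
#' @return object of class `histomorph_record`: `b_pm_mm`, per-flag
#'   lengths (mm), `n_osteoclasts`, `osteoid_widths_um`,
#'   `interlabel_um`, `label_interval_days`.
#' @export
histomorph_record <- function(segments, label_interval_days = 2,
                              n_osteoclasts = NULL) {
  check_field(is.data.frame(segments) &&
                all(c("length_um", "flag") %in% names(segments)),
              "segments", "needs length_um and flag columns")
  check_field(all(segments$flag %in% .valid_flags), "flag",
              paste("must be one of:", paste(.valid_flags, collapse = ", ")))
  check_field(all(segments$length_um >= 0), "length_um", "must be >= 0")
  check_finite_positive(label_interval_days, "label_interval_days")
  b_pm_mm <- sum(segments$length_um) / 1000
  len_mm <- function(f) sum(segments$length_um[segments$flag == f]) / 1000
  widths <- if ("width_um" %in% names(segments)) {
    w <- segments$width_um[segments$flag == "osteoid" &
                             !is.na(segments$width_um)]
    check_field(all(w >= 0), "width_um", "negative widths")
    w
  } else numeric(0)
  inter <- if ("interlabel_um" %in% names(segments)) {
    d <- segments$interlabel_um[!is.na(segments$interlabel_um)]
    check_field(all(d >= 0), "interlabel_um", "distances must be >= 0")
    d
  } else numeric(0)
  if (is.null(n_osteoclasts)) {
    n_osteoclasts <- sum(segments$flag == "osteoclast")
  }
  structure(
    list(b_pm_mm = b_pm_mm,
         oc_len_mm = len_mm("osteoclast"),
         osteoid_len_mm = len_mm("osteoid"),
         eroded_len_mm = len_mm("eroded"),
         dl_len_mm = len_mm("double_label"),
         sl_len_mm = len_mm("single_label"),
         n_osteoclasts = n_osteoclasts,
         osteoid_widths_um = widths,
         interlabel_um = inter,
         label_interval_days = label_interval_days),
    class = "histomorph_record"
  )
}

# internal: covered-length sanity
.check_cover <- function(len, b_pm, what) {
  if (len > b_pm + 1e-9) {
    stop(sprintf("%s length (%g mm) exceeds bone perimeter (%g mm)",
                 what, len, b_pm), call. = FALSE)
  }
}

#' Osteoclast parameters
#'
#' @param rec a [histomorph_record()].
#' @return list: `Oc.N_per_B.Pm` (mm^-1), `Oc.S_per_B.Pm` (%), and raw
#'   osteoclast perimeter `Oc.Pm_mm` (emitted unnormalized).
#' @export
osteoclast_params <- function(rec) {
  stopifnot(inherits(rec, "histomorph_record"))
  check_field(rec$b_pm_mm > 0, "b_pm_mm", "bone perimeter must be > 0")
  .check_cover(rec$oc_len_mm, rec$b_pm_mm, "osteoclast-covered")
  list(Oc.N_per_B.Pm = rec$n_osteoclasts / rec$b_pm_mm,
       Oc.S_per_B.Pm = 100 * rec$oc_len_mm / rec$b_pm_mm,
       Oc.Pm_mm = rec$oc_len_mm)
}

#' Dynamic bone-formation parameters (MS, MAR, BFR)
#'
#' MS uses the ASBMR double + half-single convention by default; set
#' `pure_double = TRUE` to count double-labelled surface only.
#'
#' @param rec a [histomorph_record()].
#' @param pure_double count only double-labelled surface in MS.
#' @return list: `MS_percent`, `MAR_um_day` (NA with `mar_undefined` flag
#'   when there are no double labels), `BFR_um_day` (omitted as NA when
#'   MAR is undefined).
#' @export
dynamic_formation <- function(rec, pure_double = FALSE) {
  stopifnot(inherits(rec, "histomorph_record"))
  check_field(rec$b_pm_mm > 0, "b_pm_mm", "bone perimeter must be > 0")
  labelled <- rec$dl_len_mm + if (pure_double) 0 else rec$sl_len_mm / 2
  .check_cover(rec$dl_len_mm + rec$sl_len_mm, rec$b_pm_mm, "labelled")
  ms <- 100 * labelled / rec$b_pm_mm
  if (length(rec$interlabel_um) == 0) {
    return(list(MS_percent = ms, MAR_um_day = NA_real_,
                BFR_um_day = NA_real_, mar_undefined = TRUE))
  }
  mar <- mean(rec$interlabel_um) / rec$label_interval_days
  list(MS_percent = ms, MAR_um_day = mar,
       BFR_um_day = (ms / 100) * mar, mar_undefined = FALSE)
}

#' Osteoid parameters
#'
#' @param rec a [histomorph_record()].
#' @return list: `OS_per_B.Pm` (%), `O.Th_um` (NA when no widths traced).
#' @export
osteoid_params <- function(rec) {
  stopifnot(inherits(rec, "histomorph_record"))
  check_field(rec$b_pm_mm > 0, "b_pm_mm", "bone perimeter must be > 0")
  .check_cover(rec$osteoid_len_mm, rec$b_pm_mm, "osteoid")
  list(OS_per_B.Pm = 100 * rec$osteoid_len_mm / rec$b_pm_mm,
       O.Th_um = if (length(rec$osteoid_widths_um) > 0) {
         mean(rec$osteoid_widths_um)
       } else NA_real_)
}

#' Eroded (resorption) surface fraction
#'
#' @param rec a [histomorph_record()].
#' @return eroded surface as percent of bone perimeter.
#' @export
resorption_fraction <- function(rec) {
  stopifnot(inherits(rec, "histomorph_record"))
  check_field(rec$b_pm_mm > 0, "b_pm_mm", "bone perimeter must be > 0")
  .check_cover(rec$eroded_len_mm, rec$b_pm_mm, "eroded")
  100 * rec$eroded_len_mm / rec$b_pm_mm
}

#' Growth-plate zone heights and chondrocyte counts
#'
#' Zone heights are averaged over the four x-locations; relative fractions
#' are of the total growth-plate height, and cell fractions analogous.
#'
#' @param raw a `growth_plate_raw` object (see [gen_histomorph_tables()]):
#'   `boundaries` data.frame with `x_location, y_top, y_rz_pz, y_pz_hz,
#'   y_bottom` (um, 4 rows) and `cell_counts` named over RZ/PZ/HZ.
#' @return list: `heights_um` (RZ, PZ, HZ, total), `fractions_percent`,
#'   `cell_counts`, `cell_fractions_percent`.
#' @export
growth_plate_heights <- function(raw) {
  b <- raw$boundaries
  check_field(is.data.frame(b) && nrow(b) == 4 &&
                all(c("x_location", "y_top", "y_rz_pz", "y_pz_hz",
                      "y_bottom") %in% names(b)),
              "boundaries", "needs 4 x-locations with ordered boundaries")
  check_field(length(unique(b$x_location)) == 4, "boundaries",
              "missing x-location")
  ok <- b$y_top <= b$y_rz_pz & b$y_rz_pz <= b$y_pz_hz &
    b$y_pz_hz <= b$y_bottom
  check_field(all(ok), "boundaries", "zone boundaries out of order")
  h <- c(RZ = mean(b$y_rz_pz - b$y_top),
         PZ = mean(b$y_pz_hz - b$y_rz_pz),
         HZ = mean(b$y_bottom - b$y_pz_hz))
  total <- sum(h)
  counts <- raw$cell_counts
  check_field(all(counts >= 0), "cell_counts", "counts must be >= 0")
  list(heights_um = c(h, total = total),
       fractions_percent = 100 * h / total,
       cell_counts = counts,
       cell_fractions_percent = 100 * counts / sum(counts))
}

#' Average histomorphometry outputs over section replicates
#'
#' Sections from separate levels are averaged per animal before any group
#' statistics.
#'
#' @param recs list of [histomorph_record()]s from one animal.
#' @return list with the averaged parameter sets (`osteoclast`,
#'   `dynamic`, `osteoid`, `eroded_percent`); the BFR identity is
#'   re-imposed on the averaged MS and MAR.
#' @export
average_sections <- function(recs) {
  stopifnot(length(recs) >= 1)
  oc <- lapply(recs, osteoclast_params)
  dy <- lapply(recs, dynamic_formation)
  os <- lapply(recs, osteoid_params)
  er <- vapply(recs, resorption_fraction, numeric(1))
  m <- function(xs) mean(unlist(xs), na.rm = TRUE)
  ms <- m(lapply(dy, `[[`, "MS_percent"))
  mar <- m(lapply(dy, `[[`, "MAR_um_day"))
  list(
    osteoclast = list(
      Oc.N_per_B.Pm = m(lapply(oc, `[[`, "Oc.N_per_B.Pm")),
      Oc.S_per_B.Pm = m(lapply(oc, `[[`, "Oc.S_per_B.Pm"))),
    dynamic = list(MS_percent = ms, MAR_um_day = mar,
                   BFR_um_day = (ms / 100) * mar),
    osteoid = list(OS_per_B.Pm = m(lapply(os, `[[`, "OS_per_B.Pm")),
                   O.Th_um = m(lapply(os, `[[`, "O.Th_um"))),
    eroded_percent = mean(er)
  )
}
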