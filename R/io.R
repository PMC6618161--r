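# File formats.
#
# All tabular I/O is UTF-8 CSV with explicit headers; raster I/O uses
# plain-text portable graymap (PGM, P2) because it is text-reviewable and
# needs no imaging dependency; region sidecars are JSON with 0-based,
# half-open, row-major pixel coordinates.  Numeric outputs are written at
# full precision.

#' Write a load-displacement curve to CSV
#'
#' @param curve a curve data.frame (`displacement_mm`, `load_N`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(curve[, c("displacement_mm", "load_N")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a load-displacement curve from CSV
#'
#' @param path CSV with header `displacement_mm,load_N`.
#' @param sample_rate sampling frequency metadata, Hz.
#' @param test_type `"three_point_bend"` or `"compression"` (metadata
#'   only; the analysis is identical).
#' @return a `load_displacement_curve` data.frame.
#' @export
read_curve_csv <- function(path, sample_rate = 20,
                           test_type = c("three_point_bend", "compression")) {
  test_type <- match.arg(test_type)
  x <- read.csv(path)
  check_field(all(c("displacement_mm", "load_N") %in% names(x)),
              "curve file", "header must be displacement_mm,load_N")
  class(x) <- c("load_displacement_curve", "data.frame")
  attr(x, "sample_rate") <- sample_rate
  attr(x, "test_type") <- test_type
  x
}

#' Write a specimen cohort/group to CSV (+ ground-truth sidecar)
#'
#' @param cohort specimen data.frame.
#' @param path output CSV; if the cohort carries a `"truth"` attribute it
#'   is written alongside as `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("specimen_id", "genotype", "sex", "bmc", .biomech_params)
  write.csv(cohort[, intersect(cols, names(cohort))], path,
            row.names = FALSE, quote = FALSE)
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    tr$model <- NULL  # the closure-bearing model object is not serializable
    tr$bone_densities <- NULL
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a specimen cohort/group from CSV
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return data.frame of class `reference_cohort`.
#' @export
read_cohort_csv <- function(path) {
  x <- read.csv(path)
  class(x) <- c("reference_cohort", "data.frame")
  x
}

#' Write a gray field as ASCII PGM plus JSON region sidecar
#'
#' The raster goes to `<path>` (P2 portable graymap, text), the bone mask
#' to `<path>.mask.pgm` (0/1), and the standard regions to
#' `<path>.regions.json`.
#'
#' @param field a `gray_field`.
#' @param path output path for the main raster (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_gray_pgm <- function(field, path) {
  write_pgm(field$pixels, path, maxval = 2^field$bit_depth - 1)
  write_pgm(field$bone_mask * 1L, paste0(path, ".mask.pgm"), maxval = 1)
  jsonlite::write_json(
    list(standard_regions = field$standard_regions,
         bit_depth = field$bit_depth,
         coordinates = "0-based, half-open, row-major"),
    paste0(path, ".regions.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Read a gray field written by [write_gray_pgm()]
#'
#' @param path path of the main raster.
#' @return a `gray_field`-like list (`pixels`, `standard_regions`,
#'   `bone_mask`, `bit_depth`); no `truth` element.
#' @export
read_gray_pgm <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".regions.json"),
                              simplifyVector = TRUE)
  structure(
    list(pixels = read_pgm(path),
         standard_regions = side$standard_regions,
         bone_mask = read_pgm(paste0(path, ".mask.pgm")) > 0,
         bit_depth = side$bit_depth),
    class = "gray_field"
  )
}

#' Write a numeric matrix as ASCII PGM (P2)
#'
#' @param m numeric matrix (values are rounded; PGM stores integers).
#' @param path output file.
#' @param maxval maximum gray value declared in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = 65535) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), format(maxval)), con)
  apply_rows <- apply(m, 1, function(r) paste(format(round(r), trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " "))
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read an ASCII PGM (P2) file
#'
#' @param path PGM file.
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  check_field(toks[1] == "P2", "pgm", "only ASCII (P2) PGM is supported")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  check_field(length(vals) == nr * nc, "pgm", "truncated pixel data")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a density histogram to CSV
#'
#' @param h a `density_histogram`.
#' @param path output CSV (`bin_lo,bin_hi,freq`).
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(h, path) {
  nb <- length(h$freq)
  write.csv(data.frame(bin_lo = h$bin_edges[seq_len(nb)],
                       bin_hi = h$bin_edges[seq_len(nb) + 1L],
                       freq = h$freq),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a histomorphometry trace table from CSV
#'
#' @param path CSV with header
#'   `segment_id,length_um,flag,width_um,interlabel_um`.
#' @return data.frame of segments.
#' @export
read_trace_csv <- function(path) {
  x <- read.csv(path)
  check_field(all(c("segment_id", "length_um", "flag") %in% names(x)),
              "trace file", "header must include segment_id,length_um,flag")
  x
}

# internal: md5 of a canonical JSON rendering, for provenance stamps
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
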