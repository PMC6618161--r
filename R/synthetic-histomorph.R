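# Synthetic histomorphometry trace tables and growth-plate morphometry.
#
# Emulates manual/ImageJ tracing output: per-section perimeter segments
# flagged as osteoclast-covered, osteoid, eroded, calcein double/single
# labelled or plain, with osteoid widths and inter-label distances, plus
# growth-plate zone boundary coordinates at four x-locations and
# chondrocyte counts in a 200-um-wide central counting region.

#' Configuration for the synthetic histomorphometry generator
#'
#' All coverage fractions are of total bone perimeter and must sum to at
#' most 1 together; jitter SDs are relative (fraction of the mean).
#'
#' @param b_pm_mm total bone perimeter per section, mm.
#' @param n_segments number of perimeter segments the trace is split into.
#' @param oc_coverage fraction of perimeter covered by osteoclasts.
#' @param n_osteoclasts number of osteoclasts on the section.
#' @param osteoid_fraction fraction of perimeter bearing osteoid.
#' @param osteoid_width_um mean osteoid seam width, um.
#' @param eroded_fraction fraction of perimeter showing resorption.
#' @param dl_fraction fraction of perimeter double-labelled with calcein.
#' @param sl_fraction fraction single-labelled.
#' @param label_sep_um mean separation between double calcein labels, um.
#' @param label_interval_days days between calcein injections (default 2:
#'   injections 5 and 3 days before euthanasia).
#' @param n_label_measurements number of inter-label distance measurements.
#' @param zone_heights_um named vector of true growth-plate zone heights
#'   `c(RZ=, PZ=, HZ=)`, um.
#' @param cells_per_zone named vector of true chondrocyte counts in the
#'   200-um counting region per zone.
#' @param jitter relative measurement jitter SD (0 = noiseless).
#' @return a list of class `histomorph_config`.
#' @export
histomorph_config <- function(b_pm_mm = 10, n_segments = 40,
                              oc_coverage = 0.12, n_osteoclasts = 5,
                              osteoid_fraction = 0.05, osteoid_width_um = 4,
                              eroded_fraction = 0.25,
                              dl_fraction = 0.20, sl_fraction = 0.05,
                              label_sep_um = 4, label_interval_days = 2,
                              n_label_measurements = 30,
                              zone_heights_um = c(RZ = 50, PZ = 100, HZ = 50),
                              cells_per_zone = c(RZ = 10, PZ = 40, HZ = 15),
                              jitter = 0) {
  for (f in c("oc_coverage", "osteoid_fraction", "eroded_fraction",
              "dl_fraction", "sl_fraction")) {
    v <- get(f)
    check_field(is.finite(v) && v >= 0 && v <= 1, f,
                "coverage fraction must be in [0, 1]")
  }
  check_finite_positive(b_pm_mm, "b_pm_mm")
  check_finite_positive(label_sep_um, "label_sep_um")
  check_finite_positive(label_interval_days, "label_interval_days")
  check_finite_positive(jitter, "jitter", allow_zero = TRUE)
  check_field(all(zone_heights_um >= 0) &&
                all(c("RZ", "PZ", "HZ") %in% names(zone_heights_um)),
              "zone_heights_um", "needs non-negative RZ, PZ, HZ")
  check_field(all(cells_per_zone >= 0), "cells_per_zone", "counts >= 0")
  structure(as.list(environment()), class = "histomorph_config")
}

# internal: split a total length into k jittered pieces summing to total
.split_len <- function(total, k, jitter) {
  if (k == 0L || total <= 0) return(numeric(0))
  w <- rep(1, k)
  if (jitter > 0) w <- pmax(w + rnorm(k, 0, jitter), 0.05)
  total * w / sum(w)
}

#' Generate synthetic histomorphometry trace tables
#'
#' Produces one section's trace table and growth-plate raw measurements,
#' consistent with the configured ground truth (attached as `"truth"`).
#'
#' @param config a [histomorph_config()].
#' @param seed integer seed.
#' @return list of class `histomorph_tables` with elements `segments`
#'   (data.frame `segment_id, length_um, flag, width_um, interlabel_um`),
#'   `label_interval_days`, and `growth_plate` (a `growth_plate_raw`
#'   object: boundary y-coordinates at 4 x-locations plus cell counts).
#' @export
gen_histomorph_tables <- function(config = histomorph_config(), seed = 1L) {
  stopifnot(inherits(config, "histomorph_config"))
  cfg <- config
  covered <- cfg$oc_coverage + cfg$osteoid_fraction + cfg$eroded_fraction +
    cfg$dl_fraction + cfg$sl_fraction
  check_field(covered <= 1, "coverage fractions",
              "flagged fractions must sum to <= 1")
  total_um <- cfg$b_pm_mm * 1000

  with_seed(split_seed(seed, 0L), {
    flags <- c("osteoclast", "osteoid", "eroded", "double_label",
               "single_label", "plain")
    fracs <- c(cfg$oc_coverage, cfg$osteoid_fraction, cfg$eroded_fraction,
               cfg$dl_fraction, cfg$sl_fraction, 1 - covered)
    # at least one segment per non-empty class, rest proportional
    n_per <- pmax(ifelse(fracs > 0, 1L, 0L),
                  round(fracs * cfg$n_segments))
    seg_len <- list(); seg_flag <- list()
    for (i in seq_along(flags)) {
      if (n_per[i] > 0L && fracs[i] > 0) {
        # tracing error perturbs each class total as well as the splits
        class_total <- total_um * fracs[i]
        if (cfg$jitter > 0) {
          class_total <- class_total *
            max(1 + rnorm(1, 0, cfg$jitter / sqrt(n_per[i])), 0.05)
        }
        seg_len[[i]] <- .split_len(class_total, n_per[i], cfg$jitter)
        seg_flag[[i]] <- rep(flags[i], n_per[i])
      }
    }
    segments <- data.frame(
      segment_id = seq_along(unlist(seg_len)),
      length_um = unlist(seg_len),
      flag = unlist(seg_flag),
      width_um = NA_real_,
      interlabel_um = NA_real_
    )
    ost <- segments$flag == "osteoid"
    if (any(ost)) {
      w <- rep(cfg$osteoid_width_um, sum(ost))
      if (cfg$jitter > 0) {
        w <- pmax(w * (1 + rnorm(sum(ost), 0, cfg$jitter)), 0)
      }
      segments$width_um[ost] <- w
    }
    # inter-label distances ride on double-label segments (recycled)
    if (cfg$dl_fraction > 0 && cfg$n_label_measurements > 0) {
      d <- rep(cfg$label_sep_um, cfg$n_label_measurements)
      if (cfg$jitter > 0) {
        d <- pmax(d * (1 + rnorm(length(d), 0, cfg$jitter)), 0)
      }
      dl_idx <- which(segments$flag == "double_label")
      extra <- segments[rep(dl_idx[1], max(0, length(d) - length(dl_idx))), ]
      if (nrow(extra) > 0) {
        extra$length_um <- 0  # measurement-only rows carry no perimeter
        segments <- rbind(segments, extra)
      }
      rows <- c(dl_idx, seq_len(nrow(extra)) + (nrow(segments) - nrow(extra)))
      segments$interlabel_um[rows[seq_along(d)]] <- d
      segments$segment_id <- seq_len(nrow(segments))
    }

    # growth plate: 4 x-locations, stacked zone boundaries top to bottom
    zh <- cfg$zone_heights_um
    gp <- do.call(rbind, lapply(1:4, function(x) {
      j <- function(h) if (cfg$jitter > 0) max(h * (1 + rnorm(1, 0, cfg$jitter)), 0) else h
      rz <- j(zh[["RZ"]]); pz <- j(zh[["PZ"]]); hz <- j(zh[["HZ"]])
      data.frame(x_location = x, y_top = 0, y_rz_pz = rz,
                 y_pz_hz = rz + pz, y_bottom = rz + pz + hz)
    }))
    counts <- cfg$cells_per_zone
    if (cfg$jitter > 0) {
      counts <- pmax(round(counts * (1 + rnorm(length(counts), 0, cfg$jitter))), 0)
    }
    growth_plate <- structure(
      list(boundaries = gp,
           cell_counts = setNames(as.numeric(counts), names(cfg$cells_per_zone)),
           counting_region_um = 200),
      class = "growth_plate_raw"
    )

    structure(
      list(segments = segments,
           label_interval_days = cfg$label_interval_days,
           growth_plate = growth_plate),
      class = "histomorph_tables",
      truth = list(config = cfg)
    )
  })
}
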