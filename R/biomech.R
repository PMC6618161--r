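# Extraction of biomechanical parameters from load-displacement curves.
#
# Yield load, maximum load, fracture load and stiffness are read off a
# destructive-test curve:
#   * contact: first sample whose load reaches a small fraction of the
#     curve maximum (the pre-contact toe carries no information);
#   * stiffness: least-squares slope over an automatically selected
#     elastic window between contact and the load maximum;
#   * yield: first sample after the elastic window falling a configurable
#     offset (fraction of max load) below the extrapolated elastic line;
#   * fracture: load immediately preceding the largest single-step
#     post-peak drop, when that drop is big enough to be a failure event.
#
# Window selection: among windows of length >= min_window_fraction of the
# contact-to-peak span, anchor at the earliest start position from which
# some window clears the R^2 threshold, and take the longest passing
# window from that anchor.  Anchoring matters: a ductile curve's
# post-yield (hardening) segment is also linear and can be longer than
# the elastic segment, but the elastic phase is by definition the first
# linear region after contact.  The threshold is the fixed floor `r2_min` tightened
# adaptively to max(r2_min, 1 - r2_relax * (1 - R2_best)), where R2_best
# is the best R^2 achieved by any candidate window.  On noiseless data
# R2_best ~ 1 so only exactly linear windows are accepted and the elastic
# slope is recovered to machine precision; on noisy data the adaptive
# term relaxes toward the fixed floor.  Without the adaptive term the
# longest-window rule drags the window into the hardening segment on
# clean data (a handful of post-yield points barely dent R^2), which
# biases stiffness and breaks exact recovery.

#' Configuration for biomechanical curve analysis
#'
#' @param contact_fraction load threshold for contact detection, as a
#'   fraction of the curve maximum (default 0.01).
#' @param min_window_fraction minimum elastic-window length as a fraction
#'   of the contact-to-peak span (default 0.10).
#' @param r2_min fixed floor on the elastic-fit R^2 (default 0.995).
#' @param r2_relax adaptive tightening factor (default 2): windows must
#'   reach `1 - r2_relax * (1 - best R^2)` when that is above `r2_min`.
#' @param yield_offset_fraction offset below the elastic line that marks
#'   yield, as a fraction of max load (default 0.02).
#' @param fracture_drop_fraction minimum single-step drop (fraction of max
#'   load) accepted as the fracture event (default 0.30).
#' @param smooth_window odd width of the centred moving average used only
#'   for event detection; 0 disables smoothing (default 0).  Reported load
#'   values always come from the raw curve.
#' @return list of class `biomech_config`.
#' @export
biomech_config <- function(contact_fraction = 0.01,
                           min_window_fraction = 0.10,
                           r2_min = 0.995, r2_relax = 2,
                           yield_offset_fraction = 0.02,
                           fracture_drop_fraction = 0.30,
                           smooth_window = 0) {
  check_field(contact_fraction > 0 && contact_fraction < 1,
              "contact_fraction", "must be in (0, 1)")
  check_field(min_window_fraction > 0 && min_window_fraction <= 1,
              "min_window_fraction", "must be in (0, 1]")
  check_field(r2_min > 0 && r2_min < 1, "r2_min", "must be in (0, 1)")
  check_field(r2_relax >= 1, "r2_relax", "must be >= 1")
  check_field(yield_offset_fraction > 0, "yield_offset_fraction",
              "must be > 0")
  check_field(fracture_drop_fraction > 0 && fracture_drop_fraction <= 1,
              "fracture_drop_fraction", "must be in (0, 1]")
  check_field(smooth_window == 0 ||
                (smooth_window >= 3 && smooth_window %% 2 == 1),
              "smooth_window", "must be 0 or an odd integer >= 3")
  structure(as.list(environment()), class = "biomech_config")
}

# internal: validate a curve data.frame
.check_curve <- function(curve) {
  check_field(is.data.frame(curve) &&
                all(c("displacement_mm", "load_N") %in% names(curve)),
              "curve", "needs columns displacement_mm and load_N")
  check_field(all(is.finite(curve$displacement_mm)) &&
                all(is.finite(curve$load_N)),
              "curve", "non-finite values")
  check_field(nrow(curve) >= 20, "curve", "needs >= 20 samples")
  d <- curve$displacement_mm
  if (any(diff(d) < 0)) {
    stop("non-monotone displacement: the actuator channel must be ",
         "non-decreasing", call. = FALSE)
  }
  invisible(TRUE)
}

# internal: centred moving average used only for event detection
.smooth <- function(y, w) {
  if (w == 0) return(y)
  k <- rep(1 / w, w)
  n <- length(y)
  s <- stats::filter(y, k, sides = 2)
  s <- as.numeric(s)
  s[is.na(s)] <- y[is.na(s)]
  s
}

#' Detect the contact point and the linear elastic region
#'
#' @param curve data.frame with `displacement_mm` and `load_N`.
#' @param config a [biomech_config()].
#' @return list with `contact_index`, `elastic_window` (index pair into
#'   the curve), `stiffness` (N/mm), `r_squared`, and `intercept` of the
#'   elastic line.
#' @export
detect_contact_and_elastic <- function(curve, config = biomech_config()) {
  .check_curve(curve)
  cfg <- config
  load_det <- .smooth(curve$load_N, cfg$smooth_window)
  peak <- max(load_det)
  contact <- which(load_det >= cfg$contact_fraction * peak)[1]
  imax <- which.max(load_det)
  span <- imax - contact + 1L
  if (is.na(contact) || span < 4L) {
    stop("no elastic region: curve has no usable rise before its maximum",
         call. = FALSE)
  }
  idx <- contact:imax
  x <- curve$displacement_mm[idx]
  y <- load_det[idx]
  n <- length(x)
  min_len <- max(4L, as.integer(ceiling(cfg$min_window_fraction * n)))

  # prefix sums give O(1) slope and R^2 per window
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, x^2)); cyy <- cumsum(c(0, y^2))
  cxy <- cumsum(c(0, x * y))
  win_stats <- function(starts, len) {
    e <- starts + len - 1L
    sw <- len
    sx <- cx[e + 1L] - cx[starts]; sy <- cy[e + 1L] - cy[starts]
    sxx <- cxx[e + 1L] - cxx[starts]; syy <- cyy[e + 1L] - cyy[starts]
    sxy <- cxy[e + 1L] - cxy[starts]
    vx <- sxx - sx^2 / sw
    vy <- syy - sy^2 / sw
    cvxy <- sxy - sx * sy / sw
    slope <- ifelse(vx > 0, cvxy / vx, NA_real_)
    r2 <- ifelse(vx > 0 & vy > 0, pmin(cvxy^2 / (vx * vy), 1), NA_real_)
    list(slope = slope, r2 = r2,
         intercept = (sy - slope * sx) / sw)
  }

  lens <- min_len:n
  per_len <- vector("list", length(lens))
  best_r2 <- -Inf
  for (li in seq_along(lens)) {
    len <- lens[li]
    starts <- 1:(n - len + 1L)
    st <- win_stats(starts, len)
    ok <- !is.na(st$r2) & !is.na(st$slope) & st$slope > 0
    st$r2[!ok] <- NA_real_
    per_len[[li]] <- st$r2
    if (any(ok)) best_r2 <- max(best_r2, max(st$r2, na.rm = TRUE))
  }
  if (!is.finite(best_r2) || best_r2 < cfg$r2_min) {
    stop(sprintf(
      "no elastic region: best linear-fit R^2 = %s is below r2_min = %g",
      ifelse(is.finite(best_r2), format(best_r2, digits = 4), "NA"),
      cfg$r2_min), call. = FALSE)
  }
  thresh <- max(cfg$r2_min, 1 - cfg$r2_relax * (1 - best_r2))
  # anchor at the earliest start with any passing window (the elastic
  # phase is the first linear region after contact; a later post-yield
  # segment may be longer but is not the elastic phase), then take the
  # longest passing window from that anchor
  r2_at <- function(s, li) {
    r2v <- per_len[[li]]
    if (s <= length(r2v)) r2v[s] else NA_real_
  }
  for (s in 1:(n - min_len + 1L)) {
    passing <- which(vapply(seq_along(lens), function(li) {
      r2 <- r2_at(s, li)
      !is.na(r2) && r2 >= thresh
    }, logical(1)))
    if (length(passing) > 0) {
      len <- lens[max(passing)]
      w0 <- idx[s]; w1 <- idx[s + len - 1L]
      # report slope/intercept from the raw (unsmoothed) loads
      xr <- curve$displacement_mm[w0:w1]
      yr <- curve$load_N[w0:w1]
      fit <- lm.fit(cbind(1, xr), yr)
      slope <- fit$coefficients[2]
      ssr <- sum(fit$residuals^2)
      sst <- sum((yr - mean(yr))^2)
      return(list(contact_index = idx[1],
                  elastic_window = c(w0, w1),
                  stiffness = unname(slope),
                  intercept = unname(fit$coefficients[1]),
                  r_squared = if (sst > 0) 1 - ssr / sst else NA_real_))
    }
  }
  stop(sprintf(
    "no elastic region: best linear-fit R^2 = %s is below the adaptive threshold %g",
    format(best_r2, digits = 4), thresh), call. = FALSE)
}

#' Extract yield, maximum, fracture load and stiffness from a curve
#'
#' @inheritParams detect_contact_and_elastic
#' @return list of class `biomech_params`: `yield_load`, `max_load`,
#'   `fracture_load` (N), `stiffness` (N/mm), `flags` (character vector,
#'   possibly empty: `"no distinct yield"`, `"no clean fracture"`), and
#'   `diagnostics` (elastic window, R^2, contact index).
#' @export
extract_biomech_params <- function(curve, config = biomech_config()) {
  cfg <- config
  el <- detect_contact_and_elastic(curve, cfg)
  load <- curve$load_N
  disp <- curve$displacement_mm
  n <- length(load)
  contact <- el$contact_index
  imax <- contact - 1L + which.max(load[contact:n])
  max_load <- load[imax]
  flags <- character(0)

  # yield: first post-window sample falling `offset` below the elastic line
  det <- .smooth(load, cfg$smooth_window)
  w1 <- el$elastic_window[2]
  yield_load <- NA_real_
  if (w1 < n) {
    after <- (w1 + 1L):n
    pred <- el$intercept + el$stiffness * disp[after]
    dev <- pred - det[after]
    hit <- which(dev >= cfg$yield_offset_fraction * max_load)[1]
    if (!is.na(hit)) yield_load <- load[after[hit]]
  }
  if (is.na(yield_load)) {
    yield_load <- max_load
    flags <- c(flags, "no distinct yield")
  }
  yield_load <- min(yield_load, max_load)

  # fracture: largest single-step drop after the peak
  fracture_load <- load[n]
  if (imax < n) {
    drops <- det[imax:(n - 1L)] - det[(imax + 1L):n]
    k <- which.max(drops)
    if (drops[k] >= cfg$fracture_drop_fraction * max_load) {
      fracture_load <- load[imax + k - 1L]
    } else {
      flags <- c(flags, "no clean fracture")
    }
  } else {
    flags <- c(flags, "no clean fracture")
  }
  fracture_load <- min(fracture_load, max_load)

  structure(
    list(yield_load = yield_load, max_load = max_load,
         fracture_load = fracture_load, stiffness = el$stiffness,
         flags = flags,
         diagnostics = list(contact_index = el$contact_index,
                            elastic_window = el$elastic_window,
                            r_squared = el$r_squared,
                            max_index = imax)),
    class = "biomech_params"
  )
}

#' Batch biomechanical extraction
#'
#' @param curves list of curve data.frames (optionally named).
#' @param config a [biomech_config()].
#' @return data.frame with one row per curve: the four parameters, flags
#'   (collapsed, `;`-separated) and elastic-fit diagnostics.
#' @export
biomech_report <- function(curves, config = biomech_config()) {
  rows <- lapply(seq_along(curves), function(i) {
    p <- extract_biomech_params(curves[[i]], config)
    data.frame(
      curve = if (!is.null(names(curves))) names(curves)[i] else i,
      yield_load = p$yield_load, max_load = p$max_load,
      fracture_load = p$fracture_load, stiffness = p$stiffness,
      flags = paste(p$flags, collapse = ";"),
      elastic_r2 = p$diagnostics$r_squared,
      elastic_start = p$diagnostics$elastic_window[1],
      elastic_end = p$diagnostics$elastic_window[2]
    )
  })
  do.call(rbind, rows)
}
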