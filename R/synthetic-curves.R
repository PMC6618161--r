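# Synthetic destructive-test load-displacement curves.
#
# The generator emulates records from a displacement-controlled load frame:
# constant displacement rate (default 0.03 mm/s) sampled at a fixed rate
# (default 20 Hz), so the displacement grid spacing is rate / sample_rate.
# The template curve is piecewise:
#   toe (zero load, pre-contact) -> linear elastic (slope = stiffness) ->
#   linear hardening (slope = hardening_ratio * stiffness) up to max load ->
#   linear decline to fracture load -> single-step drop to ~0.
# Additive i.i.d. Gaussian noise is applied to the load channel only; the
# displacement channel is assumed exact (the actuator is
# displacement-controlled).

#' Parameters of a synthetic load-displacement curve
#'
#' @param stiffness elastic slope, N/mm (> 0).
#' @param yield_load load at the elastic/plastic knee, N (> 0).
#' @param max_load maximum load, N (>= `yield_load`).
#' @param fracture_fraction fracture load as a fraction of `max_load`,
#'   in (0, 1].
#' @param hardening_ratio post-yield slope divided by elastic slope, in
#'   \[0, 0.5\].  When 0, `max_load` must equal `yield_load` and the
#'   post-yield region is a flat plateau.
#' @param noise_sd standard deviation of additive Gaussian load noise, N.
#' @param displacement_rate actuator speed, mm/s.
#' @param sample_rate sampling frequency, Hz.
#' @param toe_len length of the pre-contact zero-load toe, mm.
#' @param plateau_len displacement extent of the flat plateau used when
#'   `hardening_ratio` is 0, mm.
#' @param decline_len displacement extent of the post-peak decline from max
#'   load to fracture load, mm.
#' @return an object of class `curve_params`.
#' @export
curve_params <- function(stiffness = 100, yield_load = 10, max_load = 15,
                         fracture_fraction = 0.8, hardening_ratio = 0.1,
                         noise_sd = 0.05, displacement_rate = 0.03,
                         sample_rate = 20, toe_len = 0.05,
                         plateau_len = 0.2, decline_len = 0.1) {
  check_finite_positive(stiffness, "stiffness")
  check_finite_positive(yield_load, "yield_load")
  check_finite_positive(max_load, "max_load")
  check_field(max_load >= yield_load, "max_load", "must be >= yield_load")
  check_field(is.finite(fracture_fraction) && fracture_fraction > 0 &&
                fracture_fraction <= 1,
              "fracture_fraction", "must be in (0, 1]")
  check_field(is.finite(hardening_ratio) && hardening_ratio >= 0 &&
                hardening_ratio <= 0.5,
              "hardening_ratio", "must be in [0, 0.5]")
  if (hardening_ratio == 0) {
    check_field(isTRUE(all.equal(max_load, yield_load)), "hardening_ratio",
                "0 requires max_load == yield_load (flat plateau)")
  }
  check_finite_positive(noise_sd, "noise_sd", allow_zero = TRUE)
  check_finite_positive(displacement_rate, "displacement_rate")
  check_finite_positive(sample_rate, "sample_rate")
  check_finite_positive(toe_len, "toe_len", allow_zero = TRUE)
  check_finite_positive(plateau_len, "plateau_len")
  check_finite_positive(decline_len, "decline_len")
  structure(
    list(stiffness = stiffness, yield_load = yield_load,
         max_load = max_load, fracture_fraction = fracture_fraction,
         hardening_ratio = hardening_ratio, noise_sd = noise_sd,
         displacement_rate = displacement_rate, sample_rate = sample_rate,
         toe_len = toe_len, plateau_len = plateau_len,
         decline_len = decline_len),
    class = "curve_params"
  )
}

# internal: noiseless template load at displacement d (vectorised)
curve_template <- function(params, d) {
  p <- params
  d_contact <- p$toe_len
  d_yield <- d_contact + p$yield_load / p$stiffness
  if (p$hardening_ratio > 0) {
    d_max <- d_yield + (p$max_load - p$yield_load) /
      (p$hardening_ratio * p$stiffness)
  } else {
    d_max <- d_yield + p$plateau_len
  }
  frac_load <- p$fracture_fraction * p$max_load
  d_frac <- d_max + p$decline_len
  load <- numeric(length(d))
  el <- d > d_contact & d <= d_yield
  load[el] <- p$stiffness * (d[el] - d_contact)
  hd <- d > d_yield & d <= d_max
  load[hd] <- p$yield_load +
    p$hardening_ratio * p$stiffness * (d[hd] - d_yield)
  dc <- d > d_max & d <= d_frac
  if (p$fracture_fraction < 1) {
    load[dc] <- p$max_load - (p$max_load - frac_load) *
      (d[dc] - d_max) / p$decline_len
  } else {
    load[dc] <- p$max_load
  }
  # beyond d_frac the specimen has failed: load ~ 0
  list(load = load, d_contact = d_contact, d_yield = d_yield,
       d_max = d_max, d_frac = d_frac, fracture_load = frac_load)
}

#' Generate a synthetic load-displacement curve
#'
#' Simulates one destructive test record with known ground truth.  The
#' ground truth (the generating `curve_params` plus the template fracture
#' load) is attached as the `"truth"` attribute; no downstream consumer
#' reads hidden state.
#'
#' @param params a [curve_params()] object.
#' @param seed integer seed; fixed seed gives a bit-identical curve.
#' @param tail_samples number of near-zero samples appended after failure.
#' @return a data.frame of class `load_displacement_curve` with columns
#'   `displacement_mm` and `load_N`, attributes `sample_rate`, `test_type`
#'   and `truth`.
#' @export
gen_load_displacement <- function(params, seed = 1L, tail_samples = 5L) {
  stopifnot(inherits(params, "curve_params"))
  p <- params
  step <- p$displacement_rate / p$sample_rate
  tmpl <- curve_template(p, numeric(0))
  d <- seq(0, tmpl$d_frac, by = step)
  tm <- curve_template(p, d)
  load <- tm$load
  # single-step drop: append tail samples at ~0 load
  d <- c(d, tmpl$d_frac + step * seq_len(tail_samples))
  load <- c(load, rep(0, tail_samples))
  if (p$noise_sd > 0) {
    load <- load + with_seed(seed, rnorm(length(load), 0, p$noise_sd))
  }
  out <- data.frame(displacement_mm = d, load_N = load)
  class(out) <- c("load_displacement_curve", "data.frame")
  attr(out, "sample_rate") <- p$sample_rate
  attr(out, "test_type") <- "three_point_bend"
  attr(out, "truth") <- list(
    stiffness = p$stiffness, yield_load = p$yield_load,
    max_load = p$max_load, fracture_load = tmpl$fracture_load,
    d_contact = tmpl$d_contact, d_yield = tmpl$d_yield,
    d_max = tmpl$d_max, params = p
  )
  out
}
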