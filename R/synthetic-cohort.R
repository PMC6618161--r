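# Synthetic wild-type reference cohorts and mutant groups.
#
# Each specimen has a relative BMC (median gray level, arbitrary units)
# drawn Normal(bmc_mean, (bmc_cv * bmc_mean)^2) and four biomechanical
# parameters generated from a linear BMC relationship plus residual noise:
#   param = intercept + slope * BMC + Normal(0, residual_sd^2).
#
# Default marginal CVs follow the phenotyping screen's catalogue:
# BMC 2%, maximum load 9%, fracture load 20%; yield load and stiffness
# CVs are not catalogued and default to 10%.  The share of each
# parameter's variance explained by BMC is set from the printed slope
# significance of the n = 320 reference regressions (p = 0.005, <1e-5,
# 3e-5 and 0.003 for yield, max, fracture, stiffness), which at n = 320
# corresponds to correlations of about 0.16, 0.24, 0.23 and 0.17.

.biomech_params <- c("yield_load", "max_load", "fracture_load", "stiffness")

# correlation implied by a two-sided slope p-value at sample size n
.r_from_p <- function(p, n) {
  t <- qt(1 - p / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}

#' Generating model for a reference cohort
#'
#' Defines the joint distribution of BMC and the four biomechanical
#' parameters.  `means`, `cvs` and `cors` are named vectors over
#' `yield_load`, `max_load`, `fracture_load`, `stiffness`; `cors` gives
#' each parameter's correlation with BMC, from which slope and
#' residual SD are derived:
#' `slope = cor * total_sd / bmc_sd`, `residual_sd = total_sd * sqrt(1 - cor^2)`.
#'
#' @param n number of specimens (>= 3).
#' @param bmc_mean mean relative BMC, gray-level units.
#' @param bmc_cv coefficient of variation of BMC (default 0.02).
#' @param means mean of each biomechanical parameter at the population
#'   level (N, N, N, N/mm).
#' @param cvs marginal coefficient of variation of each parameter.
#' @param cors correlation of each parameter with BMC, in \[0, 1).
#' @param sex cohort sex label (the reference is sex-matched).
#' @param seed integer seed.
#' @return an object of class `cohort_model` carrying derived
#'   slope/intercept/residual_sd per parameter.
#' @export
cohort_model <- function(n = 320,
                         bmc_mean = 100, bmc_cv = 0.02,
                         means = c(yield_load = 10, max_load = 15,
                                   fracture_load = 12, stiffness = 100),
                         cvs = c(yield_load = 0.10, max_load = 0.09,
                                 fracture_load = 0.20, stiffness = 0.10),
                         cors = c(yield_load = .r_from_p(0.005, 320),
                                  max_load = .r_from_p(1e-5, 320),
                                  fracture_load = .r_from_p(3e-5, 320),
                                  stiffness = .r_from_p(0.003, 320)),
                         sex = "F", seed = 1L) {
  check_field(is.numeric(n) && n >= 3, "n", "regression needs >= 3 specimens")
  check_finite_positive(bmc_mean, "bmc_mean")
  check_finite_positive(bmc_cv, "bmc_cv", allow_zero = TRUE)
  for (nm in .biomech_params) {
    check_field(nm %in% names(means), "means", paste("missing", nm))
    check_field(nm %in% names(cvs), "cvs", paste("missing", nm))
    check_field(nm %in% names(cors), "cors", paste("missing", nm))
    check_finite_positive(means[[nm]], paste0("means$", nm))
    check_finite_positive(cvs[[nm]], paste0("cvs$", nm), allow_zero = TRUE)
    check_field(cors[[nm]] >= 0 && cors[[nm]] < 1, paste0("cors$", nm),
                "must be in [0, 1)")
  }
  bmc_sd <- bmc_cv * bmc_mean
  coefs <- lapply(setNames(.biomech_params, .biomech_params), function(nm) {
    total_sd <- cvs[[nm]] * means[[nm]]
    slope <- if (bmc_sd > 0) cors[[nm]] * total_sd / bmc_sd else 0
    list(slope = slope,
         intercept = means[[nm]] - slope * bmc_mean,
         residual_sd = total_sd * sqrt(1 - cors[[nm]]^2))
  })
  structure(
    list(n = as.integer(n), bmc_mean = bmc_mean, bmc_cv = bmc_cv,
         means = means, cvs = cvs, cors = cors, coefs = coefs,
         sex = sex, seed = as.integer(seed)),
    class = "cohort_model"
  )
}

# internal: draw n specimens from the model (no deficit)
.draw_specimens <- function(model, n, seed, genotype) {
  bmc_sd <- model$bmc_cv * model$bmc_mean
  with_seed(seed, {
    bmc <- rnorm(n, model$bmc_mean, bmc_sd)
    out <- data.frame(
      specimen_id = sprintf("%s_%04d", genotype, seq_len(n)),
      genotype = genotype, sex = model$sex, bmc = bmc
    )
    for (nm in .biomech_params) {
      cf <- model$coefs[[nm]]
      out[[nm]] <- cf$intercept + cf$slope * bmc +
        rnorm(n, 0, cf$residual_sd)
    }
    out
  })
}

#' Generate a wild-type reference cohort
#'
#' Draws `model$n` specimens.  The generating coefficients are attached as
#' the `"truth"` attribute.  A degenerate model (zero BMC variance) is
#' flagged in the truth as `degenerate_x = TRUE`: a regression refit on
#' such a cohort is undefined.
#'
#' @param model a [cohort_model()].
#' @return data.frame of class `reference_cohort` with columns
#'   `specimen_id, genotype, sex, bmc, yield_load, max_load,
#'   fracture_load, stiffness`.
#' @export
gen_reference_cohort <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  check_field(model$n >= 3, "n", "regression needs >= 3 specimens")
  out <- .draw_specimens(model, model$n, split_seed(model$seed, 0L), "WT")
  class(out) <- c("reference_cohort", "data.frame")
  attr(out, "truth") <- list(
    coefs = model$coefs, bmc_mean = model$bmc_mean, bmc_cv = model$bmc_cv,
    degenerate_x = model$bmc_cv == 0, model = model
  )
  out
}

#' Generate a mutant group with an injected bone-quality deficit
#'
#' Specimens are drawn from the same BMC-conditional model as the
#' reference, then every biomechanical parameter is shifted by
#' `deficit_sd * residual_sd` of that parameter.  Negative `deficit_sd`
#' means weaker than predicted from BMC — a pure quality deficit that
#' leaves BMC itself untouched.
#'
#' @param model a [cohort_model()].
#' @param deficit_sd deficit in residual-SD units (may be a single number
#'   or a named vector over the four parameters).
#' @param n group size.
#' @param seed integer seed.
#' @param genotype group label.
#' @return data.frame of specimens; `"truth"` attribute records the
#'   injected deficit per parameter.
#' @export
gen_mutant_group <- function(model, deficit_sd, n, seed = 2L,
                             genotype = "MUT") {
  stopifnot(inherits(model, "cohort_model"))
  if (length(deficit_sd) == 1L && is.null(names(deficit_sd))) {
    deficit_sd <- setNames(rep(deficit_sd, 4), .biomech_params)
  }
  check_field(all(.biomech_params %in% names(deficit_sd)), "deficit_sd",
              "must cover all four biomechanical parameters")
  for (nm in .biomech_params) {
    if (model$coefs[[nm]]$residual_sd == 0 && deficit_sd[[nm]] != 0) {
      stop(sprintf(
        "deficit for `%s` undefined: residual_sd is 0", nm), call. = FALSE)
    }
  }
  out <- .draw_specimens(model, n, seed, genotype)
  for (nm in .biomech_params) {
    out[[nm]] <- out[[nm]] + deficit_sd[[nm]] * model$coefs[[nm]]$residual_sd
  }
  attr(out, "truth") <- list(deficit_sd = deficit_sd, coefs = model$coefs,
                             model = model)
  out
}
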