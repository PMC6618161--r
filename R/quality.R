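# Bone quality analysis.
#
# Bone quality is operationalized as the deviation of a group's observed
# biomechanics from the value predicted by its bone mineral content,
# expressed in residual-SD units of a wild-type reference regression:
#
#   score = (observed group mean - predicted at group-mean BMC) / residual_sd
#
# The reference model is a per-parameter ordinary least squares fit of the
# biomechanical parameter on BMC over a large sex-matched WT cohort
# (n = 320 in the motivating screen).  The +/-2 SD band about the
# regression line is constant (parallel band), not a leverage-dependent
# prediction interval.  Scores outside +/-2 SD are flagged as abnormal.

#' Fit the wild-type reference regression model
#'
#' Ordinary least squares of each biomechanical parameter on BMC, with a
#' two-sided t-test p-value for the slope and the residual SD on the
#' n - 2 denominator.
#'
#' @param cohort data.frame with columns `bmc`, `yield_load`, `max_load`,
#'   `fracture_load`, `stiffness`, and optionally `sex`.
#' @param parameters which parameters to fit.
#' @param allow_mixed_sex the reference must be sex-matched; set `TRUE` to
#'   override the refusal to fit a cohort with more than one sex level.
#' @return object of class `reference_model`: per-parameter list of
#'   `slope`, `intercept`, `residual_sd`, `p_value`, `n`; plus `bmc_range`
#'   and `sex`.
#' @export
fit_reference <- function(cohort, parameters = .biomech_params,
                          allow_mixed_sex = FALSE) {
  check_field(is.data.frame(cohort) && "bmc" %in% names(cohort),
              "cohort", "needs a `bmc` column")
  check_field(nrow(cohort) >= 3, "cohort", "regression needs >= 3 specimens")
  check_field(!anyNA(cohort$bmc), "cohort", "missing BMC values")
  if ("sex" %in% names(cohort) && length(unique(cohort$sex)) > 1 &&
      !allow_mixed_sex) {
    stop("mixed-sex cohort: the reference must be sex-matched ",
         "(use allow_mixed_sex = TRUE to override)", call. = FALSE)
  }
  if (stats::var(cohort$bmc) == 0) {
    stop("zero BMC variance: regression on BMC is undefined", call. = FALSE)
  }
  n <- nrow(cohort)
  fits <- lapply(setNames(parameters, parameters), function(nm) {
    check_field(nm %in% names(cohort), "cohort", paste("missing", nm))
    y <- cohort[[nm]]
    check_field(all(is.finite(y)), nm, "non-finite values")
    fit <- lm(y ~ bmc, data = data.frame(bmc = cohort$bmc, y = y))
    res <- stats::residuals(fit)
    rsd <- sqrt(sum(res^2) / (n - 2))
    # exact fits leave only rounding noise in the residuals
    degenerate <- rsd <= 1e-10 * sd(y)
    if (degenerate) rsd <- 0
    sxx <- sum((cohort$bmc - mean(cohort$bmc))^2)
    p <- if (degenerate) NA_real_ else {
      tstat <- coef(fit)["bmc"] / (rsd / sqrt(sxx))
      unname(2 * pt(-abs(tstat), df = n - 2))
    }
    list(slope = unname(coef(fit)["bmc"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         residual_sd = rsd, p_value = p, n = n,
         degenerate = degenerate)
  })
  structure(
    list(parameters = fits,
         bmc_range = range(cohort$bmc),
         sex = if ("sex" %in% names(cohort)) unique(cohort$sex) else NA,
         n = n),
    class = "reference_model"
  )
}

#' Score a mutant group against the reference model
#'
#' @param model a [reference_model][fit_reference] object.
#' @param group data.frame of specimens with `bmc` and the biomechanical
#'   parameter columns.
#' @param flag_sd flag threshold in SD units (default 2, the gray-box
#'   band).
#' @return data.frame of class `quality_scores`, one row per parameter:
#'   `parameter, observed, predicted, score, flagged, n`.  Per-specimen
#'   scores are attached as the `"per_specimen"` attribute.
#' @export
quality_score <- function(model, group, flag_sd = 2) {
  stopifnot(inherits(model, "reference_model"))
  check_field(is.data.frame(group) && nrow(group) >= 1, "group",
              "group must be non-empty")
  check_field("bmc" %in% names(group), "group", "needs a `bmc` column")
  rows <- lapply(names(model$parameters), function(nm) {
    fit <- model$parameters[[nm]]
    if (fit$residual_sd == 0) {
      stop(sprintf("score undefined for `%s`: residual_sd is 0", nm),
           call. = FALSE)
    }
    check_field(nm %in% names(group), "group", paste("missing", nm))
    obs <- mean(group[[nm]])
    pred <- fit$intercept + fit$slope * mean(group$bmc)
    score <- (obs - pred) / fit$residual_sd
    data.frame(parameter = nm, observed = obs, predicted = pred,
               score = score, flagged = abs(score) > flag_sd,
               n = nrow(group))
  })
  out <- do.call(rbind, rows)
  per_spec <- lapply(setNames(names(model$parameters),
                              names(model$parameters)), function(nm) {
    fit <- model$parameters[[nm]]
    (group[[nm]] - (fit$intercept + fit$slope * group$bmc)) / fit$residual_sd
  })
  class(out) <- c("quality_scores", "data.frame")
  attr(out, "per_specimen") <- as.data.frame(per_spec)
  attr(out, "flag_sd") <- flag_sd
  out
}

#' Full quality report over several groups
#'
#' Per-group, per-parameter observed/predicted/score/flag table plus the
#' regression-line and +/-2 SD band coordinates for plotting.
#'
#' @param model a [reference_model][fit_reference].
#' @param groups named list of group data.frames (possibly empty).
#' @param band_sd half-width of the plotted band in SD units.
#' @param n_line number of points on the plotted regression line.
#' @return list of class `quality_report` with `scores` (data.frame,
#'   header-only when `groups` is empty) and `band` (per parameter:
#'   `bmc`, `fit`, `lower`, `upper`).
#' @export
quality_report <- function(model, groups = list(), band_sd = 2,
                           n_line = 50) {
  stopifnot(inherits(model, "reference_model"))
  empty <- data.frame(group = character(0), parameter = character(0),
                      observed = numeric(0), predicted = numeric(0),
                      score = numeric(0), flagged = logical(0),
                      n = integer(0))
  scores <- empty
  for (g in names(groups)) {
    qs <- quality_score(model, groups[[g]], flag_sd = band_sd)
    qs <- cbind(group = g, as.data.frame(qs))
    scores <- rbind(scores, qs)
  }
  bmc_grid <- seq(model$bmc_range[1], model$bmc_range[2],
                  length.out = n_line)
  band <- lapply(model$parameters, function(fit) {
    line <- fit$intercept + fit$slope * bmc_grid
    data.frame(bmc = bmc_grid, fit = line,
               lower = line - band_sd * fit$residual_sd,
               upper = line + band_sd * fit$residual_sd)
  })
  structure(list(scores = scores, band = band, band_sd = band_sd),
            class = "quality_report")
}

#' Serialize a reference model to JSON
#'
#' @param model a [reference_model][fit_reference].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_reference_model <- function(model, path) {
  payload <- list(
    parameters = model$parameters,
    bmc_range = model$bmc_range,
    sex = model$sex, n = model$n
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a reference model from JSON
#'
#' @param path file written by [write_reference_model()].
#' @return a `reference_model`.
#' @export
read_reference_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(x$parameters, function(f) {
    f$p_value <- if (is.null(f$p_value)) NA_real_ else f$p_value
    f
  })
  structure(
    list(parameters = fits, bmc_range = as.numeric(x$bmc_range),
         sex = x$sex, n = x$n),
    class = "reference_model"
  )
}
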