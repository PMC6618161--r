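# Umbrella pipeline: simulate -> biomech -> densitometry -> distcompare ->
# quality -> histomorph -> stats, driven by one validated config, writing
# one bundle directory with per-stage outputs and a provenance log.

# schema: defaults double as the list of known keys (recursively)
.default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    simulate = list(
      n_reference = 320, n_group = 100,
      deficits = list(het = -1.0, hom = -2.5),
      n_curves = 20,
      curve_noise_sd = 0.05,
      gray_shift_fraction = -0.05,
      histomorph_jitter = 0.05
    ),
    biomech = list(
      contact_fraction = 0.01, min_window_fraction = 0.10,
      r2_min = 0.995, r2_relax = 2, yield_offset_fraction = 0.02,
      fracture_drop_fraction = 0.30, smooth_window = 0
    ),
    densitometry = list(n_bins_bmc = 16, n_bins_qbse = 8),
    ks = list(alpha_levels = c(0.05, 0.01, 0.001)),
    quality = list(flag_sd = 2),
    histomorph = list(label_interval_days = 2),
    stats = list(cv = 0.10, diff = 0.20, alpha = 0.05, power = 0.90)
  )
}

# recursive merge of user config into defaults; unknown keys rejected
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key", if (length(unknown) > 1) "s" else "", ": ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected by name; omitted keys take the documented
#' module defaults.
#'
#' @param config named list of overrides, or a path to a JSON config file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out <- .merge_config(.default_config(), config)
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the full pipeline on synthetic data
#'
#' Generates every input from the configured seed, runs all analysis
#' stages, and writes a bundle directory: per-stage CSV/JSON outputs, a
#' run log (seed, config hash, package version), and a JSON summary.  Any
#' stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or overrides list / JSON path).
#' @param out_dir bundle directory (created if needed).
#' @return (invisibly) a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  chash <- config_hash(unclass(config))
  stamp <- list(seed = seed, config_hash = chash,
                package_version = as.character(packageVersion("skelphen")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate + biomech ---------------------------------------------
  bio <- stage("biomech", {
    cfg <- do.call(biomech_config, config$biomech)
    sim <- config$simulate
    curves <- lapply(seq_len(sim$n_curves), function(i) {
      gen_load_displacement(
        curve_params(noise_sd = sim$curve_noise_sd),
        seed = split_seed(seed, 100L + i))
    })
    names(curves) <- sprintf("curve_%03d", seq_along(curves))
    rep <- biomech_report(curves, cfg)
    write.csv(cbind(rep, config_hash = chash, seed = seed),
              file.path(out_dir, "biomech.csv"), row.names = FALSE)
    list(report = rep, curves = curves)
  })

  # --- quality ---------------------------------------------------------
  qual <- stage("quality", {
    sim <- config$simulate
    model <- cohort_model(n = sim$n_reference, seed = split_seed(seed, 1L))
    cohort <- gen_reference_cohort(model)
    ref <- fit_reference(cohort)
    groups <- lapply(seq_along(sim$deficits), function(i) {
      gen_mutant_group(model, sim$deficits[[i]], n = sim$n_group,
                       seed = split_seed(seed, 10L + i),
                       genotype = names(sim$deficits)[i])
    })
    names(groups) <- names(sim$deficits)
    rep <- quality_report(ref, groups, band_sd = config$quality$flag_sd)
    write.csv(cbind(rep$scores, config_hash = chash, seed = seed),
              file.path(out_dir, "quality_scores.csv"), row.names = FALSE)
    write_reference_model(ref, file.path(out_dir, "reference_model.json"))
    list(model = model, reference = ref, report = rep)
  })

  # --- densitometry + distcompare -------------------------------------
  dens <- stage("densitometry", {
    sim <- config$simulate
    f_wt <- gen_gray_field(seed = split_seed(seed, 20L))
    mu <- f_wt$truth$bone_density_mean * (1 + sim$gray_shift_fraction)
    f_mut <- gen_gray_field(bone_density_mean = mu,
                            seed = split_seed(seed, 21L))
    map <- calibrate_gray(f_wt)
    h_wt <- qbse_histogram(f_wt, map = map,
                           n_bins = config$densitometry$n_bins_qbse)
    h_mut <- qbse_histogram(f_mut, map = calibrate_gray(f_mut),
                            n_bins = config$densitometry$n_bins_qbse)
    ks <- ks_two_sample_percent(h_wt, h_mut,
                                alpha_levels = config$ks$alpha_levels)
    write_histogram_csv(h_wt, file.path(out_dir, "qbse_wt.csv"))
    write_histogram_csv(h_mut, file.path(out_dir, "qbse_mut.csv"))
    jsonlite::write_json(
      c(list(D_percent = ks$D_percent, n1 = ks$n1, n2 = ks$n2,
             crossed_levels = ks$crossed_levels), stamp),
      file.path(out_dir, "ks.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    list(map = map, ks = ks)
  })

  # --- histomorph ------------------------------------------------------
  hist <- stage("histomorph", {
    sim <- config$simulate
    tabs <- gen_histomorph_tables(
      histomorph_config(jitter = sim$histomorph_jitter,
                        label_interval_days =
                          config$histomorph$label_interval_days),
      seed = split_seed(seed, 30L))
    rec <- histomorph_record(tabs$segments,
                             label_interval_days = tabs$label_interval_days)
    res <- list(osteoclast = osteoclast_params(rec),
                dynamic = dynamic_formation(rec),
                osteoid = osteoid_params(rec),
                eroded_percent = resorption_fraction(rec),
                growth_plate = growth_plate_heights(tabs$growth_plate))
    jsonlite::write_json(c(res, stamp),
                         file.path(out_dir, "histomorph.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res
  })

  # --- stats -----------------------------------------------------------
  st <- stage("stats", {
    ps <- power_sample_size(cv = config$stats$cv, diff = config$stats$diff,
                            alpha = config$stats$alpha,
                            power = config$stats$power)
    jsonlite::write_json(c(ps, stamp), file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ps
  })

  summary <- list(
    stamp = stamp,
    quality_scores = qual$report$scores[, c("group", "parameter", "score",
                                            "flagged")],
    ks_D_percent = dens$ks$D_percent,
    biomech_median = vapply(
      bio$report[, c("yield_load", "max_load", "fracture_load",
                     "stiffness")], median, numeric(1)),
    power_n = st$n
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(stamp, list(config = unclass(config))),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(biomech = bio$report, quality = qual$report,
                 densitometry = dens, histomorph = hist, stats = st,
                 summary = summary, out_dir = out_dir))
}
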