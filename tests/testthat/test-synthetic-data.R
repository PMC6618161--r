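# Synthetic-data generators: ground truth is stored with the artifact and
# noiseless configurations round-trip exactly.

test_that("gen_load_displacement builds the stated piecewise template", {
  # noiseless: elastic slope equals stiffness exactly
  cv <- gen_load_displacement(curve_params(noise_sd = 0), seed = 1)
  tr <- attr(cv, "truth")
  el <- cv$displacement_mm > tr$d_contact & cv$displacement_mm <= tr$d_yield
  slopes <- diff(cv$load_N[el]) / diff(cv$displacement_mm[el])
  expect_equal(slopes, rep(100, sum(el) - 1), tolerance = 1e-9)
  # displacement grid spacing = rate / sample_rate
  expect_equal(unique(round(diff(cv$displacement_mm), 12)), 0.03 / 20)

  # degenerate plateau: fracture_fraction = 1, hardening 0
  pl <- gen_load_displacement(
    curve_params(yield_load = 15, max_load = 15, hardening_ratio = 0,
                 fracture_fraction = 1, noise_sd = 0), seed = 1)
  trp <- attr(pl, "truth")
  plateau <- pl$load_N[pl$displacement_mm > trp$d_yield &
                         pl$displacement_mm <= trp$d_max]
  expect_true(all(plateau == 15))
  expect_equal(trp$fracture_load, trp$max_load)

  # determinism
  expect_identical(gen_load_displacement(curve_params(), seed = 7),
                   gen_load_displacement(curve_params(), seed = 7))
})

test_that("curve noise has the configured sd against the known template", {
  p <- curve_params(noise_sd = 0.1)
  noisy <- gen_load_displacement(p, seed = 11)
  clean <- gen_load_displacement(curve_params(noise_sd = 0), seed = 11)
  resid <- noisy$load_N - clean$load_N
  expect_gt(length(resid), 500)
  expect_lt(abs(sd(resid) - 0.1) / 0.1, 0.15)
})

test_that("curve parameter validation names the offending field", {
  expect_error(curve_params(stiffness = -1), "stiffness")
  expect_error(curve_params(noise_sd = NaN), "noise_sd")
  expect_error(curve_params(fracture_fraction = 0), "fracture_fraction")
  expect_error(curve_params(yield_load = 20, max_load = 10), "max_load")
  expect_error(curve_params(hardening_ratio = 0), "hardening_ratio")
})

test_that("reference cohort generation recovers its own coefficients", {
  # noiseless line: OLS refit recovers slope/intercept to >= 6 sig digits
  m <- cohort_model(cvs = c(yield_load = 0.10, max_load = 0.09,
                            fracture_load = 0.20, stiffness = 0.10),
                    cors = c(yield_load = 0.999, max_load = 0.999,
                             fracture_load = 0.999, stiffness = 0.999),
                    seed = 3)
  # make residual_sd exactly 0 by pushing cor to 1 manually
  for (nm in names(m$coefs)) m$coefs[[nm]]$residual_sd <- 0
  coh <- gen_reference_cohort(m)
  fit <- lm(max_load ~ bmc, data = coh)
  expect_equal(unname(coef(fit)), c(m$coefs$max_load$intercept,
                                    m$coefs$max_load$slope),
               tolerance = 1e-7)

  # degenerate x flagged
  m0 <- cohort_model(bmc_cv = 0, seed = 1)
  coh0 <- gen_reference_cohort(m0)
  expect_true(attr(coh0, "truth")$degenerate_x)
  expect_equal(var(coh0$bmc), 0)

  expect_error(cohort_model(n = 2), "n")
})

test_that("configured marginal CVs are reproduced over seeds", {
  # Monte-Carlo over 200 seeds: mean empirical max-load CV within 0.5 pp
  # of the configured 9%
  cvs <- vapply(1:200, function(s) {
    coh <- gen_reference_cohort(cohort_model(seed = s))
    sd(coh$max_load) / mean(coh$max_load)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.09), 0.005)
  # BMC CV target 2%
  coh <- gen_reference_cohort(cohort_model(seed = 9))
  expect_lt(abs(sd(coh$bmc) / mean(coh$bmc) - 0.02), 0.005)
})

test_that("mutant groups carry the injected deficit", {
  m <- cohort_model(seed = 5)
  g0 <- gen_mutant_group(m, 0, n = 50, seed = 1)
  expect_equal(attr(g0, "truth")$deficit_sd,
               setNames(rep(0, 4), c("yield_load", "max_load",
                                     "fracture_load", "stiffness")))
  # sign propagation: all four shifted parameters drop
  gneg <- gen_mutant_group(m, -2.5, n = 200, seed = 1)
  gref <- gen_mutant_group(m, 0, n = 200, seed = 1)
  for (nm in c("yield_load", "max_load", "fracture_load", "stiffness")) {
    expect_equal(gneg[[nm]] - gref[[nm]],
                 rep(-2.5 * m$coefs[[nm]]$residual_sd, 200))
  }
  # zero residual sd + nonzero deficit is undefined
  m0 <- m
  m0$coefs$max_load$residual_sd <- 0
  expect_error(gen_mutant_group(m0, -1, n = 10), "residual_sd")
})

test_that("gray fields respect masks, bit depth and determinism", {
  f <- gen_gray_field(noise_sd_gray = 30, seed = 4)
  # standard regions and bone mask disjoint
  reg_mask <- matrix(FALSE, nrow(f$pixels), ncol(f$pixels))
  for (i in seq_len(nrow(f$standard_regions))) {
    r <- f$standard_regions[i, ]
    reg_mask[(r$row0 + 1):r$row1, (r$col0 + 1):r$col1] <- TRUE
  }
  expect_false(any(reg_mask & f$bone_mask))
  expect_true(all(f$pixels >= 0 & f$pixels <= 2^16 - 1))
  # bit-identical rasters for identical seeds
  f2 <- gen_gray_field(noise_sd_gray = 30, seed = 4)
  expect_identical(f$pixels, f2$pixels)
  expect_error(gen_gray_field(standards = data.frame(name = "a",
                                                     density = 1)),
               "two standards")
})

test_that("histomorph tables round-trip their configured truth", {
  cfg <- histomorph_config(jitter = 0)
  tabs <- gen_histomorph_tables(cfg, seed = 1)
  rec <- histomorph_record(tabs$segments, tabs$label_interval_days)
  expect_equal(rec$b_pm_mm, 10)
  expect_equal(osteoclast_params(rec)$Oc.S_per_B.Pm, 12)
  gp <- growth_plate_heights(tabs$growth_plate)
  expect_equal(unname(gp$heights_um["HZ"]), 50)
  # MAR estimate from many jittered label measurements within 5%
  cfgj <- histomorph_config(jitter = 0.15, n_label_measurements = 500)
  tj <- gen_histomorph_tables(cfgj, seed = 2)
  rj <- histomorph_record(tj$segments, tj$label_interval_days)
  mar <- dynamic_formation(rj)$MAR_um_day
  expect_lt(abs(mar - 4 / 2) / 2, 0.05)
  expect_error(histomorph_config(oc_coverage = 1.2), "oc_coverage")
})

test_that("seed splitting is deterministic and in integer range", {
  expect_identical(split_seed(1, 3), split_seed(1, 3))
  expect_false(split_seed(1, 1) == split_seed(1, 2))
  ss <- vapply(0:50, function(k) split_seed(123456789, k), integer(1))
  expect_true(all(ss >= 1 & ss <= 2^31 - 2))
})
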