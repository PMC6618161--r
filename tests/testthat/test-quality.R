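# Bone-quality reference regression and residual-SD scoring.

test_that("fit_reference handles exact and degenerate fits", {
  # 3 collinear points: residual_sd = 0, degenerate p flag
  coh <- data.frame(bmc = c(1, 2, 3), yield_load = c(2, 4, 6),
                    max_load = c(3, 5, 7), fracture_load = c(1, 2, 3),
                    stiffness = c(10, 20, 30))
  m <- fit_reference(coh)
  expect_equal(m$parameters$max_load$residual_sd, 0)
  expect_true(m$parameters$max_load$degenerate)
  expect_true(is.na(m$parameters$max_load$p_value))
  # zero BMC variance and tiny cohorts are rejected
  expect_error(fit_reference(data.frame(bmc = rep(1, 5), yield_load = 1:5,
                                        max_load = 1:5,
                                        fracture_load = 1:5,
                                        stiffness = 1:5)),
               "zero BMC variance")
  expect_error(fit_reference(coh[1:2, ]), ">= 3")
})

test_that("coefficients are recovered within 3 SE on a synthetic cohort", {
  model <- cohort_model(seed = 21)
  coh <- gen_reference_cohort(model)
  fit <- fit_reference(coh)
  for (nm in names(fit$parameters)) {
    f <- fit$parameters[[nm]]
    truth <- model$coefs[[nm]]
    se_slope <- f$residual_sd / sqrt(sum((coh$bmc - mean(coh$bmc))^2))
    expect_lt(abs(f$slope - truth$slope), 3 * se_slope)
    expect_lt(abs(f$residual_sd - truth$residual_sd) / truth$residual_sd,
              0.15)
  }
})

test_that("slope test has nominal type-I error under the null", {
  # slope 0: p < 0.05 in about 5% of seeds (+/- 2 pp); 2000 seeds keep
  # the Monte-Carlo error of the rate itself well inside the band
  model <- cohort_model(cors = c(yield_load = 0, max_load = 0,
                                 fracture_load = 0, stiffness = 0))
  rej <- vapply(1:2000, function(s) {
    m <- model; m$seed <- s
    coh <- gen_reference_cohort(m)
    fit_reference(coh)$parameters$max_load$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("quality_score is exact on the line and flags per the 2SD band", {
  coh <- gen_reference_cohort(cohort_model(seed = 2))
  m <- fit_reference(coh)
  # group lying exactly on each regression line scores 0
  bmc <- c(95, 100, 105)
  grp <- data.frame(bmc = bmc)
  for (nm in names(m$parameters)) {
    f <- m$parameters[[nm]]
    grp[[nm]] <- f$intercept + f$slope * bmc
  }
  qs <- quality_score(m, grp)
  expect_equal(qs$score, rep(0, 4), tolerance = 1e-12)
  expect_false(any(qs$flagged))
  # flag logic: score magnitude just over/under 2
  grp2 <- grp
  for (nm in names(m$parameters)) {
    grp2[[nm]] <- grp[[nm]] - 2.1 * m$parameters[[nm]]$residual_sd
  }
  expect_true(all(quality_score(m, grp2)$flagged))
  expect_error(quality_score(m, grp[0, ]), "non-empty")
})

test_that("scores are invariant to affine transforms of the parameter axis", {
  model <- cohort_model(seed = 13)
  coh <- gen_reference_cohort(model)
  grp <- gen_mutant_group(model, -1.5, n = 40, seed = 3)
  s1 <- quality_score(fit_reference(coh), grp)$score
  # transform max_load axis: y -> a*y + b everywhere
  a <- 3.7; b <- -12
  coh2 <- coh; grp2 <- grp
  coh2$max_load <- a * coh2$max_load + b
  grp2$max_load <- a * grp2$max_load + b
  s2 <- quality_score(fit_reference(coh2), grp2)$score
  expect_equal(s2[2], s1[2], tolerance = 1e-9)
})

test_that("mixed-sex cohorts are refused unless overridden", {
  coh <- gen_reference_cohort(cohort_model(seed = 4))
  coh$sex[1:100] <- "M"
  expect_error(fit_reference(coh), "sex-matched")
  expect_s3_class(fit_reference(coh, allow_mixed_sex = TRUE),
                  "reference_model")
})

test_that("quality_report structure and serialization round-trip", {
  model <- cohort_model(seed = 31)
  coh <- gen_reference_cohort(model)
  m <- fit_reference(coh)
  # empty group list: header-only report
  r0 <- quality_report(m, list())
  expect_equal(nrow(r0$scores), 0)
  expect_named(r0$band, c("yield_load", "max_load", "fracture_load",
                          "stiffness"))
  # two groups: two rows per parameter, ordered as input
  het <- gen_mutant_group(model, -1, n = 30, seed = 1, genotype = "het")
  hom <- gen_mutant_group(model, -2.5, n = 30, seed = 2, genotype = "hom")
  r2 <- quality_report(m, list(het = het, hom = hom))
  expect_equal(nrow(r2$scores), 8)
  expect_equal(unique(r2$scores$group), c("het", "hom"))
  # model JSON round-trip regenerates an identical report
  tf <- tempfile(fileext = ".json")
  write_reference_model(m, tf)
  m2 <- read_reference_model(tf)
  r3 <- quality_report(m2, list(het = het, hom = hom))
  expect_equal(r3$scores$score, r2$scores$score)
  expect_equal(r3$band, r2$band)
})
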