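# ddCT expression, group comparisons, CV-based power.

make_ct <- function(n_per = 3, genes = c("Tubulin", "GusB", "Tgt1", "Tgt2"),
                    seed = 1) {
  with_seed(seed, {
    samples <- paste0("s", seq_len(2 * n_per))
    grid <- expand.grid(sample = samples, gene = genes,
                        stringsAsFactors = FALSE)
    grid$group <- ifelse(grid$sample %in% samples[seq_len(n_per)],
                         "wt", "mut")
    grid$ct <- runif(nrow(grid), 18, 30)
    grid[, c("sample", "group", "gene", "ct")]
  })
}

test_that("ddct closed form: calibrator folds to 1, +1/-2 shifts", {
  ct <- data.frame(
    sample = rep(c("w1", "m1", "m2"), each = 2),
    group = rep(c("wt", "mutA", "mutB"), each = 2),
    gene = rep(c("Ref", "Tgt"), 3),
    ct = c(20, 25,   # calibrator: dct 5
           20, 26,   # ddct +1 -> fold 0.5
           20, 23))  # ddct -2 -> fold 4
  res <- ddct_expression(ct, "Ref", "wt")
  expect_equal(res$fold[res$sample == "w1"], 1)
  expect_equal(res$fold[res$sample == "m1"], 0.5)
  expect_equal(res$fold[res$sample == "m2"], 4)
  expect_error(ddct_expression(ct, "Nope", "wt"), "absent")
})

test_that("ddct agrees with an independent wide-matrix recomputation", {
  refs <- c("Tubulin", "GusB")
  for (seed in 1:5) {
    ct <- make_ct(seed = seed)
    res <- ddct_expression(ct, refs, "wt")
    # independent oracle: reshape wide and recompute from first principles
    wide <- reshape(ct, idvar = c("sample", "group"), timevar = "gene",
                    direction = "wide")
    ref_ct <- rowMeans(wide[, paste0("ct.", refs)])
    for (g in c("Tgt1", "Tgt2")) {
      dct <- wide[[paste0("ct.", g)]] - ref_ct
      ddct <- dct - mean(dct[wide$group == "wt"])
      fold <- 2^(-ddct)
      got <- res[res$gene == g, ]
      got <- got[match(wide$sample, got$sample), ]
      expect_equal(got$fold, unname(fold), tolerance = 1e-12)
    }
  }
})

test_that("ddct is invariant to per-sample constant CT offsets", {
  ct <- make_ct(seed = 3)
  res1 <- ddct_expression(ct, c("Tubulin", "GusB"), "wt")
  ct2 <- ct
  # add a different constant to every CT of each sample
  off <- setNames(seq_along(unique(ct$sample)), unique(ct$sample))
  ct2$ct <- ct2$ct + off[ct2$sample]
  res2 <- ddct_expression(ct2, c("Tubulin", "GusB"), "wt")
  expect_equal(res2$fold, res1$fold, tolerance = 1e-12)
})

test_that("group_compare dispatches designs and validates groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  # identical groups: zero difference, t-test p = 1
  expect_equal(group_compare(g, "t_test")$p_value, 1)
  expect_error(group_compare(list(a = 1:3, b = 1:3, c = 1:3), "t_test"),
               "exactly 2 groups")
  expect_error(group_compare(list(a = 1:3), "anova_tukey"), ">= 2 groups")
  # three-group designs return a full pairwise table
  g3 <- with_seed(1, list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10)))
  for (d in c("anova_tukey", "kruskal_dunn")) {
    r <- group_compare(g3, d)
    expect_equal(nrow(r$pairwise), 3)
    expect_lt(r$p_value, 0.01)
    ab <- r$pairwise$p_value[r$pairwise$group1 %in% c("a", "b") &
                               r$pairwise$group2 %in% c("a", "b")]
    expect_lt(ab, 0.05)
  }
})

test_that("well-separated groups are detected with high power", {
  hits <- vapply(1:100, function(s) {
    g <- with_seed(s, list(a = rnorm(20, 0), b = rnorm(20, 3)))
    group_compare(g, "t_test")$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("power_sample_size limits, ordering and monotonicity", {
  # cv -> 0 (huge d): minimum n for the design
  expect_equal(power_sample_size(cv = 1e-6, diff = 0.2)$n, 2)
  # one-sample needs no more animals than two-sample at the same spec
  two <- power_sample_size(cv = 0.10, diff = 0.20)
  one <- power_sample_size(cv = 0.10, diff = 0.20,
                           design = "one_sample_vs_reference")
  expect_lte(one$n, two$n)
  expect_gte(two$achieved_power, 0.90)
  # power non-decreasing in n and d
  pow <- function(n, d) {
    df <- 2 * n - 2; ncp <- d * sqrt(n / 2); crit <- qt(0.975, df)
    pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
  }
  ns <- 2:20
  expect_true(all(diff(vapply(ns, pow, numeric(1), d = 1)) > 0))
  ds <- seq(0.5, 4, by = 0.25)
  expect_true(all(diff(vapply(ds, pow, numeric(1), n = 5)) > 0))
  expect_error(power_sample_size(cv = 0.1, diff = 0), "diff")
})
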