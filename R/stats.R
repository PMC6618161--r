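# Statistics: ddCT expression, group comparisons, CV-based power.

#' Relative expression by the delta-delta-CT method
#'
#' Per sample, `dCT = CT_target - mean(CT of reference genes)`; per target
#' gene, `ddCT = dCT - mean(dCT over calibrator samples)`; fold change is
#' `2^(-ddCT)`.  Multiple reference genes are aggregated by the arithmetic
#' mean of their CTs (equivalent to the geometric mean of expression).
#'
#' @param ct data.frame in long format: `sample`, `group`, `gene`, `ct`.
#' @param reference_genes character vector of reference gene names
#'   (>= 1), e.g. `c("Tubulin", "GusB", "Pinin")`.
#' @param calibrator_group group whose mean dCT anchors fold = 1.
#' @return data.frame `sample, group, gene, dct, ddct, fold` for every
#'   non-reference gene.
#' @export
ddct_expression <- function(ct, reference_genes, calibrator_group) {
  check_field(is.data.frame(ct) &&
                all(c("sample", "group", "gene", "ct") %in% names(ct)),
              "ct", "needs sample, group, gene, ct columns")
  check_field(all(is.finite(ct$ct)), "ct", "CT values must be finite")
  check_field(length(reference_genes) >= 1, "reference_genes",
              "need at least one reference gene")
  missing_ref <- setdiff(reference_genes, ct$gene)
  if (length(missing_ref) > 0) {
    stop("reference gene(s) absent from table: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  check_field(calibrator_group %in% ct$group, "calibrator_group",
              "no samples in calibrator group")
  targets <- setdiff(unique(ct$gene), reference_genes)
  check_field(length(targets) >= 1, "ct", "no target genes in table")

  ref_mean <- vapply(split(ct$ct[ct$gene %in% reference_genes],
                           ct$sample[ct$gene %in% reference_genes]),
                     mean, numeric(1))
  tgt <- ct[ct$gene %in% targets, , drop = FALSE]
  check_field(all(tgt$sample %in% names(ref_mean)), "ct",
              "every sample needs reference-gene CTs")
  tgt$dct <- tgt$ct - ref_mean[as.character(tgt$sample)]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(g) {
    cal <- g$dct[g$group == calibrator_group]
    check_field(length(cal) >= 1, "calibrator_group",
                paste("no calibrator samples for gene", g$gene[1]))
    g$ddct <- g$dct - mean(cal)
    g$fold <- 2^(-g$ddct)
    g
  }))
  rownames(out) <- NULL
  out[, c("sample", "group", "gene", "dct", "ddct", "fold")]
}

#' Group comparison dispatcher
#'
#' Dispatches the comparison named in `design`:
#' * `"t_test"` — unpaired two-sided Student's t (2 groups),
#' * `"wilcoxon"` — two-sided rank-sum (2 groups),
#' * `"anova_tukey"` — one-way ANOVA + two-sided Tukey post hoc,
#' * `"kruskal_dunn"` — Kruskal-Wallis + Dunn all-pairs z-tests.
#'
#' @param values named list of numeric vectors, one per group (>= 2
#'   groups, each >= 2 values).
#' @param design one of the designs above.
#' @param var_equal assume equal variances in the t-test (classical
#'   Student's t; default TRUE).
#' @return list: `design`, `statistic`, `p_value` (omnibus or two-group),
#'   `pairwise` (data.frame `group1, group2, estimate, p_value`; NULL for
#'   two-group designs).
#' @export
group_compare <- function(values,
                          design = c("anova_tukey", "kruskal_dunn",
                                     "t_test", "wilcoxon"),
                          var_equal = TRUE) {
  design <- match.arg(design)
  check_field(is.list(values) && length(values) >= 2 &&
                !is.null(names(values)), "values",
              "need a named list of >= 2 groups")
  check_field(all(vapply(values, length, integer(1)) >= 2), "values",
              "each group needs >= 2 values")
  k <- length(values)
  if (design %in% c("t_test", "wilcoxon") && k != 2) {
    stop(sprintf("design `%s` needs exactly 2 groups, got %d", design, k),
         call. = FALSE)
  }
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  y <- unlist(values, use.names = FALSE)
  switch(design,
    t_test = {
      tt <- t.test(values[[1]], values[[2]], var.equal = var_equal)
      list(design = design, statistic = unname(tt$statistic),
           p_value = tt$p.value, pairwise = NULL)
    },
    wilcoxon = {
      wt <- suppressWarnings(wilcox.test(values[[1]], values[[2]]))
      list(design = design, statistic = unname(wt$statistic),
           p_value = wt$p.value, pairwise = NULL)
    },
    anova_tukey = {
      fit <- aov(y ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$g
      pw <- data.frame(
        group1 = sub("-.*$", "", rownames(tk)),
        group2 = sub("^[^-]*-", "", rownames(tk)),
        estimate = tk[, "diff"], p_value = tk[, "p adj"],
        row.names = NULL)
      list(design = design,
           statistic = summary(fit)[[1]][["F value"]][1],
           p_value = p, pairwise = pw)
    },
    kruskal_dunn = {
      kw <- kruskal.test(y, g)
      # Dunn all-pairs: z-tests on mean ranks with tie correction
      n <- length(y)
      r <- rank(y)
      ties <- table(y)
      tie_c <- sum(ties^3 - ties) / (12 * (n - 1))
      rbar <- tapply(r, g, mean)
      ns <- tapply(r, g, length)
      pairs <- utils::combn(names(values), 2)
      pw <- do.call(rbind, apply(pairs, 2, function(pr) {
        se <- sqrt((n * (n + 1) / 12 - tie_c) *
                     (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
        z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
        data.frame(group1 = pr[1], group2 = pr[2], estimate = z,
                   p_value = 2 * stats::pnorm(-abs(z)))
      }))
      pw$p_value <- pmin(p.adjust(pw$p_value, "holm"), 1)
      list(design = design, statistic = unname(kw$statistic),
           p_value = kw$p.value, pairwise = pw)
    }
  )
}

#' Minimal group size for a target power from a CV and a relative difference
#'
#' Standardized effect `d = diff / cv` (both as fractions of the mean);
#' power is computed from the noncentral-t distribution of the chosen
#' design and the smallest `n` with power >= target is returned.
#'
#' @param cv coefficient of variation of the measurement (fraction).
#' @param diff detectable difference as a fraction of the mean.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param design `"two_sample_t"` (n per group) or
#'   `"one_sample_vs_reference"` (group mean against a fixed reference
#'   value).
#' @param n_max search cap.
#' @return list: `n` (per group), `achieved_power`, `d`, `design`.
#' @export
power_sample_size <- function(cv, diff, alpha = 0.05, power = 0.90,
                              design = c("two_sample_t",
                                         "one_sample_vs_reference"),
                              n_max = 10000L) {
  design <- match.arg(design)
  check_finite_positive(cv, "cv")
  check_finite_positive(diff, "diff")
  check_field(alpha > 0 && alpha < 1, "alpha", "must be in (0, 1)")
  check_field(power > 0 && power < 1, "power", "must be in (0, 1)")
  d <- diff / cv
  if (!is.finite(d) || d <= 0) {
    stop("unattainable: standardized effect d = diff/cv must be > 0",
         call. = FALSE)
  }
  pow_at <- function(n) {
    if (design == "two_sample_t") {
      df <- 2 * n - 2
      ncp <- d * sqrt(n / 2)
    } else {
      df <- n - 1
      ncp <- d * sqrt(n)
    }
    crit <- qt(1 - alpha / 2, df)
    pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
  }
  for (n in 2:n_max) {
    p <- pow_at(n)
    if (p >= power) {
      return(list(n = n, achieved_power = p, d = d, design = design))
    }
  }
  stop("no n <= ", n_max, " reaches the target power", call. = FALSE)
}
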