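# Shared fixtures and independent oracles.

# Hand-built bilinear curve (independent of the generator): zero toe,
# elastic slope k to yield, hardening slope hk to max, linear decline to
# frac, step drop to zero.
make_bilinear_curve <- function(k = 100, yield = 10, max_load = 15,
                                frac = 12, h = 0.1, step = 0.0015,
                                toe = 0.05, decline = 0.1) {
  d_y <- toe + yield / k
  d_m <- d_y + (max_load - yield) / (h * k)
  d_f <- d_m + decline
  d <- seq(0, d_f + 5 * step, by = step)
  load <- ifelse(d <= toe, 0,
          ifelse(d <= d_y, k * (d - toe),
          ifelse(d <= d_m, yield + h * k * (d - d_y),
          ifelse(d <= d_f, max_load - (max_load - frac) * (d - d_m) / decline,
                 0))))
  data.frame(displacement_mm = d, load_N = load)
}

# Brute-force two-sample KS oracle: max ECDF gap over all pooled points.
ks_oracle_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Vectorised Monte-Carlo power of the classical two-sample / one-sample
# t-test at standardized effect d and per-group size n.
mc_t_power <- function(n, d, reps = 1e4, alpha = 0.05,
                       design = "two_sample_t") {
  if (design == "two_sample_t") {
    a <- matrix(rnorm(n * reps, d), n)
    b <- matrix(rnorm(n * reps, 0), n)
    va <- colSums((a - rep(colMeans(a), each = n))^2) / (n - 1)
    vb <- colSums((b - rep(colMeans(b), each = n))^2) / (n - 1)
    sp <- sqrt((va + vb) / 2)
    tstat <- (colMeans(a) - colMeans(b)) / (sp * sqrt(2 / n))
    df <- 2 * n - 2
  } else {
    a <- matrix(rnorm(n * reps, d), n)
    va <- colSums((a - rep(colMeans(a), each = n))^2) / (n - 1)
    tstat <- colMeans(a) / sqrt(va / n)
    df <- n - 1
  }
  mean(abs(tstat) > qt(1 - alpha / 2, df))
}
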