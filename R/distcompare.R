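# Percent-scaled two-sample Kolmogorov-Smirnov comparison.
#
# Mineralization-density distributions are compared with the two-sample
# KS statistic expressed on a percent scale:
#   D% = 100 * sup |ECDF1 - ECDF2|
# with analytic critical values
#   D%_crit = 100 * c(alpha) * sqrt((n1 + n2) / (n1 * n2))
# using the tabulated coefficients c = 1.36 (alpha 0.05), 1.63 (0.01),
# 1.95 (0.001).  At n1 = n2 = 1024 these give the printed thresholds
# 6.01, 7.20 and 8.62.  (The exact asymptotic expression
# sqrt(-ln(alpha/2)/2) gives 1.3581/1.6276/1.9495 and does not reproduce
# all three printed values at two decimals; the tabulated coefficients
# are therefore the canonical ones here.)

.ks_coefficients <- c("0.05" = 1.36, "0.01" = 1.63, "0.001" = 1.95)

#' Analytic two-sample KS critical value on the percent scale
#'
#' @param alpha significance level; one of 0.05, 0.01, 0.001.
#' @param n1,n2 sample sizes (>= 1).
#' @return critical D in percent.
#' @export
ks_critical_percent <- function(alpha, n1, n2) {
  key <- format(alpha, trim = TRUE)
  if (!key %in% names(.ks_coefficients)) {
    stop("unsupported alpha ", alpha, "; supported levels: ",
         paste(names(.ks_coefficients), collapse = ", "), call. = FALSE)
  }
  check_field(n1 >= 1 && n2 >= 1, "n1/n2", "sample sizes must be >= 1")
  100 * .ks_coefficients[[key]] * sqrt((n1 + n2) / (n1 * n2))
}

# internal: D = sup |ECDF1 - ECDF2| via sorted pooled ranks.  Counts are
# kept as integers until one final division, so the result is bit-equal
# to evaluating mean(x <= t) - mean(y <= t) at every pooled unique value
# (a cumsum of 1/n increments would not be, and ties across samples are
# resolved by only evaluating at the end of each tie block).
.ks_D_fast <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  o <- order(pooled)
  cx <- cumsum(o <= n1)            # running count of x-values <= t
  sorted <- pooled[o]
  keep <- c(diff(sorted) != 0, TRUE)
  i <- which(keep)
  max(abs(cx[i] / n1 - (i - cx[i]) / n2))
}

#' Two-sample Kolmogorov-Smirnov statistic in percent
#'
#' Accepts either raw samples or two `density_histogram`s sharing bin
#' edges (then D is the maximum absolute difference of cumulative relative
#' frequencies over the bin edges and n1/n2 are the pixel counts).
#'
#' @param a,b numeric samples (each >= 2 observations) or
#'   `density_histogram` objects with identical `bin_edges`.
#' @param alpha_levels significance levels to check.
#' @return object of class `ks_result`: `D_percent`, `n1`, `n2`,
#'   `critical` (named vector of critical D% per level) and
#'   `crossed_levels` (subset of `alpha_levels` with D > critical).
#' @export
ks_two_sample_percent <- function(a, b,
                                  alpha_levels = c(0.05, 0.01, 0.001)) {
  if (inherits(a, "density_histogram") || inherits(b, "density_histogram")) {
    stopifnot(inherits(a, "density_histogram"),
              inherits(b, "density_histogram"))
    if (length(a$bin_edges) != length(b$bin_edges) ||
        any(a$bin_edges != b$bin_edges)) {
      stop("histograms do not share bin edges; rebin over a common fixed ",
           "range before comparing", call. = FALSE)
    }
    check_field(sum(a$freq > 0) >= 2 && sum(b$freq > 0) >= 2,
                "histograms", "need >= 2 non-empty bins each")
    D <- max(abs(cumsum(a$freq) - cumsum(b$freq)))
    n1 <- a$n_pixels; n2 <- b$n_pixels
  } else {
    check_field(is.numeric(a) && length(a) >= 2, "a", ">= 2 observations")
    check_field(is.numeric(b) && length(b) >= 2, "b", ">= 2 observations")
    D <- .ks_D_fast(a, b)
    n1 <- length(a); n2 <- length(b)
  }
  crit <- vapply(alpha_levels, ks_critical_percent, numeric(1),
                 n1 = n1, n2 = n2)
  names(crit) <- format(alpha_levels, trim = TRUE)
  D_percent <- 100 * D
  structure(
    list(D_percent = D_percent, n1 = n1, n2 = n2, critical = crit,
         crossed_levels = alpha_levels[D_percent > crit]),
    class = "ks_result"
  )
}
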