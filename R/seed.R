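# Deterministic seed handling.
#
# All randomness in the package flows from one user-supplied integer seed.
# Sub-generators receive child seeds derived with a fixed multiplicative
# congruential step so that adding a new sub-generator never perturbs the
# streams of existing ones.  The RNG is pinned to Mersenne-Twister with
# inversion normals, so fixed seeds give bit-identical output across
# platforms and R versions >= 3.6.

#' Derive a child seed from a parent seed
#'
#' Deterministic seed splitting: `split_seed(seed, k)` returns the k-th
#' child stream seed.  Uses a Lehmer step modulo the Mersenne prime
#' 2^31 - 1, so results stay within R's 32-bit integer range.
#'
#' @param seed integer parent seed.
#' @param k non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  x <- (abs(seed) %% m) + 1
  # one Lehmer step per index increment; 48271 is the MINSTD multiplier
  for (i in seq_len(k + 1L)) {
    x <- (x * 48271) %% m
  }
  as.integer(x)
}

#' Evaluate an expression under a fixed, pinned RNG state
#'
#' Sets the RNG to Mersenne-Twister / inversion, seeds it, evaluates
#' `expr`, and restores the caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# internal: fail with the offending field named
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

check_finite_positive <- function(x, field, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  check_field(ok, field,
              if (allow_zero) "must be a finite number >= 0"
              else "must be a finite number > 0")
}
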