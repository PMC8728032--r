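#' @importFrom stats cor cov dist pchisq pf plnorm pnorm qnorm rnorm
#'   rchisq sd shapiro.test var binomial glm
#' @importFrom rlang abort warn inform .data
#' @keywords internal
"_PACKAGE"

# Derive a 32-bit seed from a master seed and a counter.  Two rounds of a
# Lehmer-style congruential mix; all intermediates stay below 2^53 so the
# arithmetic is exact in doubles.  Used everywhere a protocol needs
# per-replication seeds that are individually reproducible.
derive_seed <- function(master, counter) {
  x <- (as.double(master) %% 2147483647) + 1
  y <- as.double(counter) %% 2147483647
  z <- (x * 48271 + y * 16807 + 11) %% 2147483647
  z <- (z * 69621 + 7) %% 2147483647
  as.integer(z)
}

# Evaluate `code` under `seed` (when non-NULL), restoring the caller's RNG
# state afterwards so library code never perturbs the user's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coerce samples-by-variables input (matrix or data frame) to a numeric
# matrix, with the checks shared by every multivariate test.
as_sample_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  }
  if (!is.matrix(x)) {
    x <- matrix(x, ncol = 1)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric matrix (no NA/NaN/Inf).", arg))
  }
  x
}

# (b + 1) / (B + 1) resampling p-value.
resample_pvalue <- function(n_as_extreme, n_resamples) {
  (n_as_extreme + 1) / (n_resamples + 1)
}
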