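# Shared machinery for the multivariate-normality tests: Mahalanobis
# standardization and the Royston normalizing transformation of the
# Shapiro-Wilk W.

# Center x and whiten with S^{-1/2}, S the maximum-likelihood covariance
# (divisor n). Symmetric eigendecomposition; eigenvalues below
# 1e-12 * trace(S) are treated as singular and refused -- the protocol is
# expected to subset genes so that n > p + 1 rather than regularize.
mvn_standardize <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 1) {
    abort(sprintf(
      "Need n > p + 1 to invert the sample covariance (n = %d, p = %d).", n, p
    ))
  }
  xc <- sweep(x, 2, colMeans(x))
  s <- crossprod(xc) / n
  es <- eigen(s, symmetric = TRUE)
  floor_ <- 1e-12 * sum(diag(s))
  if (any(es$values < floor_)) {
    abort("Sample covariance is numerically singular (degenerate variables or n <= p).")
  }
  inv_sqrt <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  inv <- es$vectors %*% (t(es$vectors) / es$values)
  list(z = xc %*% inv_sqrt, centered = xc, s = s, s_inv = inv)
}

# Royston (1992) normalizing transformation: maps a Shapiro-Wilk W computed
# on n observations to an approximately N(0, 1) equivalent deviate.
royston_z <- function(w, n) {
  if (n < 4 || n > 2000) {
    abort("Royston's normalization of Shapiro-Wilk W is valid for 4 <= n <= 2000.")
  }
  if (n <= 11) {
    g <- -2.273 + 0.459 * n
    m <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    s <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    (-log(g - log(1 - w)) - m) / s
  } else {
    ln <- log(n)
    m <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    s <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    (log(1 - w) - m) / s
  }
}

# Shapiro-Wilk W with a clear error for degenerate input.
sw_w <- function(v) {
  if (sd(v) == 0) {
    abort("Degenerate (constant) variable: Shapiro-Wilk W undefined.")
  }
  unname(shapiro.test(v)$statistic)
}

new_mvn_result <- function(method, statistic, p_value, null_method,
                           n_resamples = 0L, components = NULL, n = NA_integer_,
                           p = NA_integer_) {
  structure(
    list(
      method = method, statistic = unname(statistic),
      p_value = unname(p_value), components = components,
      null_method = null_method, n_resamples = as.integer(n_resamples),
      n = as.integer(n), p = as.integer(p)
    ),
    class = c(paste0("mvn_", method), "mvn_test_result")
  )
}

#' @export
print.mvn_test_result <- function(x, ...) {
  cat(sprintf(
    "<mvn_test_result: %s> statistic = %.6g, p = %.4g (%s%s)\n",
    x$method, x$statistic, x$p_value, x$null_method,
    if (x$n_resamples > 0) sprintf(", B = %d", x$n_resamples) else ""
  ))
  if (!is.null(x$components)) {
    cat("  components:", paste(sprintf("%s = %.4g", names(x$components), x$components),
      collapse = ", "
    ), "\n")
  }
  invisible(x)
}
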