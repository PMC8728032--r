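#' Mardia's multivariate skewness and kurtosis test
#'
#' Computes Mardia's moment-based measures on the Mahalanobis-standardized
#' sample: skewness `b1p = n^-2 sum_ij m_ij^3` and kurtosis
#' `b2p = n^-1 sum_i m_ii^2`, with `m_ij = (x_i - xbar)' S^-1 (x_j - xbar)`
#' and S the maximum-likelihood covariance. The skewness statistic
#' `n b1p / 6` is referred to a chi-square with `p(p+1)(p+2)/6` df and the
#' kurtosis deviate `(b2p - p(p+2)) / sqrt(8 p (p+2) / n)` to a two-sided
#' standard normal. Normality is rejected when *either* component is
#' significant, so the reported `p_value` is the minimum of the two; both
#' component p-values are carried in `components`.
#'
#' @param x Samples x variables numeric matrix (or data frame).
#' @param small_sample If `TRUE`, apply the usual small-sample correction
#'   factor to the skewness statistic. Off by default.
#' @return An object of class `mvn_test_result`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' mardia_test(x)
#' @export
mardia_test <- function(x, small_sample = FALSE) {
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  st <- mvn_standardize(x)
  z <- st$z # m_ij = z_i . z_j; accumulate in row blocks to keep memory O(n)
  b1 <- 0
  block <- max(1L, min(n, as.integer(4e7 / n)))
  start <- 1L
  while (start <= n) {
    idx <- start:min(n, start + block - 1L)
    g <- z[idx, , drop = FALSE] %*% t(z)
    b1 <- b1 + sum(g^3)
    start <- start + block
  }
  b1 <- b1 / n^2
  b2 <- sum(rowSums(z^2)^2) / n
  skew_stat <- n * b1 / 6
  if (small_sample) {
    skew_stat <- skew_stat * (p + 1) * (n + 1) * (n + 3) /
      (n * ((n + 1) * (p + 1) - 6))
  }
  df_skew <- p * (p + 1) * (p + 2) / 6
  p_skew <- pchisq(skew_stat, df = df_skew, lower.tail = FALSE)
  z_kurt <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  p_kurt <- 2 * pnorm(-abs(z_kurt))
  new_mvn_result(
    "mardia",
    statistic = min(p_skew, p_kurt), # decision-scale summary; see components
    p_value = min(p_skew, p_kurt),
    null_method = "asymptotic",
    components = c(
      b1p = b1, b2p = b2, skew_stat = skew_stat, kurt_z = z_kurt,
      p_skewness = p_skew, p_kurtosis = p_kurt
    ),
    n = n, p = p
  )
}

# Henze-Zirkler smoothing bandwidth.
hz_beta <- function(n, p) {
  ((n * (2 * p + 1)) / 4)^(1 / (p + 4)) / sqrt(2)
}

hz_statistic <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  st <- mvn_standardize(x)
  z <- st$z
  b <- hz_beta(n, p)
  d2 <- as.matrix(dist(z))^2 # D_ij = squared Mahalanobis distances
  di <- rowSums(z^2) # D_i
  n * (sum(exp(-b^2 * d2 / 2)) / n^2 -
    2 * (1 + b^2)^(-p / 2) * mean(exp(-b^2 * di / (2 * (1 + b^2)))) +
    (1 + 2 * b^2)^(-p / 2))
}

#' Henze-Zirkler test of multivariate normality
#'
#' A weighted L2 distance between the empirical characteristic function of
#' the standardized sample and that of the standard multivariate normal,
#' with the data-driven smoothing bandwidth
#' `beta = (n (2p + 1) / 4)^(1/(p+4)) / sqrt(2)`. The default p-value uses
#' the lognormal approximation of the null distribution; a Monte-Carlo null
#' (fresh standard-normal samples of the same size, valid by affine
#' invariance) is available instead.
#'
#' @inheritParams mardia_test
#' @param null_method `"asymptotic"` (lognormal approximation) or
#'   `"monte_carlo"`.
#' @param n_mc Number of Monte-Carlo null replicates when
#'   `null_method = "monte_carlo"`.
#' @param seed Optional seed for the Monte-Carlo null.
#' @return An object of class `mvn_test_result`.
#' @export
hz_test <- function(x, null_method = c("asymptotic", "monte_carlo"),
                    n_mc = 499, seed = NULL) {
  null_method <- match.arg(null_method)
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  hz <- hz_statistic(x)
  if (null_method == "asymptotic") {
    b <- hz_beta(n, p)
    a <- 1 + 2 * b^2
    wb <- (1 + b^2) * (1 + 3 * b^2)
    mu <- 1 - a^(-p / 2) * (1 + p * b^2 / a + p * (p + 2) * b^4 / (2 * a^2))
    si2 <- 2 * (1 + 4 * b^2)^(-p / 2) +
      2 * a^(-p) * (1 + 2 * p * b^4 / a^2 + 3 * p * (p + 2) * b^8 / (4 * a^4)) -
      4 * wb^(-p / 2) * (1 + 3 * p * b^4 / (2 * wb) + p * (p + 2) * b^8 / (2 * wb^2))
    pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
    psi <- sqrt(log((si2 + mu^2) / mu^2))
    pv <- plnorm(hz, pmu, psi, lower.tail = FALSE)
    new_mvn_result("hz", hz, pv, "asymptotic", n = n, p = p)
  } else {
    null_stats <- with_seed(seed, replicate(n_mc, hz_statistic(matrix(rnorm(n * p), n, p))))
    pv <- resample_pvalue(sum(null_stats >= hz), n_mc)
    new_mvn_result("hz", hz, pv, "monte_carlo", n_resamples = n_mc, n = n, p = p)
  }
}

royston_statistic <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  z <- vapply(seq_len(p), function(j) royston_z(sw_w(x[, j]), n), numeric(1))
  k <- qnorm(pnorm(-z) / 2)^2
  ln <- log(n)
  u <- 0.715
  v <- 0.21364 + 0.015124 * ln^2 - 0.0018034 * ln^3
  l <- 5
  e <- if (p == 1L) {
    1
  } else {
    r <- cor(x)
    cmat <- r^l * (1 - u * (1 - r)^u / v)
    mean_c <- (sum(cmat) - p) / (p^2 - p)
    p / (1 + (p - 1) * mean_c)
  }
  list(h = e * sum(k) / p, e = e)
}

#' Royston's multivariate extension of the Shapiro-Wilk test
#'
#' Computes the Shapiro-Wilk W of every coordinate, maps each to an
#' approximately standard-normal deviate by Royston's normalizing
#' transformation, folds the deviates to chi-square-1-like quantities
#' `k_j = qnorm(pnorm(-z_j)/2)^2`, and refers `H = (e/p) sum k_j` to a
#' chi-square with `e` degrees of freedom. The equivalent degrees of freedom
#' `e` in `[1, p]` shrink from `p` as the average transformed pairwise
#' correlation grows.
#'
#' @inheritParams mardia_test
#' @return An object of class `mvn_test_result` (component `e` carries the
#'   equivalent degrees of freedom).
#' @export
royston_test <- function(x) {
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  mvn_standardize(x) # enforce invertibility precondition
  rs <- royston_statistic(x)
  pv <- pchisq(rs$h, df = rs$e, lower.tail = FALSE)
  new_mvn_result("royston", rs$h, pv, "asymptotic",
    components = c(e = rs$e), n = n, p = p
  )
}

# FA statistic on a standardized sample: minimum Shapiro-Wilk W over the
# projections of the data onto each observation's own direction.
fa_statistic <- function(z) {
  norms <- sqrt(rowSums(z^2))
  keep <- norms > 0
  if (!any(keep)) abort("All standardized observations have zero norm.")
  if (!all(keep)) {
    inform(sprintf("fa_statistic: skipping %d zero-norm direction(s).", sum(!keep)))
  }
  d <- z[keep, , drop = FALSE] / norms[keep]
  proj <- z %*% t(d) # column i = projections onto direction i
  min(vapply(seq_len(ncol(proj)), function(i) sw_w(proj[, i]), numeric(1)))
}

# TN statistic: average Shapiro-Wilk non-normality (1 - W) over the p
# coordinates of the standardized sample.
tn_statistic <- function(z) {
  mean(vapply(seq_len(ncol(z)), function(j) 1 - sw_w(z[, j]), numeric(1)))
}

mc_null_pvalue <- function(stat, null_stats, lower_tail) {
  b <- if (lower_tail) sum(null_stats <= stat) else sum(null_stats >= stat)
  resample_pvalue(b, length(null_stats))
}

#' Monte-Carlo null distributions for affine-invariant MVN statistics
#'
#' The FA, TN and energy statistics are invariant under invertible affine
#' maps of the data, so their null distributions depend only on the sample
#' size `n`, the dimension `p` and the resample count. This helper draws the
#' null once so that repeated tests of same-shaped data (as in the
#' rejection-rate protocol) can share it via the `null_stats` argument of
#' [fa_test()], [tn_test()] and [energy_mvn_test()].
#'
#' @param method `"fa"`, `"tn"` or `"energy"`.
#' @param n,p Sample size and dimension.
#' @param n_mc Number of null replicates.
#' @param seed Optional seed.
#' @return Numeric vector of `n_mc` null statistic values.
#' @export
mvn_null_stats <- function(method = c("fa", "tn", "energy"), n, p, n_mc = 499,
                           seed = NULL) {
  method <- match.arg(method)
  stat_fun <- switch(method,
    fa = function(x) fa_statistic(mvn_standardize(x)$z),
    tn = function(x) tn_statistic(mvn_standardize(x)$z),
    energy = function(x) energy_statistic(mvn_standardize(x)$z)
  )
  with_seed(seed, vapply(
    seq_len(n_mc),
    function(b) stat_fun(matrix(rnorm(n * p), n, p)),
    numeric(1)
  ))
}

#' Fattorini FA projection test of multivariate normality
#'
#' Standardizes the sample, takes each observation's own direction
#' `d_i = z_i / ||z_i||`, projects all standardized points onto it, and
#' computes the univariate Shapiro-Wilk W of each projection. The statistic
#' is the minimum W over directions (small W = evidence against normality).
#' Because the statistic is affine invariant its exact null distribution is
#' obtained by Monte Carlo from standard-normal samples of the same shape.
#'
#' @inheritParams mardia_test
#' @param n_mc Number of Monte-Carlo null samples.
#' @param seed Optional seed for the null draw.
#' @param null_stats Optional precomputed null statistics from
#'   [mvn_null_stats()] (must match `n`, `p`).
#' @return An object of class `mvn_test_result`.
#' @export
fa_test <- function(x, n_mc = 499, seed = NULL, null_stats = NULL) {
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stat <- fa_statistic(mvn_standardize(x)$z)
  if (is.null(null_stats)) {
    null_stats <- mvn_null_stats("fa", n, p, n_mc, seed)
  }
  pv <- mc_null_pvalue(stat, null_stats, lower_tail = TRUE)
  new_mvn_result("fa", stat, pv, "monte_carlo",
    n_resamples = length(null_stats), n = n, p = p
  )
}

#' TN coordinate-wise Shapiro-Wilk test of multivariate normality
#'
#' Standardizes the sample and averages the coordinate-wise Shapiro-Wilk
#' departures: `T = mean_j (1 - W_j)` over the `p` standardized coordinates
#' (large T = evidence against normality). The combination rule is isolated
#' in one internal function so an alternative summary can be swapped in
#' without touching any protocol code. The p-value comes from a Monte-Carlo
#' null under the standard multivariate normal, exact by affine invariance.
#'
#' @inheritParams fa_test
#' @return An object of class `mvn_test_result`.
#' @export
tn_test <- function(x, n_mc = 499, seed = NULL, null_stats = NULL) {
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stat <- tn_statistic(mvn_standardize(x)$z)
  if (is.null(null_stats)) {
    null_stats <- mvn_null_stats("tn", n, p, n_mc, seed)
  }
  pv <- mc_null_pvalue(stat, null_stats, lower_tail = FALSE)
  new_mvn_result("tn", stat, pv, "monte_carlo",
    n_resamples = length(null_stats), n = n, p = p
  )
}

# E||Z - Z'|| for independent standard normals in p dimensions.
expected_norm_zz <- function(p) {
  2 * exp(lgamma((p + 1) / 2) - lgamma(p / 2))
}

# E||a - Z|| for Z ~ N(0, I_p), as a function of lambda = ||a||^2.
# ||a - Z||^2 is noncentral chi-square(p, lambda); its expected square root
# is sqrt(2) Gamma((p+1)/2)/Gamma(p/2) exp(-lambda/2) 1F1((p+1)/2; p/2; lambda/2).
# The Kummer series is summed directly for moderate lambda; for large lambda
# a moment expansion of E sqrt(X) around E X is used (relative error < 1e-4
# in the switchover region).
expected_norm_az <- function(lambda, p) {
  one <- function(lam) {
    if (lam < 160) {
      a <- (p + 1) / 2
      b <- p / 2
      x <- lam / 2
      term <- 1
      s <- 1
      for (k in 1:500) {
        term <- term * (a + k - 1) / (b + k - 1) * x / k
        s <- s + term
        if (term < s * 1e-14) break
      }
      sqrt(2) * exp(lgamma(a) - lgamma(b) - x) * s
    } else {
      mu <- p + lam
      v <- 2 * (p + 2 * lam)
      sqrt(mu) * (1 - v / (8 * mu^2))
    }
  }
  vapply(lambda, one, numeric(1))
}

# Energy (e-distance) goodness-of-fit statistic for a standardized sample.
energy_statistic <- function(z) {
  n <- nrow(z)
  p <- ncol(z)
  e_az <- expected_norm_az(rowSums(z^2), p)
  pair_mean <- sum(dist(z)) * 2 / n^2
  n * (2 * mean(e_az) - expected_norm_zz(p) - pair_mean)
}

#' Energy test of multivariate normality
#'
#' The e-distance between the standardized sample and the standard
#' multivariate normal:
#' `E = n (2/n sum_i E||y_i - Z|| - E||Z - Z'|| - n^-2 sum_ij ||y_i - y_j||)`
#' with `Z, Z'` independent standard normals. The closed forms
#' `E||Z - Z'|| = 2 Gamma((p+1)/2) / Gamma(p/2)` and the confluent
#' hypergeometric expression for `E||a - Z||` are evaluated exactly. The
#' p-value uses a parametric bootstrap: standard-normal samples of the same
#' shape, re-standardized, statistic recomputed (valid by affine
#' invariance).
#'
#' @inheritParams fa_test
#' @param n_boot Number of parametric-bootstrap null samples.
#' @return An object of class `mvn_test_result`.
#' @export
energy_mvn_test <- function(x, n_boot = 499, seed = NULL, null_stats = NULL) {
  x <- as_sample_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stat <- energy_statistic(mvn_standardize(x)$z)
  if (is.null(null_stats)) {
    null_stats <- mvn_null_stats("energy", n, p, n_boot, seed)
  }
  pv <- mc_null_pvalue(stat, null_stats, lower_tail = FALSE)
  new_mvn_result("energy", stat, pv, "parametric_bootstrap",
    n_resamples = length(null_stats), n = n, p = p
  )
}

mvn_methods <- function() c("mardia", "hz", "royston", "fa", "tn", "energy")

#' Run the full battery of six MVN tests
#'
#' Applies Mardia, Henze-Zirkler, Royston, FA, TN and energy tests to one
#' sample, with per-method seeds derived from one master seed. Monte-Carlo
#' nulls for the affine-invariant statistics can be shared across calls via
#' `null_cache` (see [mvn_null_stats()]), which is how the rejection-rate
#' protocol keeps 1000 replications affordable.
#'
#' @inheritParams mardia_test
#' @param methods Subset of `c("mardia", "hz", "royston", "fa", "tn",
#'   "energy")`; default all six, in that order.
#' @param n_mc Resamples for the Monte-Carlo / bootstrap null tests.
#' @param seed Master seed for the resampling nulls.
#' @param null_cache Optional named list with elements `fa`, `tn`, `energy`
#'   of precomputed null statistics.
#' @return An object of class `mvn_battery`: a list of `mvn_test_result`
#'   (or `try-error` for a method that failed), one per method. Use
#'   [generics::tidy()] for a tibble.
#' @examples
#' x <- matrix(rnorm(250), 50, 5)
#' tidy(mvn_battery(x, n_mc = 99, seed = 1))
#' @export
mvn_battery <- function(x, methods = mvn_methods(), n_mc = 499, seed = NULL,
                        null_cache = NULL) {
  methods <- match.arg(methods, mvn_methods(), several.ok = TRUE)
  methods <- mvn_methods()[mvn_methods() %in% methods]
  x <- as_sample_matrix(x)
  run <- function(method, i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    switch(method,
      mardia = mardia_test(x),
      hz = hz_test(x),
      royston = royston_test(x),
      fa = fa_test(x, n_mc = n_mc, seed = s, null_stats = null_cache$fa),
      tn = tn_test(x, n_mc = n_mc, seed = s, null_stats = null_cache$tn),
      energy = energy_mvn_test(x, n_boot = n_mc, seed = s, null_stats = null_cache$energy)
    )
  }
  out <- lapply(seq_along(methods), function(i) {
    tryCatch(run(methods[i], i), error = function(e) {
      structure(list(method = methods[i], message = conditionMessage(e)),
        class = "mvn_test_failure"
      )
    })
  })
  names(out) <- methods
  structure(out, class = "mvn_battery")
}

#' @export
print.mvn_battery <- function(x, ...) {
  for (r in x) {
    if (inherits(r, "mvn_test_failure")) {
      cat(sprintf("<%s> failed: %s\n", r$method, r$message))
    } else {
      print(r)
    }
  }
  invisible(x)
}
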