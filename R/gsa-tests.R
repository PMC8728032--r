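# The eight self-contained functional-class-scoring GSA tests. Each maps a
# two_group_dataset (samples x genes restricted to one gene set) to a
# gsa_test_result.

new_gsa_result <- function(method, statistic, p_value, null_method,
                           n_resamples = 0L, seed = NULL, note = NULL) {
  structure(
    list(
      method = method, statistic = unname(statistic),
      p_value = unname(p_value), null_method = null_method,
      n_resamples = as.integer(n_resamples), seed = seed, note = note
    ),
    class = "gsa_test_result"
  )
}

#' @export
print.gsa_test_result <- function(x, ...) {
  cat(sprintf(
    "<gsa_test_result: %s> statistic = %.6g, p = %.4g (%s%s)\n",
    x$method, x$statistic, x$p_value, x$null_method,
    if (x$n_resamples > 0) sprintf(", B = %d", x$n_resamples) else ""
  ))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Count null statistics at least as extreme as the observed one, with a
# relative tie tolerance: permutations that reproduce the observed labeling
# (or its mirror) regenerate the same statistic through a different
# floating-point path, and must count as ties, not near-misses.
count_ge <- function(null_stats, obs) {
  sum(null_stats >= obs - 1e-10 * (abs(obs) + 1))
}

check_two_group <- function(data) {
  if (!inherits(data, "two_group_dataset")) {
    abort("`data` must be a two_group_dataset (see two_group_dataset(), as_two_group_dataset()).")
  }
  if (nrow(data$x_control) < 1 || nrow(data$x_case) < 1) {
    abort("Both groups must be non-empty.")
  }
  data
}

# n x B matrix of 0/1 group indicators under label permutation, column 1
# never the observed labels (those are handled separately by each test).
permute_labels <- function(y, n_perm) {
  n <- length(y)
  vapply(seq_len(n_perm), function(b) y[sample.int(n)], integer(n))
}

#' Global test for gene-set association
#'
#' Tests for heterogeneity of the random gene effects in a generalized
#' linear model of the binary response on the set's expression: with
#' centered label vector `yc` and gene-centered expression `X` (samples x
#' genes), the score statistic is `Q = yc' X X' yc / m`, `m` the set size.
#' The p-value comes from label permutation, which is exact under the
#' self-contained null of no gene-response association.
#'
#' @param data A [two_group_dataset()] restricted to one gene set.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @return A `gsa_test_result`.
#' @export
global_test <- function(data, n_perm = 999, seed = NULL) {
  data <- check_two_group(data)
  pooled <- pool_two_group(data)
  x <- scale(pooled$x, center = TRUE, scale = FALSE)
  y <- pooled$y
  if (length(unique(y)) < 2) abort("Labels are constant.")
  m <- ncol(x)
  xt <- t(x)
  q_of <- function(yv) sum((xt %*% (yv - mean(yv)))^2) / m
  q_obs <- q_of(y)
  with_seed(seed, {
    perms <- permute_labels(y, n_perm)
    yc <- sweep(perms, 2, colMeans(perms))
    q_null <- colSums((xt %*% yc)^2) / m
    pv <- resample_pvalue(count_ge(q_null, q_obs), n_perm)
    new_gsa_result("global", q_obs, pv, "permutation", n_perm, seed)
  })
}

hotelling_t2 <- function(data, ridge = 0) {
  n1 <- nrow(data$x_control)
  n2 <- nrow(data$x_case)
  p <- ncol(data$x_control)
  d <- colMeans(data$x_control) - colMeans(data$x_case)
  s1 <- if (n1 > 1) cov(data$x_control) else matrix(0, p, p)
  s2 <- if (n2 > 1) cov(data$x_case) else matrix(0, p, p)
  sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  if (ridge > 0) sp <- sp + ridge * mean(diag(sp)) * diag(p)
  sol <- tryCatch(solve(sp, d), error = function(e) NULL)
  if (is.null(sol)) {
    abort("Pooled covariance is singular; use the shrinkage path (shrinkage = TRUE).")
  }
  (n1 * n2 / (n1 + n2)) * sum(d * sol)
}

#' Hotelling's T2 test for a mean-vector difference
#'
#' Compares the case and control mean expression vectors with the pooled
#' covariance: `T2 = (n1 n2 / (n1 + n2)) (xbar1 - xbar2)' Sp^-1 (xbar1 -
#' xbar2)`. When the residual degrees of freedom exceed the set size
#' (`n1 + n2 - 2 > p`) the classical F reference
#' `T2 (n1 + n2 - p - 1) / ((n1 + n2 - 2) p) ~ F(p, n1 + n2 - p - 1)` is
#' used; otherwise (or on request) the pooled covariance is ridge-shrunk
#' toward a scaled identity and the p-value comes from label permutation.
#'
#' @inheritParams global_test
#' @param shrinkage `NULL` (auto: shrink only when the classical path is
#'   unavailable), `TRUE` or `FALSE`.
#' @param ridge Ridge weight, as a fraction of the average pooled variance,
#'   used on the shrinkage path.
#' @return A `gsa_test_result`.
#' @export
hotelling_test <- function(data, shrinkage = NULL, n_perm = 999, seed = NULL,
                           ridge = 0.1) {
  data <- check_two_group(data)
  n1 <- nrow(data$x_control)
  n2 <- nrow(data$x_case)
  p <- ncol(data$x_control)
  classical_ok <- (n1 + n2 - 2) > p
  use_shrink <- isTRUE(shrinkage) || (!classical_ok && is.null(shrinkage))
  if (!classical_ok && isFALSE(shrinkage)) {
    abort("n1 + n2 - 2 <= p: the classical path is unavailable, use shrinkage.")
  }
  if (!use_shrink) {
    t2 <- hotelling_t2(data)
    f_stat <- t2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
    pv <- pf(f_stat, p, n1 + n2 - p - 1, lower.tail = FALSE)
    return(new_gsa_result("hotelling", t2, pv, "analytic_f"))
  }
  t2 <- hotelling_t2(data, ridge = ridge)
  pooled <- pool_two_group(data)
  with_seed(seed, {
    null_stats <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n1 + n2)
      d <- two_group_dataset(
        pooled$x[idx[seq_len(n1)], , drop = FALSE],
        pooled$x[idx[n1 + seq_len(n2)], , drop = FALSE]
      )
      hotelling_t2(d, ridge = ridge)
    }, numeric(1))
    pv <- resample_pvalue(count_ge(null_stats, t2), n_perm)
    new_gsa_result("hotelling", t2, pv, "permutation", n_perm, seed)
  })
}

#' Rotation gene-set test (ROAST)
#'
#' Fits the two-group linear model per gene, moderates the residual
#' variances by empirical-Bayes shrinkage toward a common prior, and
#' summarizes the moderated t statistics (converted to z) over the set by
#' their mean (two-sided; `"msq"` uses the mean square instead). The null
#' distribution is generated by random rotations of the residual space,
#' which preserves the intergenic correlation structure without permuting
#' samples. The rotation machinery is delegated to [limma::roast()] (the
#' standard implementation); the reported statistic is the set's mean
#' moderated z from [limma::eBayes()].
#'
#' @inheritParams global_test
#' @param n_rot Number of random rotations.
#' @param set_stat `"mean"` (directional, two-sided) or `"msq"`.
#' @return A `gsa_test_result` with `null_method = "rotation"`.
#' @export
roast_test <- function(data, n_rot = 999, set_stat = c("mean", "msq"),
                       seed = NULL) {
  set_stat <- match.arg(set_stat)
  data <- check_two_group(data)
  if (nrow(data$x_control) + nrow(data$x_case) - 2 < 2) {
    abort("Need residual degrees of freedom >= 2 for rotation testing.")
  }
  pooled <- pool_two_group(data)
  expr <- t(pooled$x) # genes x samples for the linear model
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  design <- cbind(Intercept = 1, Group = pooled$y)
  fit <- limma::eBayes(limma::lmFit(expr, design))
  if (any(!is.finite(fit$s2.post)) || any(fit$s2.post <= 0)) {
    bad <- rownames(expr)[!is.finite(fit$s2.post) | fit$s2.post <= 0]
    abort(paste0(
      "Zero residual variance after shrinkage for gene(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  z <- limma::zscoreT(fit$t[, "Group"], df = fit$df.total, approx = FALSE)
  stat <- if (set_stat == "mean") mean(z) else mean(z^2)
  res <- with_seed(seed, limma::roast(
    y = expr, index = seq_len(nrow(expr)), design = design, contrast = 2,
    nrot = n_rot, set.statistic = if (set_stat == "mean") "mean" else "msq"
  ))
  row <- if (set_stat == "mean") "UpOrDown" else "Mixed"
  pv <- res$p.value[row, "P.Value"]
  new_gsa_result("roast", stat, pv, "rotation", n_rot, seed)
}

# Rank/|correlation|-weighted per-sample pathway activity score. Isolated so
# that an alternative published weighting can be swapped in without touching
# the test or protocol code.
pscore_score <- function(x) {
  p <- ncol(x)
  if (p < 2) abort("The pathway activity score needs at least 2 genes.")
  ranks <- apply(x, 2, rank)
  cors <- abs(cor(x))
  w <- (rowSums(cors) - 1) / (p - 1) # mean |cor| with the other set genes
  if (sum(w) <= 0) abort("All gene weights are zero; score undefined.")
  as.numeric(ranks %*% w) / sum(w)
}

#' Pathway activity score (P-score) test
#'
#' Builds a per-sample activity score from the set's expression -- each
#' gene's within-cohort ranks weighted by the mean absolute correlation with
#' the other genes in the set -- and tests its association with the binary
#' response by the likelihood-ratio test of the score coefficient in a
#' logistic regression. The score is invariant to monotone transformations
#' of any single gene.
#'
#' @inheritParams global_test
#' @return A `gsa_test_result` with `null_method = "likelihood_ratio"`; the
#'   statistic is the LRT deviance on 1 df. A non-converged fit (perfect
#'   separation) is reported with a note rather than an error.
#' @export
pscore_test <- function(data, seed = NULL) {
  data <- check_two_group(data)
  pooled <- pool_two_group(data)
  score <- pscore_score(pooled$x)
  note <- NULL
  fit <- withCallingHandlers(
    glm(pooled$y ~ score, family = binomial()),
    warning = function(w) {
      note <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  lrt <- fit$null.deviance - fit$deviance
  pv <- pchisq(lrt, df = 1, lower.tail = FALSE)
  new_gsa_result("pscore", lrt, pv, "likelihood_ratio", seed = seed, note = note)
}

# Pooled-variance two-sample t statistics for every gene, for the observed
# labels and (vectorized) for permuted label matrices.
pooled_t_stats <- function(x, ind1, n1, n2) {
  # x: samples x genes; ind1: n x B 0/1 indicator of group 1 membership
  tot <- colSums(x)
  tot2 <- colSums(x^2)
  m1 <- crossprod(x, ind1) / n1 # genes x B
  q1 <- crossprod(x^2, ind1)
  m2 <- (tot - n1 * m1) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (tot2 - q1 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / denom
  tt[denom == 0] <- 0
  tt
}

#' Self-contained GSEA (sum of gene-level t statistics)
#'
#' The self-contained modification of gene-set enrichment analysis for a
#' predetermined set: the set statistic is the sum of the per-gene pooled
#' two-sample t statistics, and significance comes from sample-label
#' permutation (two-sided). Genes with zero variance in both groups
#' contribute t = 0 with a notice.
#'
#' @inheritParams global_test
#' @return A `gsa_test_result`.
#' @export
gsea_test <- function(data, n_perm = 999, seed = NULL) {
  data <- check_two_group(data)
  n1 <- nrow(data$x_control)
  n2 <- nrow(data$x_case)
  if (n1 < 2 || n2 < 2) abort("Both groups need >= 2 samples for t statistics.")
  pooled <- pool_two_group(data)
  obs1 <- matrix(as.numeric(pooled$y == 0), ncol = 1)
  t_obs <- pooled_t_stats(pooled$x, obs1, n1, n2)
  if (any(t_obs == 0) && any(apply(pooled$x, 2, sd) == 0)) {
    inform("gsea_test: zero-variance gene(s) contribute t = 0.")
  }
  t_set <- sum(t_obs)
  with_seed(seed, {
    perms <- permute_labels(pooled$y, n_perm)
    t_null <- colSums(pooled_t_stats(pooled$x, matrix(as.numeric(perms == 0), nrow(perms)), n1, n2))
    pv <- resample_pvalue(count_ge(abs(t_null), abs(t_set)), n_perm)
    new_gsa_result("gsea", t_set, pv, "permutation", n_perm, seed)
  })
}

# N-statistic (two-sample e-distance) from a precomputed pooled distance
# matrix and a 0/1 group-1 indicator; vectorized over indicator columns.
nstat_from_dist <- function(d, ind1) {
  n <- nrow(d)
  n1 <- colSums(ind1)
  n2 <- n - n1
  r <- d %*% ind1
  s11 <- colSums(ind1 * r)
  s1dot <- colSums(r)
  s12 <- s1dot - s11
  s22 <- sum(d) - 2 * s12 - s11
  (n1 * n2 / (n1 + n2)) * (2 * s12 / (n1 * n2) - s11 / n1^2 - s22 / n2^2)
}

#' N-statistic (two-sample energy) test
#'
#' Compares the two groups' multivariate distributions through expected
#' pairwise Euclidean distances:
#' `N = (n1 n2 / (n1 + n2)) (2 mean ||x_i - y_j|| - mean ||x_i - x_i'|| -
#' mean ||y_j - y_j'||)`, which is nonnegative and zero iff the empirical
#' distributions coincide. The p-value comes from label permutation over the
#' precomputed pooled distance matrix.
#'
#' @inheritParams global_test
#' @return A `gsa_test_result`.
#' @export
n_statistic_test <- function(data, n_perm = 999, seed = NULL) {
  data <- check_two_group(data)
  pooled <- pool_two_group(data)
  d <- as.matrix(dist(pooled$x))
  obs <- nstat_from_dist(d, matrix(as.numeric(pooled$y == 0), ncol = 1))
  with_seed(seed, {
    perms <- permute_labels(pooled$y, n_perm)
    null_stats <- nstat_from_dist(d, matrix(as.numeric(perms == 0), nrow(perms)))
    pv <- resample_pvalue(count_ge(null_stats, obs), n_perm)
    new_gsa_result("nstat", obs, pv, "permutation", n_perm, seed)
  })
}

# Kolmogorov-Smirnov running-difference statistic over a fixed ranking;
# vectorized over permuted group-1 indicator columns.
ks_running_stat <- function(ord, ind1, n1, n2) {
  i1 <- ind1[ord, , drop = FALSE]
  c1 <- apply(i1, 2, cumsum)
  steps <- seq_len(nrow(i1))
  c2 <- steps - c1
  apply(abs(c1 / n1 - c2 / n2), 2, max)
}

ks_mst_test <- function(data, mode, method_tag, n_perm, seed) {
  data <- check_two_group(data)
  pooled <- pool_two_group(data)
  n1 <- nrow(data$x_control)
  n2 <- nrow(data$x_case)
  ranks <- mst_hdp_ranks(pooled$x, mode = mode)
  ord <- order(ranks)
  obs <- ks_running_stat(ord, matrix(as.numeric(pooled$y == 0), ncol = 1), n1, n2)
  with_seed(seed, {
    perms <- permute_labels(pooled$y, n_perm)
    null_stats <- ks_running_stat(
      ord, matrix(as.numeric(perms == 0), nrow(perms)), n1, n2
    )
    pv <- resample_pvalue(count_ge(null_stats, obs), n_perm)
    new_gsa_result(method_tag, obs, pv, "permutation", n_perm, seed)
  })
}

#' MST-based multivariate Kolmogorov-Smirnov tests
#'
#' Rank the pooled multivariate samples with [mst_hdp_ranks()] (location
#' ranking from the minimum spanning tree for `ks_mean_test`, radial ranking
#' from the centroid for `ks_var_test`), then compute the running difference
#' between the two groups' cumulative membership along the ranking,
#' `d_i = (#group1 among first i)/n1 - (#group2 among first i)/n2`, and take
#' `D = max_i |d_i|`. Because the ranking is label-independent, labels are
#' permuted over the fixed ranking to obtain the null.
#'
#' @inheritParams global_test
#' @return A `gsa_test_result` with statistic `D` in `[0, 1]`.
#' @export
ks_mean_test <- function(data, n_perm = 999, seed = NULL) {
  ks_mst_test(data, "location", "ks_mean", n_perm, seed)
}

#' @rdname ks_mean_test
#' @export
ks_var_test <- function(data, n_perm = 999, seed = NULL) {
  ks_mst_test(data, "scale", "ks_var", n_perm, seed)
}

gsa_methods <- function() {
  c("global", "hotelling", "roast", "pscore", "gsea", "nstat", "ks_mean", "ks_var")
}

#' Run a battery of GSA tests on one two-group dataset
#'
#' Applies the requested subset of the eight self-contained GSA tests to the
#' same dataset, with per-method seeds derived from one master seed. A
#' method failure is recorded per-method without aborting the battery.
#'
#' @inheritParams global_test
#' @param methods Subset of `c("global", "hotelling", "roast", "pscore",
#'   "gsea", "nstat", "ks_mean", "ks_var")`.
#' @param n_perm Resamples for every permutation/rotation test.
#' @return An object of class `gsa_battery`; use [generics::tidy()] for a
#'   tibble of statistics and p-values.
#' @examples
#' d <- generate_setting("A", delta = 0.5, n_per_group = 20, p = 5, seed = 1)
#' tidy(run_gsa(d, n_perm = 99, seed = 2))
#' @export
run_gsa <- function(data, methods = gsa_methods(), n_perm = 999, seed = NULL) {
  methods <- match.arg(methods, gsa_methods(), several.ok = TRUE)
  methods <- gsa_methods()[gsa_methods() %in% methods]
  data <- check_two_group(data)
  run <- function(method, i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    switch(method,
      global = global_test(data, n_perm = n_perm, seed = s),
      hotelling = hotelling_test(data, n_perm = n_perm, seed = s),
      roast = roast_test(data, n_rot = n_perm, seed = s),
      pscore = pscore_test(data, seed = s),
      gsea = gsea_test(data, n_perm = n_perm, seed = s),
      nstat = n_statistic_test(data, n_perm = n_perm, seed = s),
      ks_mean = ks_mean_test(data, n_perm = n_perm, seed = s),
      ks_var = ks_var_test(data, n_perm = n_perm, seed = s)
    )
  }
  out <- lapply(seq_along(methods), function(i) {
    tryCatch(run(methods[i], i), error = function(e) {
      structure(list(method = methods[i], message = conditionMessage(e)),
        class = "gsa_test_failure"
      )
    })
  })
  names(out) <- methods
  structure(out, class = "gsa_battery")
}

#' @export
print.gsa_battery <- function(x, ...) {
  for (r in x) {
    if (inherits(r, "gsa_test_failure")) {
      cat(sprintf("<%s> failed: %s\n", r$method, r$message))
    } else {
      print(r)
    }
  }
  invisible(x)
}
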