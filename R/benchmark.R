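# The two experimental protocols: the gene-subset rejection-rate study (Q)
# for the MVN tests, and the type-I-error / power simulation grid for the
# GSA tests.

#' Gene-subset size rule
#'
#' The rejection-rate protocol tests random gene subsets rather than whole
#' pathways so that the sample covariance stays invertible: 10 genes when
#' the cohort has more than 30 samples, 5 genes otherwise.
#'
#' @param n_samples Number of samples in the cohort.
#' @return 5L or 10L.
#' @export
subset_size_rule <- function(n_samples) {
  stopifnot(n_samples >= 1)
  if (n_samples > 30) 10L else 5L
}

#' Rejection rate Q of an MVN test over random gene subsets
#'
#' The gene-subset rejection-rate protocol: per replication, draw
#' `subset_size` genes (per [subset_size_rule()]) without replacement from
#' the named gene set, run one MVN test on the samples x subset matrix, and
#' record its p-value. `Q` is the fraction of replications with `p <=
#' alpha`. If the data are multivariate normal, Q sits near `alpha`; values
#' far above it are evidence against normality somewhere in the set.
#' Replications whose covariance is singular are excluded from the
#' denominator and counted in `n_excluded`.
#'
#' Monte-Carlo nulls of the affine-invariant tests are computed once per
#' call and shared across replications (see [mvn_null_stats()]).
#'
#' @param expr An [expression_dataset()].
#' @param set_name Name of a gene set in `expr$gene_sets`, or a character
#'   vector of gene ids.
#' @param test One of `"mardia"`, `"hz"`, `"royston"`, `"fa"`, `"tn"`,
#'   `"energy"`; or a function taking a samples x genes matrix and returning
#'   anything with a `p_value` field (or a bare p-value), for plugging a
#'   custom test into the protocol.
#' @param n_reps Number of replications (the protocol uses 1000).
#' @param alpha Significance level.
#' @param seed Master seed; replication seeds are derived from it.
#' @param n_mc Resamples for Monte-Carlo-null tests.
#' @return A one-row tibble of class `rejection_summary` with columns
#'   `method`, `Q`, `n_reps`, `n_excluded`, `alpha`, `subset_size`, `seed`.
#' @export
q_rejection_rate <- function(expr, set_name, test = mvn_methods(),
                             n_reps = 1000, alpha = 0.05, seed = 1,
                             n_mc = 199) {
  custom <- is.function(test)
  if (!custom) test <- match.arg(test)
  stopifnot(inherits(expr, "expression_dataset"))
  genes <- if (length(set_name) == 1L && set_name %in% names(expr$gene_sets)) {
    expr$gene_sets[[set_name]]
  } else {
    as.character(set_name)
  }
  genes <- intersect(genes, expr$gene_ids)
  n_samples <- length(expr$sample_ids)
  size <- subset_size_rule(n_samples)
  if (length(genes) < size) {
    abort(sprintf(
      "Gene set resolves to %d gene(s); the protocol needs at least the subset size %d.",
      length(genes), size
    ))
  }
  if (n_samples <= size + 1) {
    abort(sprintf(
      "Need more than subset_size + 1 = %d samples (have %d).", size + 1, n_samples
    ))
  }
  cache <- if (!custom && test %in% c("fa", "tn", "energy")) {
    mvn_null_stats(test, n_samples, size, n_mc, seed = derive_seed(seed, 0))
  } else {
    NULL
  }
  xall <- t(expr$matrix[genes, , drop = FALSE])
  pvals <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    s <- derive_seed(seed, i)
    cols <- with_seed(s, sample.int(length(genes), size))
    x <- xall[, cols, drop = FALSE]
    res <- tryCatch(
      if (custom) {
        r <- test(x)
        if (is.list(r)) r$p_value else as.numeric(r)
      } else {
        switch(test,
          mardia = mardia_test(x),
          hz = hz_test(x),
          royston = royston_test(x),
          fa = fa_test(x, n_mc = n_mc, null_stats = cache),
          tn = tn_test(x, n_mc = n_mc, null_stats = cache),
          energy = energy_mvn_test(x, n_boot = n_mc, null_stats = cache)
        )$p_value
      },
      error = function(e) NULL
    )
    if (!is.null(res)) pvals[i] <- res
  }
  valid <- !is.na(pvals)
  out <- tibble::tibble(
    method = if (custom) "custom" else test,
    Q = sum(pvals[valid] <= alpha) / sum(valid),
    n_reps = as.integer(n_reps),
    n_excluded = as.integer(sum(!valid)),
    alpha = alpha,
    subset_size = size,
    seed = as.integer(seed)
  )
  class(out) <- c("rejection_summary", class(out))
  out
}

#' Null calibration of the MVN tests
#'
#' Draws `n_reps` independent standard multivariate normal samples and
#' records each requested test's rejection rate at `alpha`. Under this null
#' every rate should sit near `alpha` (the p-values are uniform). The
#' Monte-Carlo tests share one null reference sample of `n_mc` statistics
#' per method; `n_mc` defaults high (9999) because the shared reference
#' contributes a *common* error of standard deviation
#' `sqrt(alpha (1 - alpha) / n_mc)` to every replication's rejection
#' decision -- with a small shared reference the replications would be
#' correlated and the usual binomial bands around `alpha` would not apply.
#'
#' @param methods Subset of the six MVN test names.
#' @param n_reps Replications.
#' @param n,p Sample size and dimension of each draw.
#' @param alpha Significance level.
#' @param n_mc Size of the shared null reference for Monte-Carlo-null tests.
#' @param seed Master seed.
#' @return A tibble with columns `method`, `Q`, `n_reps`, `alpha`, `n`, `p`.
#' @export
mvn_calibration <- function(methods = mvn_methods(), n_reps = 1000, n = 50,
                            p = 10, alpha = 0.05, n_mc = 9999, seed = 1) {
  methods <- match.arg(methods, mvn_methods(), several.ok = TRUE)
  methods <- mvn_methods()[mvn_methods() %in% methods]
  cache <- list()
  for (m in intersect(methods, c("fa", "tn", "energy"))) {
    cache[[m]] <- mvn_null_stats(m, n, p, n_mc, seed = derive_seed(seed, match(m, mvn_methods())))
  }
  rej <- matrix(NA_real_, n_reps, length(methods), dimnames = list(NULL, methods))
  for (i in seq_len(n_reps)) {
    x <- with_seed(derive_seed(seed, 100L + i), matrix(rnorm(n * p), n, p))
    bat <- mvn_battery(x, methods = methods, n_mc = n_mc, null_cache = cache)
    for (m in methods) {
      r <- bat[[m]]
      if (inherits(r, "mvn_test_result")) rej[i, m] <- r$p_value
    }
  }
  tibble::tibble(
    method = methods,
    Q = colMeans(rej <= alpha, na.rm = TRUE)[methods],
    n_reps = as.integer(n_reps),
    alpha = alpha, n = as.integer(n), p = as.integer(p)
  )
}

#' Type-I-error and power study of the GSA tests
#'
#' Runs the full simulation grid: for every (setting, delta) cell, generate
#' `n_reps` independent two-group datasets, apply every requested GSA test
#' to each, and estimate power as the fraction of p-values at or below
#' `alpha`. Rows with `delta = 0` estimate the type-I error. Everything is
#' an exact function of the master seed: per-replication data seeds and
#' per-method test seeds are derived by a counter scheme, so any cell can be
#' reproduced in isolation.
#'
#' @param settings Character vector of setting ids (`"A"`..`"H"`).
#' @param deltas Numeric vector of mean shifts (include 0 for type-I error).
#' @param methods Subset of [gsa_methods()].
#' @param n_reps Replications per cell.
#' @param n_resamples Resamples per resampling test within each replication.
#' @param n_per_group,p Group size and dimension (defaults 50, 30).
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return A tibble of class `gsa_power_table` with columns `setting_id`,
#'   `delta`, `method`, `power`, `n_reps`, `mc_se` (binomial Monte-Carlo
#'   standard error), `n_failed`, plus run parameters.
#' @examples
#' \donttest{
#' pt <- power_study("A", c(0, 0.5),
#'   methods = "hotelling", n_reps = 20,
#'   n_per_group = 20, p = 5, seed = 1
#' )
#' }
#' @export
power_study <- function(settings, deltas, methods = gsa_methods(),
                        n_reps = 1000, n_resamples = 199, n_per_group = 50,
                        p = 30, alpha = 0.05, seed = 1) {
  methods <- match.arg(methods, gsa_methods(), several.ok = TRUE)
  methods <- gsa_methods()[gsa_methods() %in% methods]
  grid <- expand.grid(
    setting_id = as.character(settings), delta = deltas,
    stringsAsFactors = FALSE
  )
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sid <- grid$setting_id[g]
    delta <- grid$delta[g]
    pmat <- matrix(NA_real_, n_reps, length(methods),
      dimnames = list(NULL, methods)
    )
    for (i in seq_len(n_reps)) {
      counter <- (g - 1L) * n_reps + i
      data_seed <- derive_seed(seed, 2L * counter)
      test_seed <- derive_seed(seed, 2L * counter + 1L)
      d <- generate_setting(sid, delta, n_per_group, p, seed = data_seed)
      bat <- run_gsa(d, methods = methods, n_perm = n_resamples, seed = test_seed)
      for (m in methods) {
        r <- bat[[m]]
        if (inherits(r, "gsa_test_result")) pmat[i, m] <- r$p_value
      }
    }
    pw <- colMeans(pmat <= alpha, na.rm = TRUE)
    nf <- colSums(is.na(pmat))
    rows[[g]] <- tibble::tibble(
      setting_id = sid, delta = delta, method = methods,
      power = unname(pw[methods]),
      n_reps = as.integer(n_reps),
      mc_se = sqrt(unname(pw[methods]) * (1 - unname(pw[methods])) / n_reps),
      n_failed = as.integer(unname(nf[methods]))
    )
  }
  out <- dplyr::bind_rows(rows)
  out$n_resamples <- as.integer(n_resamples)
  out$n_per_group <- as.integer(n_per_group)
  out$p <- as.integer(p)
  out$alpha <- alpha
  out$seed <- as.integer(seed)
  class(out) <- c("gsa_power_table", class(out))
  out
}
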