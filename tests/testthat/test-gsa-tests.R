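test_that("global test matches a direct covariance permutation oracle", {
  # single gene: Q is a monotone function of the squared label-gene
  # covariance, so with a shared RNG stream the permutation p-values of the
  # two statistics are identical
  d <- generate_setting("A", 0.8, n_per_group = 10, p = 1, seed = 6)
  g <- global_test(d, n_perm = 999, seed = 7)
  pl <- gsanorm:::pool_two_group(d)
  set.seed(7)
  obs <- cov(pl$x[, 1], pl$y)^2
  null <- replicate(999, cov(pl$x[, 1], sample(pl$y))^2)
  expect_equal(g$p_value, (sum(null >= obs) + 1) / 1000)

  expect_error(
    global_test(two_group_dataset(matrix(numeric(0), 0, 2), matrix(1:4, 2))),
    "non-empty"
  )
})

test_that("permutation p-values agree with exhaustive enumeration", {
  # 3 vs 3 samples: only 20 distinct labelings; exact p by full enumeration
  d <- toy_two_group(n1 = 3, n2 = 3, p = 2, delta = 1.5, seed = 31)
  pl <- gsanorm:::pool_two_group(d)
  labelings <- all_labelings(6, 3)

  exact_p <- function(stat_fun) {
    obs <- stat_fun(pl$y)
    null <- apply(labelings, 2, stat_fun)
    mean(null >= obs - 1e-12)
  }

  # global test
  xt <- t(scale(pl$x, center = TRUE, scale = FALSE))
  q_stat <- function(y) sum((xt %*% (y - mean(y)))^2) / ncol(pl$x)
  expect_lt(abs(global_test(d, n_perm = 3999, seed = 1)$p_value - exact_p(q_stat)), 0.03)

  # N-statistic
  dm <- as.matrix(dist(pl$x))
  n_stat <- function(y) {
    gsanorm:::nstat_from_dist(dm, matrix(as.numeric(y == 0), ncol = 1))
  }
  expect_lt(abs(n_statistic_test(d, n_perm = 3999, seed = 2)$p_value - exact_p(n_stat)), 0.03)

  # MST KS (mean): ranking is fixed, only labels permute
  ranks <- mst_hdp_ranks(pl$x, "location")
  ord <- order(ranks)
  ks_stat <- function(y) {
    l <- y[ord]
    max(abs(cumsum(l == 0) / 3 - cumsum(l == 1) / 3))
  }
  expect_lt(abs(ks_mean_test(d, n_perm = 3999, seed = 3)$p_value - exact_p(ks_stat)), 0.03)

  # GSEA with 2 vs 2: six labelings, |sum of t| as the two-sided statistic
  d2 <- toy_two_group(n1 = 2, n2 = 2, p = 3, delta = 2, seed = 32)
  pl2 <- gsanorm:::pool_two_group(d2)
  lab2 <- all_labelings(4, 2)
  t_sum <- function(y) {
    abs(sum(gsanorm:::pooled_t_stats(pl2$x, matrix(as.numeric(y == 0), ncol = 1), 2, 2)))
  }
  obs2 <- t_sum(pl2$y)
  exact2 <- mean(apply(lab2, 2, t_sum) >= obs2 - 1e-12)
  expect_lt(abs(gsea_test(d2, n_perm = 3999, seed = 4)$p_value - exact2), 0.03)
})

test_that("Hotelling T2 reduces to the squared two-sample t and exact F", {
  d <- toy_two_group(n1 = 12, n2 = 9, p = 1, delta = 0.8, seed = 41)
  h <- hotelling_test(d)
  tt <- t.test(d$x_control[, 1], d$x_case[, 1], var.equal = TRUE)
  expect_equal(h$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$p_value, tt$p.value, tolerance = 1e-10)

  # small integer-valued case: classical p reproduced by a direct F-CDF
  # evaluation from first principles
  xc <- matrix(c(1, 2, 3, 4, 2, 4, 3, 5), 4, 2)
  xt2 <- matrix(c(3, 5, 4, 6, 5, 7, 8, 6), 4, 2)
  d2 <- two_group_dataset(xc, xt2)
  h2 <- hotelling_test(d2)
  dmean <- colMeans(xc) - colMeans(xt2)
  sp <- (cov(xc) * 3 + cov(xt2) * 3) / 6
  t2_hand <- (4 * 4 / 8) * as.numeric(t(dmean) %*% solve(sp) %*% dmean)
  expect_equal(h2$statistic, t2_hand, tolerance = 1e-12)
  expect_equal(
    h2$p_value,
    pf(t2_hand * (8 - 2 - 1) / (6 * 2), 2, 5, lower.tail = FALSE),
    tolerance = 1e-12
  )

  # swapping the group labels leaves T2 unchanged
  d_swap <- two_group_dataset(d$x_case, d$x_control)
  expect_equal(hotelling_test(d_swap)$statistic, h$statistic, tolerance = 1e-12)

  # p >= n: classical path refused, shrinkage path works
  d3 <- toy_two_group(n1 = 5, n2 = 5, p = 12, delta = 0, seed = 42)
  expect_error(hotelling_test(d3, shrinkage = FALSE), "classical")
  h3 <- hotelling_test(d3, n_perm = 99, seed = 1)
  expect_equal(h3$null_method, "permutation")
  expect_true(h3$p_value > 0 && h3$p_value <= 1)
})

test_that("rotation test matches a single-gene oracle and floors its p-value", {
  # for one gene the rotation null of the (un-moderated) group t statistic
  # is its exact t distribution, so the rotation p approaches the classical
  # two-sided t-test p
  d <- generate_setting("A", 0.8, n_per_group = 10, p = 1, seed = 21)
  r <- roast_test(d, n_rot = 9999, seed = 5)
  pl <- gsanorm:::pool_two_group(d)
  tt <- t.test(pl$x[pl$y == 1, 1], pl$x[pl$y == 0, 1], var.equal = TRUE)
  expect_lt(abs(r$p_value - tt$p.value), 0.02)

  # resampling p-value floor at 1/(n_rot + 1)
  d_strong <- generate_setting("A", 3, n_per_group = 15, p = 5, seed = 22)
  r2 <- roast_test(d_strong, n_rot = 99, seed = 1)
  expect_gte(r2$p_value, 1 / 100)
  expect_lte(r2$p_value, 3 / 100)

  # msq variant runs and reports the mean squared moderated z
  r3 <- roast_test(d_strong, n_rot = 99, set_stat = "msq", seed = 2)
  expect_gt(r3$statistic, 0)
})

test_that("pathway activity score matches hand computation and rank rules", {
  # 8-sample, 3-gene toy: score recomputed with explicit loops
  set.seed(51)
  x <- matrix(rnorm(24), 8, 3)
  score <- gsanorm:::pscore_score(x)
  ranks <- apply(x, 2, rank)
  cors <- abs(cor(x))
  w <- numeric(3)
  for (g in 1:3) w[g] <- mean(cors[g, -g])
  hand <- as.numeric(ranks %*% w) / sum(w)
  expect_equal(score, hand, tolerance = 1e-12)

  # monotone transformation of one gene leaves the ranks, and nearly the
  # score, unchanged (weights change only through |cor|)
  x2 <- x
  x2[, 2] <- exp(x2[, 2])
  expect_equal(apply(x2, 2, rank), ranks)

  # two identical genes get identical weights and a score proportional to
  # their common rank vector
  xi <- cbind(g1 = c(1, 3, 2, 5, 4, 6), g2 = c(1, 3, 2, 5, 4, 6) * 2)
  cors_i <- abs(cor(xi))
  expect_equal(cors_i[1, 2], 1)
  s_i <- gsanorm:::pscore_score(xi)
  expect_equal(s_i, rank(xi[, 1]), tolerance = 1e-12)

  # the full test returns a likelihood-ratio p-value
  d <- toy_two_group(n1 = 15, n2 = 15, p = 4, delta = 1, seed = 52)
  pr <- pscore_test(d)
  expect_equal(pr$null_method, "likelihood_ratio")
  expect_lt(pr$p_value, 0.05)
  expect_error(pscore_test(toy_two_group(p = 1, seed = 3)), "at least 2 genes")
})

test_that("GSEA set statistic is antisymmetric under relabeling", {
  d <- toy_two_group(n1 = 6, n2 = 6, p = 4, delta = 1, seed = 61)
  g1 <- gsea_test(d, n_perm = 499, seed = 9)
  d_swap <- two_group_dataset(d$x_case, d$x_control)
  g2 <- gsea_test(d_swap, n_perm = 499, seed = 9)
  expect_equal(g1$statistic, -g2$statistic, tolerance = 1e-10)
  expect_equal(g1$p_value, g2$p_value)

  # zero-variance gene contributes t = 0 instead of NaN
  d$x_control[, 1] <- 1
  d$x_case[, 1] <- 1
  expect_message(g3 <- gsea_test(d, n_perm = 99, seed = 1), "zero-variance")
  expect_true(is.finite(g3$statistic))
})

test_that("N-statistic is a nonnegative e-distance, zero on identical groups", {
  x <- matrix(rnorm(20), 5, 4)
  d_same <- two_group_dataset(x, x)
  expect_equal(n_statistic_test(d_same, n_perm = 19, seed = 1)$statistic, 0,
    tolerance = 1e-12
  )

  # brute-force oracle on a univariate toy: {0,1} vs {10,11}
  d_toy <- two_group_dataset(matrix(c(0, 1), 2), matrix(c(10, 11), 2))
  cross <- mean(c(10, 11, 9, 10)) # all |x_i - y_j|
  within <- mean(c(0, 1, 1, 0)) # both groups have the same within pattern
  n_hand <- (2 * 2 / 4) * (2 * cross - within - within)
  expect_equal(n_statistic_test(d_toy, n_perm = 19, seed = 1)$statistic,
    n_hand,
    tolerance = 1e-12
  )

  for (i in 1:5) {
    d <- toy_two_group(n1 = 6, n2 = 8, p = 3, delta = runif(1, 0, 2), seed = i)
    expect_gte(n_statistic_test(d, n_perm = 9, seed = 1)$statistic, -1e-12)
  }
})

test_that("MST construction and rankings follow their definitions", {
  # collinear chain 0 - 1 - 3: edges (1,2), (2,3)
  x <- matrix(c(0, 1, 3), ncol = 1)
  edges <- gsanorm:::euclidean_mst(x)
  canon <- t(apply(edges, 1, sort))
  expect_equal(canon[order(canon[, 1]), ], rbind(c(1, 2), c(2, 3)))

  # location ranks of a chain graph run end to end
  xc <- matrix(c(0, 1, 2.2, 3.1, 4.5), ncol = 1)
  ranks <- mst_hdp_ranks(xc, "location")
  expect_true(identical(ranks, 1:5) || identical(ranks, 5:1))

  # scale ranks follow the distance from the centroid (here the origin):
  # radii 1 < 2 < 5 < sqrt(40)
  xs <- rbind(c(1, 0), c(0, 2), c(5, 0), c(-6, -2))
  expect_equal(mst_hdp_ranks(xs, "scale"), 1:4)

  ranks_big <- mst_hdp_ranks(matrix(rnorm(60), 20, 3), "location")
  expect_setequal(ranks_big, 1:20)
})

test_that("KS running statistic matches brute force and hits 1 at separation", {
  # 3 vs 3 toy, brute-force prefix scan over the ranking
  d <- toy_two_group(n1 = 3, n2 = 3, p = 2, delta = 0.5, seed = 71)
  pl <- gsanorm:::pool_two_group(d)
  ranks <- mst_hdp_ranks(pl$x, "location")
  lab_in_order <- pl$y[order(ranks)]
  prefix_d <- numeric(6)
  for (i in 1:6) {
    prefix_d[i] <- abs(
      sum(lab_in_order[1:i] == 0) / 3 - sum(lab_in_order[1:i] == 1) / 3
    )
  }
  expect_equal(ks_mean_test(d, n_perm = 19, seed = 1)$statistic, max(prefix_d))

  # groups at opposite ends of a chain separate perfectly: D = 1
  d_sep <- two_group_dataset(
    matrix(c(1, 2, 3, 4, 5), 5, 1),
    matrix(c(50, 51, 52, 53, 54), 5, 1)
  )
  expect_equal(ks_mean_test(d_sep, n_perm = 19, seed = 1)$statistic, 1)
  for (i in 1:4) {
    d_r <- toy_two_group(n1 = 5, n2 = 7, p = 2, delta = 0.3, seed = 80 + i)
    stat <- ks_var_test(d_r, n_perm = 9, seed = 1)$statistic
    expect_true(stat >= 0 && stat <= 1)
  }
})

test_that("the GSA battery contains failures and keeps a stable order", {
  d <- toy_two_group(n1 = 8, n2 = 8, p = 1, delta = 0.5, seed = 91)
  bat <- run_gsa(d, n_perm = 49, seed = 3)
  td <- tidy(bat)
  expect_equal(td$method, c(
    "global", "hotelling", "roast", "pscore", "gsea",
    "nstat", "ks_mean", "ks_var"
  ))
  # pscore needs >= 2 genes and must fail alone
  expect_true(is.na(td$p_value[td$method == "pscore"]))
  expect_equal(sum(is.na(td$p_value)), 1)
  expect_equal(glance(bat)$n_failed, 1)
})
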