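test_that("Mardia's moments match hand computation and known limits", {
  # symmetric 3-point sample: m_ij = (x_i - xbar)(x_j - xbar)/S with S = 2/3
  # gives m = {1.5, 0, 1.5} on the diagonal, b1 = 0 by symmetry, b2 = 1.5
  x <- matrix(c(-1, 0, 1), ncol = 1)
  res <- mardia_test(x)
  expect_equal(unname(res$components["b1p"]), 0)
  expect_equal(unname(res$components["b2p"]), 1.5)

  # hand computation of b1, b2 on an asymmetric sample by explicit loops
  x2 <- matrix(c(0, 1, 3, 7), ncol = 1)
  s_mle <- mean((x2 - mean(x2))^2)
  m <- outer(x2[, 1] - mean(x2), x2[, 1] - mean(x2)) / s_mle
  expect_equal(unname(mardia_test(x2)$components["b1p"]), sum(m^3) / 16)
  expect_equal(unname(mardia_test(x2)$components["b2p"]), sum(diag(m)^2) / 4)

  # b2 converges to p(p+2) = 15 for a large trivariate normal sample
  xn <- matrix(rnorm(60000), 20000, 3)
  expect_equal(unname(mardia_test(xn)$components["b2p"]), 15, tolerance = 0.03)

  # reported p-value is the smaller of the two component p-values
  expect_equal(
    res$p_value,
    min(res$components[c("p_skewness", "p_kurtosis")])
  )
})

test_that("Henze-Zirkler statistic matches a literal double-loop evaluation", {
  # direct evaluation of ((n(2p+1))/4)^(1/(p+4))/sqrt(2) at n=100, p=30
  expect_equal(gsanorm:::hz_beta(100, 30), 1525^(1 / 34) / sqrt(2), tolerance = 1e-10)
  expect_equal(gsanorm:::hz_beta(100, 30), 0.8772, tolerance = 1e-4)

  set.seed(31)
  x <- matrix(rnorm(15 * 3), 15, 3)
  n <- 15
  p <- 3
  # independent oracle: the defining double sum, written as plain loops on
  # Mahalanobis distances from the MLE covariance
  xc <- sweep(x, 2, colMeans(x))
  s_inv <- solve(crossprod(xc) / n)
  b <- gsanorm:::hz_beta(n, p)
  acc1 <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      dij <- as.numeric(t(xc[i, ] - xc[j, ]) %*% s_inv %*% (xc[i, ] - xc[j, ]))
      acc1 <- acc1 + exp(-b^2 * dij / 2)
    }
  }
  acc2 <- 0
  for (i in 1:n) {
    di <- as.numeric(t(xc[i, ]) %*% s_inv %*% xc[i, ])
    acc2 <- acc2 + exp(-b^2 * di / (2 * (1 + b^2)))
  }
  hz_oracle <- n * (acc1 / n^2 - 2 * (1 + b^2)^(-p / 2) * acc2 / n + (1 + 2 * b^2)^(-p / 2))
  expect_equal(hz_test(x)$statistic, hz_oracle, tolerance = 1e-12)

  # nonnegativity on assorted inputs, including clearly non-normal ones
  for (seed in 1:5) {
    set.seed(seed)
    xx <- matrix(exp(rnorm(80)), 20, 4)
    expect_gte(hz_test(xx)$statistic, 0)
  }

  # Monte-Carlo null path produces (b+1)/(B+1)-style p-values
  r <- hz_test(matrix(rnorm(60), 20, 3), null_method = "monte_carlo", n_mc = 99, seed = 1)
  expect_equal(r$n_resamples, 99L)
  expect_true(r$p_value >= 1 / 100 && r$p_value <= 1)
})

test_that("Royston's test reduces to Shapiro-Wilk at p = 1 and e tracks p", {
  set.seed(41)
  x <- matrix(rexp(30), ncol = 1)
  r <- royston_test(x)
  expect_equal(unname(r$components["e"]), 1)
  expect_equal(r$p_value, shapiro.test(x[, 1])$p.value, tolerance = 1e-6)

  # independent columns: the correlation adjustment vanishes, e ~ p
  xi <- matrix(rnorm(500 * 5), 500, 5)
  expect_gt(unname(royston_test(xi)$components["e"]), 4.5)
  # strongly correlated columns: e shrinks well below p
  xc <- matrix(rnorm(500), 500, 1)[, rep(1, 5)] + matrix(rnorm(2500, sd = 0.3), 500, 5)
  expect_lt(unname(royston_test(xc)$components["e"]), 3.5)

  expect_error(royston_test(cbind(rnorm(20), rep(1, 20))), "singular|[Dd]egenerate")
})

test_that("FA and TN statistics live on their defined ranges", {
  set.seed(51)
  x <- matrix(rnorm(40 * 4), 40, 4)
  fa <- fa_test(x, n_mc = 49, seed = 1)
  tn <- tn_test(x, n_mc = 49, seed = 1)
  expect_true(fa$statistic > 0 && fa$statistic <= 1)
  expect_gte(tn$statistic, 0)
  expect_equal(fa$n_resamples, 49L)

  # power sanity: a strongly lognormal sample is rejected in nearly all seeds
  rejections <- vapply(1:15, function(i) {
    set.seed(100 + i)
    xl <- matrix(exp(rnorm(50 * 5)), 50, 5)
    fa_test(xl, n_mc = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})

test_that("energy closed forms agree with numeric integration", {
  # E||Z - Z'|| in one dimension is 2/sqrt(pi)
  expect_equal(gsanorm:::expected_norm_zz(1), 2 / sqrt(pi), tolerance = 1e-12)

  # E||a - Z|| at a = 0 equals E||Z|| = E||Z - Z'||/sqrt(2)
  for (p in c(1, 3, 10, 30)) {
    expect_equal(
      gsanorm:::expected_norm_az(0, p),
      gsanorm:::expected_norm_zz(p) / sqrt(2),
      tolerance = 1e-10
    )
  }

  # oracle: ||a - Z||^2 ~ noncentral chi-square, integrate sqrt(x) density
  for (case in list(c(3, 4), c(10, 0.5), c(30, 25), c(5, 180))) {
    p <- case[1]
    lambda <- case[2]
    oracle <- stats::integrate(function(t) sqrt(t) * stats::dchisq(t, df = p, ncp = lambda),
      0, Inf,
      rel.tol = 1e-10
    )$value
    expect_equal(gsanorm:::expected_norm_az(lambda, p), oracle, tolerance = 1e-4)
  }

  # the statistic is nonnegative
  set.seed(61)
  for (i in 1:5) {
    x <- matrix(rt(100, df = 2), 25, 4)
    expect_gte(energy_mvn_test(x, n_boot = 19, seed = i)$statistic, -1e-10)
  }
})

test_that("affine maps leave the invariant statistics unchanged", {
  set.seed(71)
  x <- matrix(rnorm(40 * 4), 40, 4)
  for (rep in 1:3) {
    a <- random_invertible(4)
    b <- rnorm(4)
    y <- x %*% a + rep(b, each = 40)

    expect_equal(gsanorm:::hz_statistic(y), gsanorm:::hz_statistic(x),
      tolerance = 1e-8
    )
    expect_equal(
      gsanorm:::fa_statistic(gsanorm:::mvn_standardize(y)$z),
      gsanorm:::fa_statistic(gsanorm:::mvn_standardize(x)$z),
      tolerance = 1e-8
    )
    expect_equal(
      gsanorm:::energy_statistic(gsanorm:::mvn_standardize(y)$z),
      gsanorm:::energy_statistic(gsanorm:::mvn_standardize(x)$z),
      tolerance = 1e-8
    )
    mx <- mardia_test(x)$components[c("b1p", "b2p")]
    my <- mardia_test(y)$components[c("b1p", "b2p")]
    expect_equal(my, mx, tolerance = 1e-8)
  }

  # Royston works coordinate-wise, so its invariance group is the
  # coordinate-wise (diagonal) affine maps
  dscale <- diag(c(2, 0.5, 3, 10))
  yd <- x %*% dscale + 5
  expect_equal(royston_test(yd)$statistic, royston_test(x)$statistic,
    tolerance = 1e-8
  )
})

test_that("monotone contamination drives the median p-value down", {
  # a shifted contaminating component makes the sample increasingly skewed
  # as its weight grows (up to the point where the mixture turns symmetric
  # again, so the grid stays in the low-weight regime)
  contaminated_p <- function(w) {
    comps <- list(
      mixture_component("normal", rep(0, 3), diag(3), weight = 1 - w),
      mixture_component("normal", rep(2.5, 3), diag(3), weight = w)
    )
    if (w == 0) comps <- comps[1]
    if (w == 1) comps <- comps[2]
    null_cache <- mvn_null_stats("energy", 40, 3, 99, seed = 99)
    median(vapply(1:25, function(i) {
      x <- sample_mixture(comps, 40, seed = 500 + i)
      energy_mvn_test(x, null_stats = null_cache)$p_value
    }, numeric(1)))
  }
  meds <- vapply(c(0, 0.05, 0.12), contaminated_p, numeric(1))
  expect_true(meds[2] <= meds[1] && meds[3] <= meds[2])
  expect_lt(meds[3], 0.05)
})

test_that("the battery runs all six tests and composes with direct calls", {
  set.seed(81)
  x <- matrix(rnorm(50 * 5), 50, 5)
  bat <- mvn_battery(x, n_mc = 99, seed = 7)
  td <- tidy(bat)
  expect_equal(td$method, c("mardia", "hz", "royston", "fa", "tn", "energy"))
  expect_false(any(is.na(td$p_value)))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))

  # composition: the battery equals calling each test with its derived seed
  expect_identical(bat$mardia$p_value, mardia_test(x)$p_value)
  expect_identical(
    bat$fa$p_value,
    fa_test(x, n_mc = 99, seed = gsanorm:::derive_seed(7, 4))$p_value
  )
  expect_identical(
    bat$energy$p_value,
    energy_mvn_test(x, n_boot = 99, seed = gsanorm:::derive_seed(7, 6))$p_value
  )

  # a failing method is contained, the rest still run (n = 2005 is outside
  # the validity range of Royston's normalization but fine for Mardia)
  x_big <- matrix(rnorm(2005 * 2), 2005, 2)
  bat_bad <- mvn_battery(x_big, methods = c("mardia", "royston"))
  td_bad <- tidy(bat_bad)
  expect_false(is.na(td_bad$p_value[td_bad$method == "mardia"]))
  expect_true(is.na(td_bad$p_value[td_bad$method == "royston"]))
})

test_that("singular covariances are refused with an informative error", {
  expect_error(mardia_test(matrix(rnorm(12), 3, 4)), "n > p \\+ 1")
  x <- matrix(rnorm(30), 10, 3)
  x <- cbind(x, x[, 1]) # exact collinearity
  expect_error(hz_test(x), "singular")
})
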