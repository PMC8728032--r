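# Shared helpers for the test suite. Fixtures are built in code; nothing is
# read from disk except what a test itself writes to a tempdir.

# Two-sided binomial acceptance band around a nominal rate, at confidence
# `conf`, for an empirical proportion estimated from n_reps replications.
binomial_band <- function(nominal, n_reps, conf = 0.99) {
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(nominal * (1 - nominal) / n_reps)
  c(lower = nominal - half, upper = nominal + half)
}

expect_in_band <- function(rate, nominal, n_reps, conf = 0.99,
                           label = "rejection rate") {
  band <- binomial_band(nominal, n_reps, conf)
  expect_true(
    rate >= band["lower"] && rate <= band["upper"],
    label = sprintf(
      "%s %.4f inside [%.4f, %.4f] (nominal %.3f, %d reps)",
      label, rate, band["lower"], band["upper"], nominal, n_reps
    )
  )
}

# Random invertible matrix (regenerated until comfortably conditioned).
random_invertible <- function(p) {
  repeat {
    a <- matrix(rnorm(p * p), p, p)
    if (abs(det(a)) > 0.1) {
      return(a)
    }
  }
}

# A small labelled two-group dataset for the GSA tests.
toy_two_group <- function(n1 = 10, n2 = 10, p = 4, delta = 0, seed = 1) {
  generate_setting("A", delta = delta, n_per_group = n1, p = p, seed = seed)
}

# All distinct 0/1 labelings of n samples with n1 zeros, as an n x K matrix.
all_labelings <- function(n, n1) {
  combos <- utils::combn(n, n1)
  apply(combos, 2, function(idx) {
    y <- rep(1L, n)
    y[idx] <- 0L
    y
  })
}
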