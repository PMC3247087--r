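# Shared fixtures, built in code.

# A planted scenario pair embedded in noise, seeded like the peaking bench.
planted_dataset <- function(scenario, p, seed, n0 = 40, n1 = 40) {
  d <- simulate_scenario(scenario_spec(scenario, n0 = n0, n1 = n1,
                                       seed = seed))
  if (p > 2) {
    d <- add_noise_features(d, p - 2, seed = seed + 1000000L)
  }
  d
}

# Two well-separated Gaussian clouds: CV error should be exactly 0.
separated_dataset <- function(n = 40, seed = 1) {
  X <- withr::with_seed(seed, rbind(
    matrix(rnorm(2 * n, mean = -100), n, 2),
    matrix(rnorm(2 * n, mean = 100), n, 2)
  ))
  labeled_dataset(X, rep(c(0L, 1L), each = n))
}

# Random positive-definite covariance matrix.
random_spd <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p), p, p)
    crossprod(A) / p + diag(0.5, p)
  })
}

# Brute-force Bayes classification: per-class Gaussian density times prior,
# computed without Cholesky factors (stats::mahalanobis + det), so it is an
# independent route from the package's discriminant.
bayes_classify <- function(X, mu0, mu1, sigma0, sigma1, priors) {
  d0 <- exp(-0.5 * stats::mahalanobis(X, mu0, sigma0)) /
    sqrt(det(2 * pi * sigma0))
  d1 <- exp(-0.5 * stats::mahalanobis(X, mu1, sigma1)) /
    sqrt(det(2 * pi * sigma1))
  as.integer(priors[2] * d1 > priors[1] * d0)
}
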