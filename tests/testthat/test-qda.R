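test_that("fit_qda recovers plug-in estimates and priors", {
  # duplicated rows per class: means equal the duplicated rows
  X <- rbind(c(1, 2), c(1, 2), c(5, -1), c(5, -1))
  y <- c(0, 0, 1, 1)
  m <- fit_qda(X, y, ridge = 0.1)
  expect_equal(m$mu0, c(1, 2))
  expect_equal(m$mu1, c(5, -1))
  expect_equal(m$priors, c(0.5, 0.5))

  # prior policies
  y2 <- c(0, 1, 1, 1)
  X2 <- matrix(rnorm(8), 4, 2)
  expect_equal(fit_qda(X2, y2, priors = "balanced", ridge = 1)$priors,
               c(0.5, 0.5))
  expect_equal(fit_qda(X2, y2, priors = "empirical", ridge = 1)$priors,
               c(0.25, 0.75))
  expect_equal(fit_qda(X2, y2, priors = c(0.3, 0.7), ridge = 1)$priors,
               c(0.3, 0.7))

  # one-class input errors
  expect_error(fit_qda(X, rep(1, 4)), "absent")

  # Monte-Carlo consistency: fitted means within 4 SE of the truth
  n <- 5000
  d <- withr::with_seed(41, rbind(
    matrix(rnorm(2 * n, 0, 1), n, 2),
    matrix(rnorm(2 * n, 3, 2), n, 2)))
  mfit <- fit_qda(d, rep(c(0, 1), each = n))
  expect_true(all(abs(mfit$mu0 - 0) < 4 / sqrt(n)))
  expect_true(all(abs(mfit$mu1 - 3) < 4 * 2 / sqrt(n)))
  expect_lt(max(abs(mfit$sigma1 - diag(4, 2))), 0.3)
})

test_that("the discriminant degenerates as theory predicts", {
  sg <- random_spd(2, seed = 1)
  # equal covariances + equal priors: score is affine in x
  m <- qda_model(c(0, 0), c(1, 2), sg, sg)
  xs <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(0, 2), c(1, 1), c(2, 2))
  s <- qda_discriminant(m, xs)
  # second differences along each axis vanish for an affine function
  expect_equal(s[3] - s[2], s[2] - s[1], tolerance = 1e-10)
  expect_equal(s[5] - s[4], s[4] - s[1], tolerance = 1e-10)
  # full symmetry: identical classes give score identically zero
  m0 <- qda_model(c(1, 1), c(1, 1), sg, sg)
  expect_equal(qda_discriminant(m0, xs), rep(0, nrow(xs)))
  # dimension mismatch is caught
  expect_error(qda_discriminant(m, c(1, 2, 3)), "columns")
})

test_that("qda_predict matches the Bayes oracle and breaks ties to class 0", {
  grid <- as.matrix(expand.grid(x1 = seq(-3, 3, length.out = 21),
                                x2 = seq(-3, 3, length.out = 21)))
  for (s in 1:5) {
    mu0 <- withr::with_seed(s, rnorm(2))
    mu1 <- withr::with_seed(s + 100, rnorm(2))
    s0 <- random_spd(2, seed = s + 200)
    s1 <- random_spd(2, seed = s + 300)
    pr <- c(0.4, 0.6)
    m <- qda_model(mu0, mu1, s0, s1, priors = pr)
    expect_equal(qda_predict(m, grid),
                 bayes_classify(grid, mu0, mu1, s0, s1, pr))
  }
  # tie at score exactly zero goes to class 0: a fully symmetric model
  sg <- diag(2)
  m0 <- qda_model(c(0, 0), c(0, 0), sg, sg)
  expect_equal(qda_predict(m0, rbind(c(1, 1), c(0, 0))), c(0L, 0L))
  # point at mu0 with shared covariance and priors: class 0
  m <- qda_model(c(-1, 0), c(1, 0), sg, sg)
  expect_equal(qda_predict(m, rbind(c(-1, 0))), 0L)
})

test_that("predictions are translation equivariant", {
  d <- separated_dataset(seed = 7)
  m <- fit_qda(d$X, d$y)
  shift <- c(13.5, -2.25)
  m2 <- fit_qda(sweep(d$X, 2, -shift), d$y)
  Xnew <- withr::with_seed(8, matrix(rnorm(40, sd = 50), 20, 2))
  expect_equal(qda_predict(m, Xnew), qda_predict(m2, sweep(Xnew, 2, -shift)))
})

test_that("stratified folds conserve samples and balance classes", {
  y <- rep(c(0L, 1L), c(22, 40))
  f <- make_folds(y, k = 10, seed = 3)
  expect_true(all(f %in% 1:10))
  expect_length(f, 62)
  for (cls in 0:1) {
    sizes <- tabulate(f[y == cls], 10)
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_identical(f, make_folds(y, k = 10, seed = 3))
  expect_error(make_folds(rep(c(0L, 1L), c(5, 40)), k = 10), "k <= 5")
})

test_that("cv_error pools fold misclassifications deterministically", {
  d <- separated_dataset(seed = 9)
  est <- cv_error(d$X, d$y, seed = 4)
  expect_equal(est$error_rate, 0)            # perfectly separated clouds
  expect_length(est$fold_errors, 10)

  # determinism: same inputs, same estimate
  d2 <- planted_dataset("circular", p = 5, seed = 17)
  e1 <- cv_error(d2$X, d2$y, seed = 5)
  e2 <- cv_error(d2$X, d2$y, seed = 5)
  expect_identical(e1, e2)

  # scenario-1 pair alone classifies far better than chance
  d3 <- simulate_scenario(scenario_spec("linear", seed = 23))
  expect_lt(cv_error(d3$X, d3$y, seed = 23)$error_rate, 0.2)

  # error_rate equals pooled misclassified count / n
  folds <- make_folds(d2$y, 10, 5)
  sizes <- tabulate(folds, 10)
  expect_equal(e1$error_rate, sum(e1$fold_errors * sizes) / 80)
})

test_that("labels independent of the features give chance-level error", {
  errs <- vapply(1:100, function(s) {
    d <- simulate_noise_only(40, 40, 2, seed = s)
    cv_error(d$X, d$y, seed = s)$error_rate
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.05)
})

test_that("the C++ CV engine agrees exactly with the pure-R classifier", {
  # Dual route: re-run every fold with the exported fit_qda / qda_predict
  # and compare the pooled error with cv_error's on identical folds.
  for (s in 1:5) {
    d <- planted_dataset(c("linear", "xor", "circular")[1 + s %% 3],
                         p = 6, seed = s)
    folds <- make_folds(d$y, 10, seed = s)
    miss <- 0L
    for (f in 1:10) {
      m <- fit_qda(d$X[folds != f, , drop = FALSE], d$y[folds != f])
      miss <- miss + sum(qda_predict(m, d$X[folds == f, , drop = FALSE]) !=
                           d$y[folds == f])
    }
    expect_equal(cv_error(d$X, d$y, seed = s)$error_rate, miss / 80)
  }
})

test_that("predictions agree with an established QDA implementation", {
  skip_if_not_installed("MASS")
  for (s in 1:3) {
    d <- planted_dataset("linear", p = 4, seed = s, n0 = 50, n1 = 50)
    ref <- MASS::qda(d$X, grouping = factor(d$y))
    Xnew <- withr::with_seed(s + 50, matrix(rnorm(200), 50, 4))
    expect_equal(qda_predict(fit_qda(d$X, d$y), Xnew),
                 as.integer(as.character(predict(ref, Xnew)$class)))
  }
})

test_that("increasing the ridge never breaks positive-definiteness", {
  # rank-deficient class covariance: 3 samples in 5 dimensions
  X <- withr::with_seed(31, matrix(rnorm(40), 8, 5))
  y <- rep(c(0L, 1L), each = 4L)
  for (r in c(1e-6, 1e-3, 1, 100)) {
    expect_s3_class(fit_qda(X, y, ridge = r), "qda_model")
  }
  expect_error(fit_qda(X, y, ridge = 0), "positive-definite")
})
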