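#' Fit a binary quadratic discriminant classifier by plug-in estimation
#'
#' Estimates per-class mean vectors and covariance matrices (denominator
#' `n_c - 1`) and plugs them, together with the class priors, into the
#' Gaussian quadratic discriminant rule. A small ridge is always added to
#' the covariance diagonals so that folds leaving `n_c <= p` training
#' samples do not produce singular covariances; by default the ridge is
#' `1e-6 * trace(S_c) / p` per class.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1), both classes present.
#' @param priors `"empirical"` (class proportions, the default),
#'   `"balanced"` (0.5/0.5), or an explicit numeric pair `(pi_0, pi_1)`
#'   summing to 1.
#' @param ridge non-negative scalar added to each covariance diagonal;
#'   `NULL` (default) uses the per-class adaptive value above.
#' @return An object of class `qda_model`; see [qda_model()] for its
#'   contents.
#' @seealso [qda_predict()], [qda_discriminant()], [cv_error()]
#' @export
fit_qda <- function(X, y, priors = "empirical", ridge = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  n_c <- c(sum(y == 0L), sum(y == 1L))
  if (any(n_c == 0L)) {
    stop("class ", which(n_c == 0L)[1] - 1L, " is absent; QDA needs both classes")
  }
  pr <- resolve_priors(priors, n_c)
  est <- lapply(c(0L, 1L), function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    p <- ncol(Xc)
    mu <- colMeans(Xc)
    S <- if (nrow(Xc) > 1L) stats::cov(Xc) else matrix(0, p, p)
    r <- if (is.null(ridge)) 1e-6 * sum(diag(S)) / p else ridge
    Sreg <- S + diag(r, p)
    ch <- tryCatch(chol(Sreg), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf(
        "regularized covariance of class %d is not positive-definite (n_%d = %d, p = %d); increase ridge",
        cls, cls, nrow(Xc), p))
    }
    list(mu = mu, sigma = S, chol = ch,
         logdet = 2 * sum(log(diag(ch))), ridge = r)
  })
  qda_model(mu0 = est[[1]]$mu, mu1 = est[[2]]$mu,
            sigma0 = est[[1]]$sigma + diag(est[[1]]$ridge, ncol(X)),
            sigma1 = est[[2]]$sigma + diag(est[[2]]$ridge, ncol(X)),
            priors = pr)
}

#' Construct a QDA model from explicit Gaussian parameters
#'
#' Builds the quadratic discriminant rule directly from population (or
#' otherwise externally supplied) class means, covariances and priors,
#' bypassing estimation — the route used to compare the plug-in classifier
#' against the Bayes rule it estimates.
#'
#' @param mu0,mu1 class mean vectors of common length `p`.
#' @param sigma0,sigma1 class `p x p` covariance matrices, symmetric
#'   positive-definite.
#' @param priors numeric pair `(pi_0, pi_1)`, both in (0, 1), summing to 1.
#' @return An object of class `qda_model`: a list with the means,
#'   covariances, priors, Cholesky factors and log-determinants.
#' @export
qda_model <- function(mu0, mu1, sigma0, sigma1, priors = c(0.5, 0.5)) {
  p <- length(mu0)
  stopifnot(length(mu1) == p,
            is.matrix(sigma0), all(dim(sigma0) == p),
            is.matrix(sigma1), all(dim(sigma1) == p))
  priors <- as.numeric(priors)
  if (length(priors) != 2 || abs(sum(priors) - 1) > 1e-8 ||
      any(priors <= 0) || any(priors >= 1)) {
    stop("priors must be two probabilities in (0,1) summing to 1")
  }
  ch0 <- tryCatch(chol(sigma0), error = function(e)
    stop("sigma0 is not positive-definite"))
  ch1 <- tryCatch(chol(sigma1), error = function(e)
    stop("sigma1 is not positive-definite"))
  structure(
    list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
         sigma0 = sigma0, sigma1 = sigma1,
         chol0 = ch0, chol1 = ch1,
         logdet0 = 2 * sum(log(diag(ch0))),
         logdet1 = 2 * sum(log(diag(ch1))),
         priors = priors, p = p),
    class = "qda_model"
  )
}

#' @export
print.qda_model <- function(x, ...) {
  cat(sprintf("qda_model: p = %d, priors = (%.3f, %.3f)\n",
              x$p, x$priors[1], x$priors[2]))
  invisible(x)
}

resolve_priors <- function(priors, n_c) {
  if (is.character(priors)) {
    switch(match.arg(priors, c("empirical", "balanced")),
           empirical = n_c / sum(n_c),
           balanced = c(0.5, 0.5))
  } else {
    pr <- as.numeric(priors)
    if (length(pr) != 2 || abs(sum(pr) - 1) > 1e-8 || any(pr <= 0)) {
      stop("explicit priors must be two positive values summing to 1")
    }
    pr
  }
}

#' Quadratic discriminant score
#'
#' The log-posterior difference `log P(Y=1|x) - log P(Y=0|x)` under the
#' model's two Gaussian class-conditional densities and priors. Its sign
#' gives the predicted class and its zero level set is the hyperquadric
#' decision boundary determined by the difference of the inverse
#' covariances; when the covariances coincide the quadratic term cancels
#' and the boundary degenerates to the linear discriminant.
#'
#' @param model a `qda_model`.
#' @param x a numeric vector of length `p`, or a matrix with `p` columns
#'   (one score per row).
#' @return A numeric scalar (or vector, for matrix input).
#' @export
qda_discriminant <- function(model, x) {
  stopifnot(inherits(model, "qda_model"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$p) {
    stop(sprintf("x has %d columns but the model expects %d", ncol(X), model$p))
  }
  q0 <- mahal_sq(X, model$mu0, model$chol0)
  q1 <- mahal_sq(X, model$mu1, model$chol1)
  s <- (log(model$priors[2]) - 0.5 * model$logdet1 - 0.5 * q1) -
       (log(model$priors[1]) - 0.5 * model$logdet0 - 0.5 * q0)
  if (is.matrix(x)) s else s[[1]]
}

# Squared Mahalanobis distances of rows of X from mu, given chol(sigma).
mahal_sq <- function(X, mu, ch) {
  Z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  colSums(Z^2)
}

#' Predict class labels with a QDA model
#'
#' Class 1 if and only if the discriminant score strictly favours class 1;
#' the tie at a score of exactly zero resolves to class 0.
#'
#' @param model a `qda_model`.
#' @param X numeric matrix with `p` columns.
#' @return Integer vector of 0/1 predictions, one per row.
#' @export
qda_predict <- function(model, X) {
  X <- as.matrix(X)
  as.integer(qda_discriminant(model, X) > 0)
}

#' Stratified k-fold partition
#'
#' Assigns every sample to exactly one test fold, shuffling within each
#' class so each fold's class counts differ by at most one from the others.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer RNG seed; the same `(y, k, seed)` reproduce the
#'   partition exactly.
#' @return Integer vector of fold memberships in `1..k`.
#' @export
make_folds <- function(y, k = 10, seed = 1) {
  y <- as.integer(y)
  k <- as.integer(k)
  n_c <- c(sum(y == 0L), sum(y == 1L))
  if (any(n_c < k)) {
    stop(sprintf(
      "class %d has only %d samples; use k <= %d for stratified folds",
      which(n_c < k)[1] - 1L, min(n_c), min(n_c)))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated QDA error rate
#'
#' Stratified k-fold cross-validation of the plug-in QDA classifier: for
#' each fold the model is fitted on the complement and misclassifications
#' are counted on the held-out fold; the reported error pools the
#' misclassified counts over all folds and divides by `n`. The fold
#' partition is a deterministic function of `(y, k, seed)` only, so scoring
#' different feature subsets of the same samples with the same seed uses
#' identical folds — the paired design the block search relies on.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels; each class needs at least `k` members.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for the fold partition.
#' @inheritParams fit_qda
#' @return An object of class `cv_error_estimate`: list with `error_rate`,
#'   `k`, `fold_errors` (per-fold error fractions), `n` and `seed`.
#' @examples
#' d <- simulate_scenario(scenario_spec("linear", seed = 3))
#' cv_error(d$X, d$y, seed = 3)$error_rate
#' @export
cv_error <- function(X, y, k = 10, seed = 1, priors = "empirical",
                     ridge = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  folds <- make_folds(y, k, seed)
  res <- cpp_cv_qda(X, y, folds, as.integer(k),
                    prior_code(priors), prior_values(priors),
                    if (is.null(ridge)) -1 else as.numeric(ridge))
  structure(
    list(error_rate = res$error_rate, k = as.integer(k),
         fold_errors = res$fold_errors, n = length(y),
         seed = as.integer(seed)),
    class = "cv_error_estimate"
  )
}

#' @export
print.cv_error_estimate <- function(x, ...) {
  cat(sprintf("cv_error_estimate: %.4f (%d-fold, n = %d, seed = %d)\n",
              x$error_rate, x$k, x$n, x$seed))
  invisible(x)
}

prior_code <- function(priors) {
  if (is.character(priors)) {
    switch(match.arg(priors, c("empirical", "balanced")),
           empirical = 0L, balanced = 1L)
  } else 2L
}

prior_values <- function(priors) {
  if (is.character(priors)) c(0.5, 0.5) else resolve_priors(priors, c(1, 1))
}

# Fast internal path: pooled CV error for a column subset under
# precomputed folds. Used by the detector and the peaking bench, where
# thousands of these are evaluated per run.
qda_cv_rate <- function(X, y, folds, k, priors = "empirical", ridge = NULL) {
  cpp_cv_qda(X, y, folds, as.integer(k),
             prior_code(priors), prior_values(priors),
             if (is.null(ridge)) -1 else as.numeric(ridge))$error_rate
}

#' QDA classifier adapter
#'
#' The packaged classifier adapter used by the peaking bench. An adapter is
#' a list with elements `fit(X, y) -> model` and `predict(model, X) ->
#' labels`; any classifier honouring this contract can be benchmarked in
#' place of QDA.
#'
#' @inheritParams fit_qda
#' @return A `classifier_adapter` object wrapping [fit_qda()] and
#'   [qda_predict()].
#' @export
qda_adapter <- function(priors = "empirical", ridge = NULL) {
  structure(
    list(
      fit = function(X, y) fit_qda(X, y, priors = priors, ridge = ridge),
      predict = function(model, X) qda_predict(model, X),
      priors = priors, ridge = ridge
    ),
    class = c("qda_adapter", "classifier_adapter")
  )
}

# Generic adapter-based CV, the slow path for external classifiers.
adapter_cv_rate <- function(adapter, X, y, folds, k) {
  miss <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    model <- adapter$fit(X[!test, , drop = FALSE], y[!test])
    miss <- miss + sum(adapter$predict(model, X[test, , drop = FALSE]) != y[test])
  }
  miss / length(y)
}
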