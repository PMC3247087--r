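#' Configure a peaking experiment
#'
#' Parameters shared by [peaking_curve()] and [overlap_experiment()]: which
#' planted scenario to embed, the grid of total feature-space dimensions,
#' the number of Monte-Carlo replicates, the CV folds and the classifier.
#'
#' @param scenario a [scenario_spec()] describing the planted pair.
#' @param p_grid increasing vector of total dimensions, minimum 2. The
#'   default grid 2, 5, 10, 15, 20, 30 spans the range over which QDA's
#'   resistance to added noise degrades.
#' @param B number of replicates (default 100).
#' @param k CV folds (default 10).
#' @param seed root seed; replicate `b` uses `seed + b` for both the signal
#'   and the noise arm, so arms are paired.
#' @param classifier a classifier adapter (see [qda_adapter()], the
#'   default). Any object with `fit(X, y)` and `predict(model, X)` elements
#'   can be plugged in.
#' @return An object of class `peaking_config`.
#' @export
peaking_config <- function(scenario, p_grid = c(2, 5, 10, 15, 20, 30),
                           B = 100, k = 10, seed = 1,
                           classifier = qda_adapter()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p_grid <- as.integer(p_grid)
  if (min(p_grid) < 2L) stop("p_grid entries must be >= 2")
  if (is.unsorted(p_grid, strictly = TRUE)) stop("p_grid must be increasing")
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  structure(
    list(scenario = scenario, p_grid = p_grid, B = B, k = as.integer(k),
         seed = as.integer(seed), classifier = classifier),
    class = "peaking_config"
  )
}

# Deterministic sub-stream derivation so e.g. the noise draw of a replicate
# never perturbs its signal draw; Lehmer-style mix kept below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream) %% 2147483647)
}

# Signal arm: the scenario pair embedded in p - 2 standard-normal noise
# features.
signal_dataset <- function(spec, p, seed) {
  spec$seed <- as.integer(seed)
  d <- simulate_scenario(spec)
  if (p > 2L) d <- add_noise_features(d, p - 2L, derive_seed(seed, 1L)) else d
}

replicate_rate <- function(config, data, seed) {
  folds <- make_folds(data$y, config$k, seed)
  cls <- config$classifier
  if (inherits(cls, "qda_adapter")) {
    qda_cv_rate(data$X, data$y, folds, config$k,
                priors = cls$priors, ridge = cls$ridge)
  } else {
    adapter_cv_rate(cls, data$X, data$y, folds, config$k)
  }
}

#' Error-versus-dimension peaking curve
#'
#' For each total dimension `p` on the grid, embeds the planted pair in
#' `p - 2` independent standard-normal noise features and records the
#' classifier's k-fold CV error, averaged over `B` replicates. Rising error
#' along the grid is the peaking phenomenon: at fixed sample size, added
#' uninformative features degrade the designed classifier until the signal
#' is indistinguishable from noise.
#'
#' @param config a [peaking_config()].
#' @return An object of class `peaking_curve`: list with `summary`
#'   (data.frame of `p`, `mean_error`) and `replicates` (data.frame of `p`,
#'   `replicate`, `error`).
#' @export
peaking_curve <- function(config) {
  stopifnot(inherits(config, "peaking_config"))
  rows <- expand.grid(replicate = seq_len(config$B), p = config$p_grid)
  rows$error <- NA_real_
  for (i in seq_len(nrow(rows))) {
    b <- rows$replicate[i]
    seed_b <- config$seed + b
    d <- signal_dataset(config$scenario, rows$p[i], seed_b)
    rows$error[i] <- tryCatch(
      replicate_rate(config, d, seed_b),
      error = function(e) stop(sprintf("classifier failed at p = %d: %s",
                                       rows$p[i], conditionMessage(e)))
    )
  }
  summary <- stats::aggregate(error ~ p, data = rows, FUN = mean)
  names(summary)[2] <- "mean_error"
  structure(
    list(summary = summary[order(summary$p), ],
         replicates = rows[, c("p", "replicate", "error")]),
    class = "peaking_curve"
  )
}

#' Overlap between two error-rate populations
#'
#' Standardizes the mean gap between two samples of error rates by their
#' pooled standard deviation (the univariate Mahalanobis distance `Delta`)
#' and reports the overlap `Phi(-Delta/2)` — under equal-covariance Gaussian
#' assumptions, the error rate of the linear discriminant separating the
#' two populations. An overlap of 0.5 means the populations are
#' indistinguishable; values near 0 mean a classifier score cleanly tells
#' signal-bearing feature chunks from pure-noise chunks.
#'
#' @param errors_a,errors_b numeric vectors of error rates (lengths may
#'   differ; the pooled SD weights by `length - 1`).
#' @return List with `delta` and `overlap`.
#' @export
overlap_measure <- function(errors_a, errors_b) {
  na <- length(errors_a); nb <- length(errors_b)
  stopifnot(na >= 2, nb >= 2)
  gap <- mean(errors_a) - mean(errors_b)
  if (gap == 0) {
    return(list(delta = 0, overlap = 0.5))
  }
  pooled_var <- ((na - 1) * stats::var(errors_a) +
                 (nb - 1) * stats::var(errors_b)) / (na + nb - 2)
  if (pooled_var <= 0) {
    stop("zero pooled variance with a nonzero mean gap: delta is undefined ",
         "(both error populations are constant)")
  }
  delta <- abs(gap) / sqrt(pooled_var)
  list(delta = delta, overlap = stats::pnorm(-delta / 2))
}

#' Signal-versus-noise overlap experiment
#'
#' For each dimension `p` on the grid, draws `B` signal-bearing datasets
#' (the planted pair plus `p - 2` noise features) and `B` pure-noise
#' datasets (`p` noise features), scores each by k-fold CV error, and
#' summarizes the separation of the two error populations by the
#' `Phi(-Delta/2)` overlap of [overlap_measure()]. Small overlap at a given
#' `p` means the classifier can still tell a feature chunk carrying the
#' planted interaction from a chunk of pure noise at that chunk size —
#' the property the blockwise search exploits.
#'
#' @param config a [peaking_config()] with `B >= 2`.
#' @return An object of class `overlap_experiment`: list with `summary`
#'   (data.frame of `p`, `delta`, `overlap`) and `errors` (data.frame of
#'   `p`, `arm` in \{"signal", "noise"\}, `replicate`, `error`).
#' @export
overlap_experiment <- function(config) {
  stopifnot(inherits(config, "peaking_config"))
  if (config$B < 2L) stop("overlap needs B >= 2 (variance of each arm)")
  spec <- config$scenario
  out_err <- vector("list", length(config$p_grid))
  out_sum <- vector("list", length(config$p_grid))
  for (j in seq_along(config$p_grid)) {
    p <- config$p_grid[j]
    es <- en <- numeric(config$B)
    for (b in seq_len(config$B)) {
      seed_b <- config$seed + b
      ds <- signal_dataset(spec, p, seed_b)
      dn <- simulate_noise_only(spec$n0, spec$n1, p, derive_seed(seed_b, 2L))
      es[b] <- replicate_rate(config, ds, seed_b)
      en[b] <- replicate_rate(config, dn, seed_b)
    }
    ov <- overlap_measure(es, en)
    out_sum[[j]] <- data.frame(p = p, delta = ov$delta, overlap = ov$overlap)
    out_err[[j]] <- data.frame(
      p = p, arm = rep(c("signal", "noise"), each = config$B),
      replicate = rep(seq_len(config$B), 2), error = c(es, en))
  }
  structure(
    list(summary = do.call(rbind, out_sum), errors = do.call(rbind, out_err)),
    class = "overlap_experiment"
  )
}
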