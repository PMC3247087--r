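#' Specify a synthetic weak-marginal / strong-bivariate scenario
#'
#' Four planted two-feature interaction patterns in which each feature alone
#' is (nearly) useless for telling the two classes apart, while the pair
#' jointly separates them:
#'
#' * `"linear"`: both classes bivariate normal with a shared covariance;
#'   class 0 centred at `mu0`, class 1 at `mu1`. With the default strongly
#'   correlated covariance the mean shift is almost orthogonal to the
#'   principal axis of the noise, so the marginals overlap heavily.
#' * `"xor"`: class 0 uniform on the two quadrants where the coordinates
#'   share a sign, class 1 on the two where the signs differ.
#' * `"circular"`: points standard bivariate normal; label 0 iff the squared
#'   radius is at most `r0sq`, label 1 iff it exceeds `r1sq` (points in
#'   between, when `r0sq < r1sq`, are rejected).
#' * `"vshape"`: `x1` uniform on \[-1, 1\]; class 0 has `x2` uniform on a
#'   band sitting on the curve `|x1|`, class 1 on a disjoint higher band.
#'
#' Scenario constants default to values chosen so that, at `n0 = n1 = 40`,
#' each marginal is weak while the pair separates the classes; all are
#' parameters so alternative geometries can be explored.
#'
#' @param scenario one of `"linear"`, `"xor"`, `"circular"`, `"vshape"`.
#' @param n0,n1 class sample sizes (non-negative, `n0 + n1 >= 1`).
#' @param seed integer RNG seed; the same spec and seed reproduce the
#'   dataset bit-identically.
#' @param mu0,mu1 linear scenario class means (length-2).
#' @param sigma linear scenario shared 2x2 covariance; must be symmetric
#'   positive-definite (checked by Cholesky factorization).
#' @param halfwidth xor scenario quadrant half-width.
#' @param r0sq,r1sq circular scenario squared-radius thresholds,
#'   `r0sq <= r1sq`; defaults are the chi-squared(2) median so classes are
#'   balanced in expectation with no gap.
#' @param band_offsets,band_widths vshape scenario: class-c `x2` is uniform
#'   on `[|x1| + band_offsets[c+1], |x1| + band_offsets[c+1] + band_widths[c+1]]`.
#'
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("linear", "xor", "circular", "vshape"),
                          n0 = 40, n1 = 40, seed = 1,
                          mu0 = c(0, 0), mu1 = c(-1, 1),
                          sigma = matrix(c(1, 0.9, 0.9, 1), 2, 2),
                          halfwidth = 1,
                          r0sq = stats::qchisq(0.5, df = 2),
                          r1sq = stats::qchisq(0.5, df = 2),
                          band_offsets = c(0, 0.5),
                          band_widths = c(0.3, 0.3)) {
  scenario <- match.arg(scenario)
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  if (n0 < 0L || n1 < 0L || n0 + n1 < 1L) {
    stop("need n0 >= 0, n1 >= 0 and n0 + n1 >= 1")
  }
  params <- switch(scenario,
    linear = {
      stopifnot(length(mu0) == 2, length(mu1) == 2,
                is.matrix(sigma), all(dim(sigma) == 2))
      if (max(abs(sigma - t(sigma))) > 1e-12) {
        stop("linear scenario covariance must be symmetric")
      }
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
      if (is.null(ch)) {
        stop("linear scenario covariance is not positive-definite")
      }
      list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1), sigma = sigma)
    },
    xor = {
      stopifnot(halfwidth > 0)
      list(halfwidth = halfwidth)
    },
    circular = {
      if (r0sq > r1sq) stop("circular scenario requires r0sq <= r1sq")
      stopifnot(r0sq > 0)
      list(r0sq = r0sq, r1sq = r1sq)
    },
    vshape = {
      stopifnot(length(band_offsets) == 2, length(band_widths) == 2,
                all(band_widths > 0))
      list(band_offsets = as.numeric(band_offsets),
           band_widths = as.numeric(band_widths))
    }
  )
  structure(
    list(scenario = scenario, n0 = n0, n1 = n1, params = params,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: %s, n0 = %d, n1 = %d, seed = %d\n",
              x$scenario, x$n0, x$n1, x$seed))
  invisible(x)
}

#' Simulate the two-feature interaction pattern of a scenario
#'
#' Draws `n0` class-0 and `n1` class-1 samples of the planted pair described
#' by `spec`. Rows are ordered class 0 first; the two columns are marked as
#' signal columns.
#'
#' @param spec a [scenario_spec()].
#' @return A [labeled_dataset()] with exactly two feature columns.
#' @examples
#' d <- simulate_scenario(scenario_spec("xor", seed = 7))
#' table(d$y)
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n0 <- spec$n0; n1 <- spec$n1; n <- n0 + n1
  X <- withr::with_seed(spec$seed, switch(spec$scenario,
    linear = {
      ch <- chol(spec$params$sigma)
      z <- matrix(stats::rnorm(2 * n), n, 2) %*% ch
      mu <- rbind(
        matrix(spec$params$mu0, n0, 2, byrow = TRUE),
        matrix(spec$params$mu1, n1, 2, byrow = TRUE)
      )
      z + mu
    },
    xor = {
      w <- spec$params$halfwidth
      s <- sample(c(-1, 1), n, replace = TRUE)
      u1 <- stats::runif(n, 0, w)
      u2 <- stats::runif(n, 0, w)
      # class 0 shares the sign across coordinates, class 1 flips it
      flip <- rep(c(1, -1), c(n0, n1))
      cbind(s * u1, s * flip * u2)
    },
    circular = {
      r0sq <- spec$params$r0sq; r1sq <- spec$params$r1sq
      acc0 <- matrix(numeric(0), 0, 2)
      acc1 <- matrix(numeric(0), 0, 2)
      while (nrow(acc0) < n0 || nrow(acc1) < n1) {
        m <- max(2 * n, 64L)
        z <- matrix(stats::rnorm(2 * m), m, 2)
        r2 <- z[, 1]^2 + z[, 2]^2
        if (nrow(acc0) < n0) acc0 <- rbind(acc0, z[r2 <= r0sq, , drop = FALSE])
        if (nrow(acc1) < n1) acc1 <- rbind(acc1, z[r2 > r1sq, , drop = FALSE])
      }
      rbind(acc0[seq_len(n0), , drop = FALSE],
            acc1[seq_len(n1), , drop = FALSE])
    },
    vshape = {
      off <- spec$params$band_offsets; wid <- spec$params$band_widths
      x1 <- stats::runif(n, -1, 1)
      lo <- abs(x1) + rep(off, c(n0, n1))
      x2 <- lo + stats::runif(n, 0, 1) * rep(wid, c(n0, n1))
      cbind(x1, x2)
    }
  ))
  dimnames(X) <- NULL
  labeled_dataset(
    X, rep(c(0L, 1L), c(n0, n1)),
    feature_ids = paste0(spec$scenario, c("_1", "_2")),
    signal_columns = 1:2
  )
}

#' Append independent standard-normal noise features
#'
#' Adds `p_noise` columns of i.i.d. N(0, 1) values, independent of the
#' labels, to an existing dataset — the high-dimensional embedding used
#' throughout the peaking experiments (e.g. a planted pair plus 198 noise
#' features makes the signal 1% of a 200-dimensional feature space). The
#' noise draw has its own seed so the signal columns are untouched.
#'
#' @param data a [labeled_dataset()].
#' @param p_noise number of noise columns to append (>= 0).
#' @param seed integer RNG seed for the noise draw.
#' @return A [labeled_dataset()] with `ncol(data$X) + p_noise` features;
#'   `signal_columns` preserved, noise columns named `"noise_0001"` etc.
#' @export
add_noise_features <- function(data, p_noise, seed) {
  stopifnot(inherits(data, "labeled_dataset"))
  p_noise <- as.integer(p_noise)
  if (p_noise < 0L) stop("p_noise must be >= 0")
  if (p_noise == 0L) return(data)
  n <- nrow(data$X)
  E <- withr::with_seed(seed, matrix(stats::rnorm(n * p_noise), n, p_noise))
  ids <- make.unique(c(data$feature_ids,
                       sprintf("noise_%04d", seq_len(p_noise))))
  labeled_dataset(cbind(data$X, E), data$y,
                  feature_ids = ids,
                  signal_columns = data$signal_columns)
}

#' Simulate a dataset of pure noise
#'
#' `n0 + n1` samples of `p` i.i.d. standard-normal features with labels
#' carrying no information about the matrix — the null arm of the
#' signal-versus-noise overlap experiment.
#'
#' @param n0,n1 class sample sizes.
#' @param p number of features (>= 1).
#' @param seed integer RNG seed.
#' @return A [labeled_dataset()] with empty `signal_columns`.
#' @export
simulate_noise_only <- function(n0, n1, p, seed) {
  n0 <- as.integer(n0); n1 <- as.integer(n1); p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  if (n0 < 0L || n1 < 0L || n0 + n1 < 1L) stop("need n0 + n1 >= 1")
  n <- n0 + n1
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  labeled_dataset(X, rep(c(0L, 1L), c(n0, n1)),
                  feature_ids = sprintf("noise_%04d", seq_len(p)))
}
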