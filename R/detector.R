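#' Configure the blockwise interaction search
#'
#' The search fits QDA on unions of two feature blocks, so every fit sees at
#' most `2 * bsize` features. The block size is constrained by the
#' classifier's resistance to peaking: `2 * bsize` must not exceed the
#' resistance threshold `p_star` (default 10), the chunk size up to which
#' the CV error of a signal-bearing chunk remains well separated from that
#' of pure noise.
#'
#' @param bsize block size (default 5).
#' @param p_star peaking-resistance threshold; configurations with
#'   `2 * bsize > p_star` are rejected.
#' @param k CV folds (default 10).
#' @param seed integer seed controlling the fold partition (and the optional
#'   feature shuffle).
#' @param top_m number of top-ranked block matchings refined in the second
#'   stage (default 6).
#' @param shuffle_features if `TRUE`, features are assigned to blocks in a
#'   seeded random order rather than column order — a robustness check on
#'   the order-dependence of the partition.
#' @return An object of class `block_search_config`.
#' @export
block_search_config <- function(bsize = 5, p_star = 10, k = 10, seed = 1,
                                top_m = 6, shuffle_features = FALSE) {
  bsize <- as.integer(bsize); p_star <- as.integer(p_star)
  top_m <- as.integer(top_m)
  if (bsize < 1L) stop("bsize must be >= 1")
  if (top_m < 1L) stop("top_m must be >= 1")
  if (2L * bsize > p_star) {
    stop(sprintf(
      "2 * bsize = %d exceeds the peaking-resistance threshold p_star = %d; use a smaller block size",
      2L * bsize, p_star))
  }
  structure(
    list(bsize = bsize, p_star = p_star, k = as.integer(k),
         seed = as.integer(seed), top_m = top_m,
         shuffle_features = isTRUE(shuffle_features)),
    class = "block_search_config"
  )
}

#' Partition feature indices into blocks
#'
#' Consecutive blocks of `bsize` indices in column order (optionally after a
#' seeded shuffle); when `bsize` does not divide `p` the last block holds
#' the remainder.
#'
#' @param p number of features (>= 2).
#' @param bsize block size (>= 1).
#' @param shuffle shuffle feature order before blocking?
#' @param seed seed for the shuffle (ignored when `shuffle = FALSE`).
#' @return List of integer vectors partitioning `1:p`; length
#'   `ceiling(p / bsize)`.
#' @examples
#' length(partition_blocks(2000, 5))  # 400 blocks
#' @export
partition_blocks <- function(p, bsize, shuffle = FALSE, seed = 1) {
  p <- as.integer(p); bsize <- as.integer(bsize)
  if (p < 2L) stop("p must be >= 2")
  if (bsize < 1L) stop("bsize must be >= 1")
  idx <- seq_len(p)
  if (isTRUE(shuffle)) idx <- withr::with_seed(seed, sample(idx))
  unname(split(idx, ceiling(seq_len(p) / bsize)))
}

#' Fit counts of the blockwise versus the exhaustive search
#'
#' The naive exhaustive pair search needs `p (p - 1) / 2` QDA fits; the
#' blockwise first stage needs only one fit per unordered pair of the
#' `ceiling(p / bsize)` blocks. For `p = 2000` genes and `bsize = 5` that
#' is 79800 blockwise fits against 1999000 exhaustive ones.
#'
#' @param p number of features (>= 2).
#' @param bsize block size.
#' @return Named list with `n_blocks`, `blockwise_fits`, `exhaustive_fits`.
#' @export
count_fits <- function(p, bsize) {
  p <- as.integer(p); bsize <- as.integer(bsize)
  if (p < 2L) stop("p must be >= 2")
  if (bsize < 1L) stop("bsize must be >= 1")
  nb <- ceiling(p / bsize)
  list(n_blocks = as.integer(nb),
       blockwise_fits = nb * (nb - 1) / 2,
       exhaustive_fits = as.double(p) * (p - 1) / 2)
}

#' Rank all block matchings by cross-validated QDA error
#'
#' Stage one of the detector: partitions the features into blocks and, for
#' every unordered pair of distinct blocks, fits QDA by k-fold CV on the
#' union of their features. A matching whose union contains a planted
#' bivariate interaction attains a low error; matchings of pure noise sit
#' near 0.5. All matchings share one fold partition (derived from the
#' config seed), so their errors are directly comparable.
#'
#' @param data a [labeled_dataset()]; both classes need at least `k`
#'   samples.
#' @param config a [block_search_config()].
#' @return An object of class `block_matching_ranking`: list with `blocks`
#'   (the partition), `matchings` (data.frame of `block_a`, `block_b`,
#'   `cv_error`, sorted ascending by error with lexicographic tie-break)
#'   and `n_fits`.
#' @export
rank_block_matchings <- function(data, config) {
  stopifnot(inherits(data, "labeled_dataset"),
            inherits(config, "block_search_config"))
  p <- ncol(data$X)
  blocks <- partition_blocks(p, config$bsize, config$shuffle_features,
                             config$seed)
  nb <- length(blocks)
  if (nb < 2L) stop("need at least two blocks; reduce bsize")
  folds <- make_folds(data$y, config$k, config$seed)
  pairs <- utils::combn(nb, 2)
  errs <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cols <- c(blocks[[a]], blocks[[b]])
    errs[i] <- tryCatch(
      qda_cv_rate(data$X[, cols, drop = FALSE], data$y, folds, config$k),
      error = function(e) stop(sprintf(
        "CV failed for block matching (%d, %d): %s", a, b,
        conditionMessage(e)))
    )
  }
  m <- data.frame(block_a = pairs[1, ], block_b = pairs[2, ],
                  cv_error = errs)
  m <- m[order(m$cv_error, m$block_a, m$block_b), ]
  rownames(m) <- NULL
  structure(
    list(blocks = blocks, matchings = m, n_fits = nb * (nb - 1) / 2),
    class = "block_matching_ranking"
  )
}

#' @export
print.block_matching_ranking <- function(x, n = 6, ...) {
  cat(sprintf("block_matching_ranking: %d blocks, %d matchings\n",
              length(x$blocks), x$n_fits))
  print(utils::head(x$matchings, n))
  invisible(x)
}

#' Pairwise QDA error heat matrix over a feature subset
#'
#' Stage two of the detector: scores every unordered pair of features in
#' `feature_subset` by two-feature QDA CV error (off-diagonal) and every
#' single feature by univariate QDA CV error (diagonal). Low off-diagonal
#' cells ("hot spots") localize bivariate interactions; a low diagonal
#' entry exposes a feature that is not so weak marginally.
#'
#' @param data a [labeled_dataset()].
#' @param feature_subset integer vector of at least two column indices.
#' @param config a [block_search_config()]; its seed fixes the shared fold
#'   partition.
#' @return An object of class `heat_matrix`: list with `feature_subset`,
#'   `feature_ids` and `errors` (symmetric matrix with univariate errors on
#'   the diagonal).
#' @export
pairwise_heatmatrix <- function(data, feature_subset, config) {
  stopifnot(inherits(data, "labeled_dataset"),
            inherits(config, "block_search_config"))
  feature_subset <- as.integer(feature_subset)
  m <- length(feature_subset)
  if (m < 2L) stop("feature_subset needs at least two features")
  if (any(feature_subset < 1L) || any(feature_subset > ncol(data$X))) {
    stop("feature_subset out of range")
  }
  folds <- make_folds(data$y, config$k, config$seed)
  E <- matrix(NA_real_, m, m,
              dimnames = list(data$feature_ids[feature_subset],
                              data$feature_ids[feature_subset]))
  for (i in seq_len(m)) {
    E[i, i] <- qda_cv_rate(data$X[, feature_subset[i], drop = FALSE],
                           data$y, folds, config$k)
    if (i < m) {
      for (j in (i + 1L):m) {
        e <- tryCatch(
          qda_cv_rate(data$X[, feature_subset[c(i, j)], drop = FALSE],
                      data$y, folds, config$k),
          error = function(err) stop(sprintf(
            "CV failed for feature pair (%s, %s): %s",
            data$feature_ids[feature_subset[i]],
            data$feature_ids[feature_subset[j]],
            conditionMessage(err)))
        )
        E[i, j] <- E[j, i] <- e
      }
    }
  }
  structure(
    list(feature_subset = feature_subset,
         feature_ids = data$feature_ids[feature_subset], errors = E),
    class = "heat_matrix"
  )
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf("heat_matrix: %d features, min off-diagonal error %.4f\n",
              length(x$feature_subset),
              min(x$errors[upper.tri(x$errors)])))
  invisible(x)
}

#' Detect weak-marginal / strong-bivariate interactions
#'
#' The full two-stage search: rank all block matchings by QDA CV error,
#' take the `top_m` best, build the pairwise error heat matrix over the
#' union of each top matching's blocks, pool all scored pairs and return
#' them sorted by error. The top of the list localizes feature pairs whose
#' joint distribution separates the classes even though each feature alone
#' does not.
#'
#' @inheritParams rank_block_matchings
#' @return An object of class `interaction_ranking`: list with `pairs` (a
#'   data.frame of `feature_i`, `feature_j` (ids), `col_i`, `col_j`
#'   (column indices, `col_i < col_j`), `cv_error` and
#'   `source_matching_rank`, sorted ascending by error with lexicographic
#'   tie-break), plus the stage-1 `ranking` and the per-matching
#'   `heatmatrices`.
#' @examples
#' \donttest{
#' d <- add_noise_features(simulate_scenario(scenario_spec("xor", seed = 2)),
#'                         48, seed = 3)
#' det <- detect_interactions(d, block_search_config(seed = 2))
#' head(det$pairs)
#' }
#' @export
detect_interactions <- function(data, config) {
  ranking <- rank_block_matchings(data, config)
  top <- utils::head(ranking$matchings, config$top_m)
  heats <- vector("list", nrow(top))
  seen <- new.env(hash = TRUE)
  rows <- vector("list", nrow(top))
  for (r in seq_len(nrow(top))) {
    subset <- sort(c(ranking$blocks[[top$block_a[r]]],
                     ranking$blocks[[top$block_b[r]]]))
    heats[[r]] <- pairwise_heatmatrix(data, subset, config)
    E <- heats[[r]]$errors
    m <- length(subset)
    keep <- list()
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- paste0(subset[i], "_", subset[j])
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          keep[[length(keep) + 1L]] <- data.frame(
            col_i = subset[i], col_j = subset[j],
            cv_error = E[i, j], source_matching_rank = r)
        }
      }
    }
    rows[[r]] <- do.call(rbind, keep)
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(pairs$cv_error, pairs$col_i, pairs$col_j), ]
  rownames(pairs) <- NULL
  pairs <- cbind(
    data.frame(feature_i = data$feature_ids[pairs$col_i],
               feature_j = data$feature_ids[pairs$col_j]),
    pairs)
  structure(
    list(pairs = pairs, ranking = ranking, heatmatrices = heats),
    class = "interaction_ranking"
  )
}

#' @export
print.interaction_ranking <- function(x, n = 10, ...) {
  cat(sprintf("interaction_ranking: %d scored pairs from top %d matchings\n",
              nrow(x$pairs), length(x$heatmatrices)))
  print(utils::head(x$pairs, n))
  invisible(x)
}

#' Screen out the strongest marginal features
#'
#' Removes the `n_remove` features with the highest importance scores (ties
#' broken by column order) before the interaction search. Strong marginal
#' features are exactly what the search is not looking for, and screening
#' them (e.g. by a random-forest mean-decrease-Gini ranking computed
#' externally) keeps them from dominating the block matchings. This
#' operation only applies the cut; how the importance vector is produced is
#' up to the caller.
#'
#' @param data a [labeled_dataset()].
#' @param importance numeric vector, one score per feature.
#' @param n_remove how many top-importance features to put aside; must
#'   leave at least one feature.
#' @return List with `screened` (the reduced dataset) and `removed` (the
#'   ids of the features put aside, in column order).
#' @export
screen_by_importance <- function(data, importance, n_remove) {
  stopifnot(inherits(data, "labeled_dataset"))
  p <- ncol(data$X)
  if (length(importance) != p) {
    stop(sprintf("importance has length %d but there are %d features",
                 length(importance), p))
  }
  n_remove <- as.integer(n_remove)
  if (n_remove >= p) stop("n_remove must leave at least one feature")
  if (n_remove == 0L) {
    return(list(screened = data, removed = character(0)))
  }
  ord <- order(-as.numeric(importance), seq_len(p))
  removed <- sort(ord[seq_len(n_remove)])
  list(screened = subset_features(data, setdiff(seq_len(p), removed)),
       removed = data$feature_ids[removed])
}

#' Drop exactly duplicated feature columns
#'
#' Removes every column whose values are identical to an earlier column,
#' keeping the first occurrence — duplicated probes would otherwise be
#' scored twice by the pair search.
#'
#' @param data a [labeled_dataset()].
#' @return A [labeled_dataset()] without duplicated columns.
#' @export
drop_duplicate_features <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  dup <- duplicated(data$X, MARGIN = 2)
  if (!any(dup)) return(data)
  subset_features(data, which(!dup))
}
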