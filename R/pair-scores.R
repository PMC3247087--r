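#' Top scoring pair (TSP) statistic
#'
#' The absolute between-class difference in the within-class empirical
#' probability that feature `i` is below feature `j`:
#' `| P(xi < xj | y = 0) - P(xi < xj | y = 1) |`. A rank-based score: it is
#' invariant under any strictly monotone transformation applied jointly to
#' the two features. Ties `xi == xj` contribute 1/2 to the within-class
#' fraction (midrank convention).
#'
#' @param xi,xj numeric sample vectors of equal length.
#' @param y binary labels; both classes must be present.
#' @return A scalar in \[0, 1\].
#' @export
tsp_score <- function(xi, xj, y) {
  y <- as.integer(y)
  stopifnot(length(xi) == length(xj), length(xi) == length(y))
  if (!all(c(0L, 1L) %in% y)) stop("both classes must be present")
  frac <- function(cls) {
    lt <- xi[y == cls] < xj[y == cls]
    eq <- xi[y == cls] == xj[y == cls]
    mean(lt + 0.5 * eq)
  }
  abs(frac(0L) - frac(1L))
}

#' CorScor gap statistic
#'
#' The absolute difference of the within-class Pearson correlations of a
#' feature pair, `| r_0 - r_1 |`, on the scale \[0, 2\]. A large value
#' means the dependence between the two features changes with the class
#' (the gap/substitution pattern); like TSP it is blind to interaction
#' shapes that leave the within-class correlations unchanged.
#'
#' @inheritParams tsp_score
#' @return A scalar in \[0, 2\].
#' @export
corscor_score <- function(xi, xj, y) {
  y <- as.integer(y)
  stopifnot(length(xi) == length(xj), length(xi) == length(y))
  if (!all(c(0L, 1L) %in% y)) stop("both classes must be present")
  r <- vapply(c(0L, 1L), function(cls) {
    a <- xi[y == cls]; b <- xj[y == cls]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop(sprintf("zero within-class variance in class %d (feature %s)",
                   cls, if (stats::sd(a) == 0) "i" else "j"))
    }
    stats::cor(a, b)
  }, numeric(1))
  abs(r[1] - r[2])
}

#' Attach TSP and CorScor scores to a table of feature pairs
#'
#' Convenience wrapper used to compare the detector's selections against
#' the two classical pair-association indexes.
#'
#' @param data a [labeled_dataset()].
#' @param pairs data.frame with columns `col_i` and `col_j` (column
#'   indices), e.g. the `pairs` element of [detect_interactions()].
#' @return `pairs` with `tsp` and `corscor` columns appended.
#' @export
score_pairs <- function(data, pairs) {
  stopifnot(inherits(data, "labeled_dataset"),
            all(c("col_i", "col_j") %in% names(pairs)))
  pairs$tsp <- mapply(function(i, j)
    tsp_score(data$X[, i], data$X[, j], data$y),
    pairs$col_i, pairs$col_j)
  pairs$corscor <- mapply(function(i, j)
    corscor_score(data$X[, i], data$X[, j], data$y),
    pairs$col_i, pairs$col_j)
  pairs
}
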