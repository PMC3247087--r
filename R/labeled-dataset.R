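#' Labelled expression dataset
#'
#' Container for a samples x features numeric matrix with a binary class
#' label per sample. This is the common currency of the package: scenario
#' simulators produce it, the detector and the pair scores consume it.
#'
#' @param X numeric matrix, samples in rows, features in columns. No missing
#'   values are allowed.
#' @param y binary label vector of length `nrow(X)`; coerced to integer
#'   values in \{0, 1\}.
#' @param feature_ids character vector of unique feature identifiers, one per
#'   column. Defaults to the column names of `X`, or `"f_0001"`-style names.
#' @param signal_columns optional integer vector of column indices known to
#'   carry a planted signal. Simulation bookkeeping only; never used by the
#'   detector itself.
#'
#' @return An object of class `labeled_dataset`: a list with elements `X`
#'   (the matrix, with `feature_ids` as column names), `y`, `feature_ids`
#'   and `signal_columns`.
#' @seealso [simulate_scenario()], [detect_interactions()]
#' @export
labeled_dataset <- function(X, y, feature_ids = NULL, signal_columns = integer(0)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("X contains missing values")
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop(sprintf("length(y) == %d but X has %d rows", length(y), nrow(X)))
  }
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(X)
    if (is.null(feature_ids)) {
      feature_ids <- sprintf("f_%04d", seq_len(ncol(X)))
    }
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X)) stop("one feature id per column required")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  signal_columns <- as.integer(signal_columns)
  if (length(signal_columns) &&
      (any(signal_columns < 1L) || any(signal_columns > ncol(X)))) {
    stop("signal_columns out of range")
  }
  colnames(X) <- feature_ids
  structure(
    list(X = X, y = y, feature_ids = feature_ids,
         signal_columns = signal_columns),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset: %d samples x %d features (class 0: %d, class 1: %d)\n",
    nrow(x$X), ncol(x$X), sum(x$y == 0L), sum(x$y == 1L)
  ))
  if (length(x$signal_columns)) {
    cat("  planted signal columns:",
        paste(x$signal_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$X)

# Internal: subset columns, keeping bookkeeping consistent.
subset_features <- function(data, cols) {
  cols <- as.integer(cols)
  keep_signal <- match(data$signal_columns, cols)
  labeled_dataset(
    data$X[, cols, drop = FALSE], data$y,
    feature_ids = data$feature_ids[cols],
    signal_columns = keep_signal[!is.na(keep_signal)]
  )
}
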