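#' Read an expression matrix and labels from delimited files
#'
#' The matrix file must have a header row; the delimiter is sniffed from
#' the extension (`.tsv`/`.txt` tab, otherwise comma) unless given. With
#' `orientation = "features_in_rows"` the matrix is transposed after
#' reading, so either layout yields a samples x features dataset. The
#' labels file holds one value per sample in a single column (header
#' optional), coercible to 0/1.
#'
#' @param matrix_path path to the expression matrix.
#' @param labels_path path to the label column.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"`.
#' @param sep field delimiter; `NULL` (default) sniffs from the extension.
#' @return A [labeled_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path,
                            orientation = c("samples_in_rows",
                                            "features_in_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", matrix_path, ignore.case = TRUE))
      "\t" else ","
  }
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  bad <- !vapply(tab, is.numeric, logical(1))
  if (any(bad)) {
    stop(sprintf("non-numeric column(s) in %s: %s", matrix_path,
                 paste(names(tab)[bad], collapse = ", ")))
  }
  X <- as.matrix(tab)
  if (orientation == "features_in_rows") {
    ids <- rownames(X)
    X <- t(X)
    colnames(X) <- ids
  }
  ylab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                            stringsAsFactors = FALSE)[[1]]
  if (is.character(ylab) && !ylab[1] %in% c("0", "1")) ylab <- ylab[-1]
  yn <- suppressWarnings(as.numeric(ylab))
  if (anyNA(yn) || !all(yn %in% c(0, 1))) {
    stop(sprintf("labels in %s must be binary 0/1 (offending value near line %d)",
                 labels_path, which(is.na(yn) | !(yn %in% c(0, 1)))[1]))
  }
  if (length(yn) != nrow(X)) {
    stop(sprintf("%d samples in %s but %d labels in %s",
                 nrow(X), matrix_path, length(yn), labels_path))
  }
  labeled_dataset(X, as.integer(yn))
}

#' Write an expression dataset to delimited files
#'
#' Inverse of [read_expression()] for the samples-in-rows layout: the
#' matrix goes out as delimited text with a header row of feature ids, the
#' labels as a single 0/1 column.
#'
#' @param data a [labeled_dataset()].
#' @param matrix_path,labels_path output paths; the delimiter is sniffed
#'   from the matrix extension as in [read_expression()].
#' @return Invisibly, `data`.
#' @export
write_expression <- function(data, matrix_path, labels_path) {
  stopifnot(inherits(data, "labeled_dataset"))
  for (d in unique(dirname(c(matrix_path, labels_path)))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  sep <- if (grepl("\\.(tsv|txt)$", matrix_path, ignore.case = TRUE))
    "\t" else ","
  utils::write.table(data$X, matrix_path, sep = sep, row.names = FALSE,
                     col.names = data$feature_ids, quote = FALSE)
  utils::write.table(data$y, labels_path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Preprocess an expression dataset
#'
#' The standard recipe before the interaction search: remove excluded
#' samples (1-based row indices, matching the case numbering of published
#' outlier lists), then optionally natural-log transform, then optionally
#' standardize each feature to mean 0 and SD 1. Exclusions are applied
#' before any statistic is computed.
#'
#' @param data a [labeled_dataset()].
#' @param log_transform natural-log transform the matrix? Requires all
#'   values strictly positive.
#' @param standardize centre and scale each feature?
#' @param sample_exclusions integer vector of 1-based sample indices to
#'   drop (e.g. a user-supplied outlier list).
#' @return A [labeled_dataset()].
#' @export
preprocess_expression <- function(data, log_transform = FALSE,
                                  standardize = FALSE,
                                  sample_exclusions = integer(0)) {
  stopifnot(inherits(data, "labeled_dataset"))
  X <- data$X
  y <- data$y
  if (length(sample_exclusions)) {
    sample_exclusions <- as.integer(sample_exclusions)
    if (any(sample_exclusions < 1L) || any(sample_exclusions > nrow(X))) {
      stop("sample_exclusions out of range (1-based sample indices)")
    }
    keep <- setdiff(seq_len(nrow(X)), sample_exclusions)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (log_transform) {
    if (any(X <= 0)) {
      bad <- which(X <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "log transform needs strictly positive values; sample %d, feature %s is %g",
        bad[1], colnames(X)[bad[2]], X[bad[1], bad[2]]))
    }
    X <- log(X)
  }
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance feature under standardization: ",
           colnames(X)[which(sds == 0)[1]])
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  labeled_dataset(X, y, feature_ids = data$feature_ids,
                  signal_columns = data$signal_columns)
}
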