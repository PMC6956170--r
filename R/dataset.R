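#' Labeled dataset container
#'
#' The tabular carrier consumed by all classifiers: a numeric feature
#' matrix, a class label per row, and an ordered class set. Labels are
#' stored as character; the class order (sorted unique labels by default)
#' is the tie-breaking order used throughout the package (one-vs-one vote
#' ties, window-label ties).
#'
#' @param X Numeric matrix or data frame, one observation per row.
#' @param y Vector of class labels, one per row of `X`.
#' @param classes Optional ordered character vector of distinct labels;
#'   defaults to `sort(unique(y))`. Must cover every label in `y`.
#' @return An object of class `labeled_dataset` with fields `X`, `y`,
#'   `classes`.
#' @export
labeled_dataset <- function(X, y, classes = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("`X` must have at least one row and one column", call. = FALSE)
  }
  y <- as.character(y)
  if (length(y) != nrow(X)) {
    stop(sprintf("length(y) = %d but nrow(X) = %d", length(y), nrow(X)),
         call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(y))
  classes <- as.character(classes)
  if (!all(y %in% classes)) {
    stop("`classes` does not cover every label in `y`", call. = FALSE)
  }
  if (anyDuplicated(classes)) stop("`classes` must be distinct", call. = FALSE)
  structure(list(X = X, y = y, classes = classes), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d samples x %d features, %d classes (%s)>\n",
              nrow(x$X), ncol(x$X), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

as_labeled_dataset <- function(x) {
  if (inherits(x, "labeled_dataset")) return(x)
  stop("expected a `labeled_dataset`", call. = FALSE)
}
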