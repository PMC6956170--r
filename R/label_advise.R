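#' Numeric label encodings
#'
#' Makes distances between class labels well-defined by mapping each
#' class to a numeric vector. Three schemes are supported:
#' \itemize{
#'   \item `signed_binary`: exactly two classes, mapped (in class order)
#'     to -1 and +1. Pairwise label distance is then 0 or 2.
#'   \item `one_hot`: L classes mapped to the L unit basis vectors;
#'     distinct classes sit at distance \eqn{\sqrt 2}.
#'   \item `integer_code`: classes mapped to 1, 2, ..., L.
#' }
#' The mapping is injective and deterministic (classes in sorted class
#' order), so decoding restores the original labels exactly.
#'
#' @param labels Character vector of class labels to encode.
#' @param scheme Encoding scheme.
#' @param classes Optional ordered class set; defaults to
#'   `sort(unique(labels))`.
#' @return A list with `matrix` (one encoded row per input label) and
#'   `encoding` (a `label_encoding` object with fields `scheme`, `classes`
#'   and `mapping`, the L x m matrix of class codes).
#' @export
encode_labels <- function(labels,
                          scheme = c("signed_binary", "one_hot", "integer_code"),
                          classes = NULL) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  enc <- fit_label_encoding(classes, scheme)
  list(matrix = enc$mapping[labels, , drop = FALSE], encoding = enc)
}

fit_label_encoding <- function(classes,
                               scheme = c("signed_binary", "one_hot", "integer_code")) {
  scheme <- match.arg(scheme)
  classes <- as.character(classes)
  L <- length(classes)
  if (L < 2L) stop("at least two distinct classes are required", call. = FALSE)
  mapping <- switch(scheme,
    signed_binary = {
      if (L != 2L) {
        stop(sprintf("signed_binary requires exactly 2 classes, got %d", L),
             call. = FALSE)
      }
      matrix(c(-1, 1), ncol = 1L)
    },
    one_hot = diag(L),
    integer_code = matrix(seq_len(L), ncol = 1L)
  )
  rownames(mapping) <- classes
  structure(list(scheme = scheme, classes = classes, mapping = mapping),
            class = "label_encoding")
}

#' @rdname encode_labels
#' @param encoding A `label_encoding`.
#' @param M Matrix of encoded rows.
#' @return `decode_labels()` returns the character labels whose codes are
#'   nearest (Euclidean) to each row of `M`.
#' @export
decode_labels <- function(encoding, M) {
  stopifnot(inherits(encoding, "label_encoding"))
  M <- as_row_matrix(M)
  idx <- apply(M, 1L, function(r) {
    which.min(colSums((t(encoding$mapping) - r)^2))
  })
  encoding$classes[idx]
}

# Distance matrix between encoded label rows A and B: plain Euclidean on
# the encodings, or kernel-induced when a label kernel is supplied.
label_distance_matrix <- function(A, B, label_kernel = NULL) {
  A <- as_row_matrix(A); B <- as_row_matrix(B)
  if (is.null(label_kernel)) {
    G <- A %*% t(B)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    induced_distance_matrix(label_kernel, A, B)
  }
}

#' Label-space neighborhood lengths
#'
#' For each misclassified point, the neighborhood length is measured
#' between encoded class labels instead of feature vectors:
#' \eqn{NL(y_i) = \min_j \{ d(y_i, y_j) : j \notin MD,\ y_j \ne y_i \}},
#' where d is Euclidean distance on the encodings or, when `label_kernel`
#' is supplied, the kernel-induced form
#' \eqn{(k(y_i,y_i) + k(y_j,y_j) - 2k(y_i,y_j))^{1/2}} with an RBF on
#' labels. With the signed binary encoding and plain distance, every
#' misclassified point with a qualifying neighbor has NL = 2.
#'
#' @param md A [find_misclassified()] result.
#' @param train The training [labeled_dataset()].
#' @param encoding A `label_encoding` fitted on the training classes.
#' @param label_kernel Optional [kernel_spec()] on encoded labels.
#' @return The `misclassified_set` with label-space `nl` filled in
#'   (`NA` flags points with no qualifying neighbor, excluded from
#'   advising).
#' @export
label_neighborhood_lengths <- function(md, train, encoding,
                                       label_kernel = NULL) {
  stopifnot(inherits(md, "misclassified_set"),
            inherits(encoding, "label_encoding"))
  train <- as_labeled_dataset(train)
  if (length(md$indices) == 0L) return(md)
  keep <- setdiff(seq_len(nrow(train$X)), md$indices)
  if (length(keep) == 0L) return(md)
  ykeep <- train$y[keep]
  # distances depend only on the label pair: one row per class suffices
  Dcls <- label_distance_matrix(encoding$mapping, encoding$mapping,
                                label_kernel)
  md$nl <- vapply(seq_along(md$indices), function(i) {
    other <- unique(ykeep[ykeep != md$labels[i]])
    if (length(other) == 0L) return(NA_real_)
    min(Dcls[match(md$labels[i], encoding$classes),
             match(other, encoding$classes)])
  }, numeric(1))
  md
}

# Per-class label-advised weights and qualifying sets for an advised_fit
# in label space. Row c of `qualify` marks which active MD points qualify
# when the base prediction is class c; `law[c]` is the corresponding LAW.
label_weight_table <- function(adv) {
  act <- which(!is.na(adv$md$nl))
  classes <- adv$encoding$classes
  mdy <- adv$md$labels[act]
  nl <- adv$md$nl[act]
  Dcls <- label_distance_matrix(adv$encoding$mapping, adv$encoding$mapping,
                                adv$label_kernel)
  D <- Dcls[, match(mdy, classes), drop = FALSE] # L x |act|
  Q <- sweep(D, 2L, nl, "<=")
  contrib <- (1 - sweep(D, 2L, nl, "/")) * Q
  cnt <- rowSums(Q)
  law <- ifelse(cnt > 0, rowSums(contrib) / pmax(cnt, 1L), 0)
  list(classes = classes, law = as.numeric(law), qualify = Q)
}

#' Label-space advised weight (LAW)
#'
#' The label advised weight scores how close the base SVM's *predicted*
#' label sits to the labels of the misclassified training set: with
#' qualifying set \eqn{S = \{ x_i \in MD : d(\hat y, y_i) \le NL(y_i) \}}
#' over label distances, \eqn{LAW(\hat y)} is the mean of
#' \eqn{1 - d(\hat y, y_i)/NL(y_i)} over S, and 0 when MD or S is empty.
#' The true test label is unknown at prediction time, so the base
#' prediction stands in for it. With two classes and plain signed
#' encoding the whole of MD qualifies (distances are 0 or 2, NL = 2) and
#' LAW reduces to the fraction of MD sharing the predicted label.
#'
#' @param adv An `advised_fit` with `space = "label"`.
#' @param labels Character vector of (predicted) class labels.
#' @return Numeric vector of label advised weights in \[0, 1\].
#' @export
label_advised_weight <- function(adv, labels) {
  stopifnot(inherits(adv, "advised_fit"), adv$space == "label")
  labels <- as.character(labels)
  if (length(which(!is.na(adv$md$nl))) == 0L) return(numeric(length(labels)))
  lw <- label_weight_table(adv)
  lw$law[match(labels, lw$classes)]
}

#' @rdname predict.advised_fit
#' @export
lsa_predict <- function(adv, Xtest) {
  stopifnot(inherits(adv, "advised_fit"), adv$space == "label")
  predict(adv, Xtest)
}
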