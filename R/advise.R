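#' Misclassified training set (MD)
#'
#' Training points whose fitted-model prediction disagrees with their
#' label. The misclassified set is the information source of the
#' self-advising layers: each of its points later receives a neighborhood
#' length (NL) bounding its advisory influence.
#'
#' @param base A fitted `svm_fit`.
#' @param train The [labeled_dataset()] the model was trained on.
#' @return An object of class `misclassified_set` with fields `indices`
#'   (training-row indices), `points` (their feature vectors), `labels`
#'   (their true labels) and `nl` (neighborhood lengths, `NA` until
#'   computed; `NA` after computation flags a point with no qualifying
#'   neighbor, excluded from advising). May be empty.
#' @export
find_misclassified <- function(base, train) {
  stopifnot(inherits(base, "svm_fit"))
  train <- as_labeled_dataset(train)
  pred <- predict(base, train$X)
  idx <- which(pred != train$y)
  structure(
    list(indices = idx,
         points = train$X[idx, , drop = FALSE],
         labels = train$y[idx],
         nl = rep(NA_real_, length(idx))),
    class = "misclassified_set"
  )
}

#' @export
print.misclassified_set <- function(x, ...) {
  cat(sprintf("<misclassified_set: %d point(s), %d with a neighborhood length>\n",
              length(x$indices), sum(!is.na(x$nl))))
  invisible(x)
}

#' Feature-space neighborhood lengths
#'
#' For each misclassified point \eqn{x_i}, the neighborhood length is the
#' kernel-induced distance to the nearest correctly classified training
#' point of a different label:
#' \eqn{NL(x_i) = \min_j \{ d(x_i, x_j) : j \notin MD,\ y_j \ne y_i \}}.
#' Points with no qualifying neighbor keep `NA` and are excluded from
#' advising (no contrast information exists for them).
#'
#' @param md A [find_misclassified()] result.
#' @param train The training [labeled_dataset()] it was extracted from.
#' @param kernel The [kernel_spec()] inducing the distance.
#' @return The `misclassified_set` with `nl` filled in.
#' @export
neighborhood_lengths <- function(md, train, kernel) {
  stopifnot(inherits(md, "misclassified_set"))
  train <- as_labeled_dataset(train)
  if (length(md$indices) == 0L) return(md)
  keep <- setdiff(seq_len(nrow(train$X)), md$indices)
  if (length(keep) == 0L) return(md)
  D <- induced_distance_matrix(kernel, md$points,
                               train$X[keep, , drop = FALSE])
  yk <- train$y[keep]
  md$nl <- vapply(seq_along(md$indices), function(i) {
    ok <- yk != md$labels[i]
    if (!any(ok)) NA_real_ else min(D[i, ok])
  }, numeric(1))
  md
}

#' Attach a self-advising layer to a fitted SVM
#'
#' `self_advise()` builds the feature-space advising layer (SA-SVM):
#' it extracts the misclassified training set, computes kernel-induced
#' neighborhood lengths, and returns a model whose predictions may
#' override low-confidence base decisions with the true label of a nearby
#' misclassified point. `label_self_advise()` builds the label-space
#' variant (LSA-SVM): neighborhood lengths and advised weights are
#' computed on encoded class labels instead of feature vectors, which
#' makes the advising pass independent of the feature dimension.
#'
#' The advised-weight normalization is the mean of \eqn{1 - d/NL} over
#' qualifying misclassified points (recorded in the model as
#' `normalization = "mean"`).
#'
#' @param base A fitted `svm_fit`.
#' @param train The [labeled_dataset()] it was trained on.
#' @return An object of class `advised_fit` with fields `base`, `md`,
#'   `space` (`"feature"` or `"label"`), `normalization`, and for the
#'   label space additionally `encoding` and `label_kernel`.
#' @seealso [predict.advised_fit()], [advised_weight()],
#'   [label_advised_weight()]
#' @export
self_advise <- function(base, train) {
  stopifnot(inherits(base, "svm_fit"))
  train <- as_labeled_dataset(train)
  md <- neighborhood_lengths(find_misclassified(base, train), train,
                             base$kernel)
  structure(
    list(base = base, md = md, space = "feature", normalization = "mean"),
    class = "advised_fit"
  )
}

#' @rdname self_advise
#' @param scheme Label-encoding scheme for the label space; defaults to
#'   `"signed_binary"` for two classes and `"one_hot"` otherwise. See
#'   [encode_labels()].
#' @param label_kernel Optional [kernel_spec()] applied to encoded labels;
#'   when given, label distances use the kernel-induced form instead of
#'   plain Euclidean distance on the encodings.
#' @export
label_self_advise <- function(base, train, scheme = NULL,
                              label_kernel = NULL) {
  stopifnot(inherits(base, "svm_fit"))
  train <- as_labeled_dataset(train)
  if (is.null(scheme)) {
    scheme <- if (length(base$classes) == 2L) "signed_binary" else "one_hot"
  }
  enc <- fit_label_encoding(base$classes, scheme)
  md <- label_neighborhood_lengths(find_misclassified(base, train), train,
                                   enc, label_kernel)
  structure(
    list(base = base, md = md, space = "label", normalization = "mean",
         encoding = enc, label_kernel = label_kernel),
    class = "advised_fit"
  )
}

#' @export
print.advised_fit <- function(x, ...) {
  cat(sprintf("<advised_fit: %s-space advising (%s normalization), |MD| = %d>\n",
              x$space, x$normalization, length(x$md$indices)))
  print(x$base)
  invisible(x)
}

#' Feature-space advised weight
#'
#' The advised weight AW of a test point is a score in \[0, 1\] of how deep
#' the point sits inside the neighborhoods of the misclassified training
#' set: with \eqn{S = \{ x_i \in MD : d(x, x_i) \le NL(x_i) \}},
#' \eqn{AW(x) = |S|^{-1} \sum_{x_i \in S} (1 - d(x, x_i)/NL(x_i))}, and 0
#' when MD or S is empty. Distances are kernel-induced.
#'
#' @param adv An `advised_fit` with `space = "feature"`.
#' @param X Feature matrix (or single vector).
#' @return Numeric vector of advised weights in \[0, 1\].
#' @export
advised_weight <- function(adv, X) {
  stopifnot(inherits(adv, "advised_fit"), adv$space == "feature")
  X <- as_row_matrix(X)
  n <- nrow(X)
  act <- which(!is.na(adv$md$nl))
  if (length(act) == 0L) return(numeric(n))
  D <- induced_distance_matrix(adv$base$kernel, X,
                               adv$md$points[act, , drop = FALSE])
  nl <- adv$md$nl[act]
  Q <- sweep(D, 2L, nl, "<=")
  contrib <- (1 - sweep(D, 2L, nl, "/")) * Q
  cnt <- rowSums(Q)
  ifelse(cnt > 0, rowSums(contrib) / pmax(cnt, 1L), 0)
}

#' Scale decision values to \[0, 1\]
#'
#' Takes absolute values and divides by the batch maximum, so the scaled
#' decision value measures relative confidence within the test batch.
#' An all-zero input maps to all zeros; an empty input stays empty. Note
#' that a single-point batch always scales to 1 (its own absolute decision
#' value is the batch maximum).
#'
#' @param values Numeric vector of raw decision values.
#' @return Numeric vector in \[0, 1\] of the same length.
#' @export
scale_decision_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) return(numeric(0))
  a <- abs(values)
  m <- max(a)
  if (m == 0) return(a)
  a / m
}

#' Predict with a self-advised SVM
#'
#' For each test point the base SVM prediction and its scaled absolute
#' decision value are computed (for one-vs-one models the decision value
#' is the vote winner's minimal pairwise absolute margin). If the advised
#' weight (feature space) or label advised weight (label space) is
#' strictly below the scaled decision value, the base label is kept;
#' otherwise the point is relabeled with the true label of the nearest
#' qualifying misclassified point in feature space (ties broken by
#' smallest MD index). When the misclassified set is empty — or no
#' misclassified point qualifies — the output equals the base prediction.
#'
#' @param object An `advised_fit`.
#' @param newdata Feature matrix (or single vector) to classify.
#' @param ... Unused.
#' @return Character vector of predicted labels, always drawn from the
#'   training class set.
#' @export
predict.advised_fit <- function(object, newdata, ...) {
  X <- as_row_matrix(newdata)
  dec <- ovo_decide(object$base, X)
  out <- dec$labels
  act <- which(!is.na(object$md$nl))
  if (length(act) == 0L) return(out)
  sdv <- scale_decision_values(dec$proxy)
  nl <- object$md$nl[act]
  mdX <- object$md$points[act, , drop = FALSE]
  mdy <- object$md$labels[act]
  Dfeat <- induced_distance_matrix(object$base$kernel, X, mdX)
  if (object$space == "feature") {
    Q <- sweep(Dfeat, 2L, nl, "<=")
    contrib <- (1 - sweep(Dfeat, 2L, nl, "/")) * Q
    cnt <- rowSums(Q)
    aw <- ifelse(cnt > 0, rowSums(contrib) / pmax(cnt, 1L), 0)
  } else {
    lw <- label_weight_table(object)
    aw <- lw$law[match(out, lw$classes)]
    Q <- lw$qualify[match(out, lw$classes), , drop = FALSE]
  }
  # strict "<" keeps the SVM label; equality routes to the relabel branch
  for (k in which(aw >= sdv)) {
    q <- which(Q[k, ])
    if (length(q) == 0L) next # nothing qualifies: keep the base label
    out[k] <- mdy[q[which.min(Dfeat[k, q])]]
  }
  out
}

#' @rdname predict.advised_fit
#' @param adv An `advised_fit` with `space = "feature"`.
#' @param Xtest Feature matrix.
#' @export
advised_predict <- function(adv, Xtest) {
  stopifnot(inherits(adv, "advised_fit"))
  predict(adv, Xtest)
}
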