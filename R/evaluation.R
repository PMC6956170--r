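#' Stratified k-fold splits
#'
#' Partitions the rows of a dataset into k disjoint, exhaustive folds with
#' (near-)equal class proportions in every fold. Deterministic given the
#' seed, so a benchmark can reuse identical folds across classifiers.
#'
#' @param ds A [labeled_dataset()] (or a plain label vector).
#' @param k Number of folds (>= 2). Every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors (the test fold indices).
#' @export
kfold_split <- function(ds, k, seed = 1L) {
  y <- if (inherits(ds, "labeled_dataset")) ds$y else as.character(ds)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  counts <- table(y)
  small <- counts[counts < k]
  if (length(small) > 0L) {
    stop(sprintf("class '%s' has %d member(s), fewer than k = %d folds",
                 names(small)[1L], small[1L], k), call. = FALSE)
  }
  assign_fold <- withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  lapply(seq_len(k), function(f) which(assign_fold == f))
}

#' Fold-count sizing rule
#'
#' 3-fold cross-validation for large datasets (n > 1000), 5-fold for small
#' and medium ones.
#'
#' @param n Number of samples.
#' @return 3 or 5.
#' @export
choose_folds <- function(n) if (n > 1000) 3L else 5L

#' Classification accuracy
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return Fraction of equal entries, in \[0, 1\].
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d true labels vs %d predictions",
                 length(y_true), length(y_pred)), call. = FALSE)
  }
  mean(as.character(y_true) == as.character(y_pred))
}

#' Sensitivity and specificity
#'
#' For a binary problem with a declared positive label, sensitivity is
#' TP/(TP+FN) and specificity TN/(TN+FP). With more than two classes the
#' one-vs-rest values are macro-averaged over classes and
#' `positive_label` is ignored.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive_label The class counted as positive (binary case).
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(y_true, y_pred, positive_label = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop(sprintf("length mismatch: %d true labels vs %d predictions",
                 length(y_true), length(y_pred)), call. = FALSE)
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  one_vs_rest <- function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fn <- sum(y_true == pos & y_pred != pos)
    tn <- sum(y_true != pos & y_pred != pos)
    fp <- sum(y_true != pos & y_pred == pos)
    c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  if (length(classes) <= 2L) {
    if (is.null(positive_label)) {
      stop("`positive_label` is required for a binary problem", call. = FALSE)
    }
    one_vs_rest(positive_label)
  } else {
    vals <- vapply(classes, one_vs_rest, numeric(2))
    c(sensitivity = mean(vals["sensitivity", ], na.rm = TRUE),
      specificity = mean(vals["specificity", ], na.rm = TRUE))
  }
}

#' Multi-label (Jaccard) accuracy
#'
#' Mean over samples of \eqn{|y_i \cap \hat y_i| / |y_i \cup \hat y_i|};
#' a sample where both sets are empty scores 1.
#'
#' @param true_sets,pred_sets Lists of label sets (vectors) of equal
#'   length.
#' @return Scalar in \[0, 1\].
#' @export
multilabel_accuracy <- function(true_sets, pred_sets) {
  if (length(true_sets) != length(pred_sets)) {
    stop(sprintf("length mismatch: %d true sets vs %d predicted sets",
                 length(true_sets), length(pred_sets)), call. = FALSE)
  }
  if (length(true_sets) == 0L) return(NaN)
  mean(vapply(seq_along(true_sets), function(i) {
    a <- unique(as.character(true_sets[[i]]))
    b <- unique(as.character(pred_sets[[i]]))
    u <- length(union(a, b))
    if (u == 0L) 1 else length(intersect(a, b)) / u
  }, numeric(1)))
}

classifier_ids <- c("c-svm", "v-svm", "c-sa-svm", "v-sa-svm",
                    "c-lsa-svm", "v-lsa-svm")

parse_classifier_id <- function(id) {
  if (!id %in% classifier_ids) {
    stop(sprintf("unknown classifier '%s'; valid ids: %s", id,
                 paste(classifier_ids, collapse = ", ")), call. = FALSE)
  }
  list(variant = if (startsWith(id, "c-")) "c" else "nu",
       advising = if (grepl("lsa", id)) "label"
                  else if (grepl("sa", id)) "feature"
                  else "none")
}

fit_classifier <- function(id, train, kernel, cost, nu) {
  cfg <- parse_classifier_id(id)
  base <- train_svm(train, cfg$variant, kernel, cost = cost, nu = nu)
  switch(cfg$advising,
    none = base,
    feature = self_advise(base, train),
    label = label_self_advise(base, train))
}

#' Cross-validated classifier benchmark
#'
#' Runs a set of classifiers over identical stratified folds of one
#' dataset (a paired comparison) and reports per-classifier accuracy,
#' macro/binary sensitivity and specificity over the pooled
#' cross-validated predictions, and training time. Supported classifier
#' ids: `c-svm`, `v-svm`, `c-sa-svm`, `v-sa-svm`, `c-lsa-svm`,
#' `v-lsa-svm`.
#'
#' @param ds A [labeled_dataset()].
#' @param classifiers Character vector of classifier ids (default: all
#'   six).
#' @param kernel Shared [kernel_spec()].
#' @param cost Penalty for the `c-` variants.
#' @param nu `nu` for the `v-` variants.
#' @param k Fold count; `NULL` applies the [choose_folds()] sizing rule.
#' @param seed Seed fixing the folds.
#' @param positive_label Positive class for binary sensitivity /
#'   specificity (`NULL` skips them for binary problems).
#' @param standardize If `TRUE`, features are z-scored per fold using
#'   means/SDs fitted on the training split only (no leakage).
#' @return A data frame with one row per classifier: `classifier`,
#'   `mean_accuracy`, `sensitivity`, `specificity`, `train_time_ms`, and a
#'   `fold_accuracies` list-column.
#' @export
benchmark <- function(ds, classifiers = classifier_ids,
                      kernel = rbf_kernel(1), cost = 1, nu = 0.2,
                      k = NULL, seed = 1L, positive_label = NULL,
                      standardize = FALSE) {
  ds <- as_labeled_dataset(ds)
  for (id in classifiers) parse_classifier_id(id) # validate up front
  if (is.null(k)) k <- choose_folds(nrow(ds$X))
  folds <- kfold_split(ds, k = k, seed = seed)
  rows <- lapply(classifiers, function(id) {
    fold_acc <- numeric(length(folds))
    pooled_true <- character(0); pooled_pred <- character(0)
    t_train <- 0
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      Xtr <- ds$X[-test_idx, , drop = FALSE]
      Xte <- ds$X[test_idx, , drop = FALSE]
      if (standardize) {
        mu <- colMeans(Xtr)
        sdv <- apply(Xtr, 2L, stats::sd)
        sdv[sdv == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
        Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
      }
      tr <- labeled_dataset(Xtr, ds$y[-test_idx], classes = ds$classes)
      t0 <- proc.time()[["elapsed"]]
      model <- fit_classifier(id, tr, kernel, cost, nu)
      t_train <- t_train + (proc.time()[["elapsed"]] - t0) * 1000
      pred <- predict(model, Xte)
      fold_acc[f] <- accuracy(ds$y[test_idx], pred)
      pooled_true <- c(pooled_true, ds$y[test_idx])
      pooled_pred <- c(pooled_pred, pred)
    }
    ss <- c(sensitivity = NA_real_, specificity = NA_real_)
    if (length(ds$classes) > 2L || !is.null(positive_label)) {
      ss <- sensitivity_specificity(pooled_true, pooled_pred, positive_label)
    }
    data.frame(classifier = id, mean_accuracy = mean(fold_acc),
               sensitivity = unname(ss["sensitivity"]),
               specificity = unname(ss["specificity"]),
               train_time_ms = t_train,
               fold_accuracies = I(list(fold_acc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
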