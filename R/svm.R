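#' Train a c-SVM or nu-SVM
#'
#' Fits a support vector machine with the requested kernel. Binary
#' problems are fitted directly; problems with more than two classes use a
#' one-vs-one reduction with majority voting (vote ties go to the earliest
#' class in class order). The quadratic program is delegated to libsvm
#' (via \pkg{e1071}); the fitted model stores support vectors, signed dual
#' coefficients and bias per class pair so that decision values can be
#' recomputed independently of the solver — training verifies that this
#' reconstruction matches the solver's own decision values to 1e-6.
#'
#' @param train A [labeled_dataset()] with at least two classes.
#' @param variant `"c"` for C-SVM (penalty `cost`) or `"nu"` for nu-SVM
#'   (`nu` bounds the fraction of margin errors and support vectors).
#' @param kernel A [kernel_spec()]; `gamma` is always explicit.
#' @param cost Positive penalty C (variant `"c"`).
#' @param nu Value in (0, 1] (variant `"nu"`). An infeasible `nu` for the
#'   class balance is surfaced as an error naming the attempted value.
#' @return An object of class `svm_fit` with fields `variant`, `kernel`,
#'   `cost`/`nu`, `classes`, `dim`, `multiclass_scheme` and `pairs` (one
#'   record per class pair: `pos`, `neg`, `sv`, `coefs`, `rho`).
#' @seealso [decision_value()], [predict.svm_fit()], [grid_search()]
#' @export
train_svm <- function(train, variant = c("c", "nu"), kernel,
                      cost = 1, nu = 0.2) {
  train <- as_labeled_dataset(train)
  variant <- match.arg(variant)
  stopifnot(inherits(kernel, "kernel_spec"))
  if (length(unique(train$y)) < 2L) {
    stop("training data contain a single class; at least two are required",
         call. = FALSE)
  }
  if (variant == "c" && (!is.finite(cost) || cost <= 0)) {
    stop("`cost` must be a positive real", call. = FALSE)
  }
  if (variant == "nu" && (!is.finite(nu) || nu <= 0 || nu > 1)) {
    stop("`nu` must lie in (0, 1]", call. = FALSE)
  }
  classes <- train$classes[train$classes %in% unique(train$y)]
  scheme <- if (length(classes) == 2L) "binary" else "one_vs_one"
  pair_idx <- utils::combn(seq_along(classes), 2L)
  pairs <- vector("list", ncol(pair_idx))
  for (p in seq_len(ncol(pair_idx))) {
    a <- classes[pair_idx[1L, p]]
    b <- classes[pair_idx[2L, p]]
    rows <- train$y %in% c(a, b)
    pairs[[p]] <- fit_binary_pair(train$X[rows, , drop = FALSE],
                                  train$y[rows], a, b,
                                  variant, kernel, cost, nu)
  }
  structure(
    list(variant = variant, kernel = kernel,
         cost = if (variant == "c") cost else NULL,
         nu = if (variant == "nu") nu else NULL,
         classes = classes, dim = ncol(train$X),
         multiclass_scheme = scheme, pairs = pairs),
    class = "svm_fit"
  )
}

# Fit one binary machine for the class pair (a, b) and normalize it to the
# package's own representation: h(x) = sum_i coefs_i k(x, sv_i) + bias,
# with h > 0 meaning `pos`. coefs are the signed products alpha_i * y_i.
fit_binary_pair <- function(X, y, a, b, variant, kernel, cost, nu) {
  type <- if (variant == "c") "C-classification" else "nu-classification"
  ek <- switch(kernel$kind, rbf = "radial", linear = "linear",
               polynomial = "polynomial", sigmoid = "sigmoid")
  fit <- tryCatch(
    e1071::svm(x = X, y = factor(y, levels = c(a, b)), scale = FALSE,
               type = type, kernel = ek, gamma = kernel$gamma,
               degree = kernel$degree, coef0 = kernel$coef0,
               cost = cost, nu = nu),
    error = function(e) {
      if (grepl("nu", conditionMessage(e), ignore.case = TRUE)) {
        stop(sprintf("nu = %g is infeasible for the class balance of pair (%s, %s): %s",
                     nu, a, b, conditionMessage(e)), call. = FALSE)
      }
      stop(e)
    }
  )
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients the decision value so that positive means the first
  # label of the "pos/neg" column name.
  lv <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  pos <- lv[1L]; neg <- lv[2L]
  sv <- unname(as.matrix(fit$SV))
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  h <- drop(kernel_matrix(kernel, X, sv) %*% coefs) + bias
  if (max(abs(h - as.numeric(dv))) > 1e-6) {
    stop("internal consistency check failed: reconstructed decision values ",
         "deviate from the solver's by more than 1e-6", call. = FALSE)
  }
  if (nrow(sv) == 0L) {
    stop("solver returned a model with zero support vectors", call. = FALSE)
  }
  list(pos = pos, neg = neg, sv = sv, coefs = coefs, rho = -bias)
}

#' SVM decision values
#'
#' Recomputes \eqn{h(x) = \sum_{\alpha_i > 0} y_i \alpha_i k(x, x_i) + b}
#' from the stored support vectors, signed dual coefficients and bias —
#' independently of the training backend.
#'
#' @param model An `svm_fit`.
#' @param X A feature vector or matrix of rows to evaluate.
#' @return For a binary model, a numeric vector of signed decision values
#'   (positive means the pair's `pos` class). For a one-vs-one model, a
#'   matrix with one column per class pair, columns named `"pos/neg"`.
#' @export
decision_value <- function(model, X) {
  stopifnot(inherits(model, "svm_fit"))
  X <- as_row_matrix(X)
  if (ncol(X) != model$dim) {
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 model$dim, ncol(X)), call. = FALSE)
  }
  H <- vapply(model$pairs, function(p) {
    drop(kernel_matrix(model$kernel, X, p$sv) %*% p$coefs) - p$rho
  }, numeric(nrow(X)))
  H <- matrix(H, nrow = nrow(X))
  colnames(H) <- vapply(model$pairs, function(p) paste0(p$pos, "/", p$neg),
                        character(1))
  if (model$multiclass_scheme == "binary") drop(H[, 1L]) else H
}

# One-vs-one vote. Returns per-point predicted labels plus the advising
# decision-value proxy: the raw h for binary models, and the vote winner's
# minimal pairwise |h| for one-vs-one models (exactly the binary |h| when
# there are two classes).
ovo_decide <- function(model, X) {
  X <- as_row_matrix(X)
  H <- decision_value(model, X)
  H <- matrix(H, nrow = nrow(X))
  n <- nrow(X)
  npair <- length(model$pairs)
  votes <- matrix(0L, n, length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (p in seq_len(npair)) {
    pr <- model$pairs[[p]]
    h <- H[, p]
    # h == 0 is an exact tie on the pair: earlier class in class order wins
    first <- model$classes[min(match(c(pr$pos, pr$neg), model$classes))]
    w <- ifelse(h > 0, pr$pos, ifelse(h < 0, pr$neg, first))
    for (cl in model$classes) votes[, cl] <- votes[, cl] + (w == cl)
  }
  labels <- model$classes[apply(votes, 1L, which.max)] # ties -> earliest class
  proxy <- numeric(n)
  if (model$multiclass_scheme == "binary") {
    proxy <- H[, 1L]
  } else {
    involve <- lapply(model$classes, function(cl) {
      which(vapply(model$pairs, function(p) cl %in% c(p$pos, p$neg),
                   logical(1)))
    })
    names(involve) <- model$classes
    for (i in seq_len(n)) {
      proxy[i] <- min(abs(H[i, involve[[labels[i]]]]))
    }
  }
  list(labels = labels, H = H, proxy = proxy)
}

#' Predict class labels from a fitted SVM
#'
#' Binary models map the sign of the decision value onto the two class
#' labels; one-vs-one models take a majority vote over the pairwise
#' machines, with ties broken by class order.
#'
#' @param object An `svm_fit`.
#' @param newdata Feature matrix (or single vector) to classify.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.svm_fit <- function(object, newdata, ...) {
  ovo_decide(object, newdata)$labels
}

#' @export
print.svm_fit <- function(x, ...) {
  par <- if (x$variant == "c") sprintf("C = %g", x$cost) else sprintf("nu = %g", x$nu)
  cat(sprintf("<svm_fit: %s-SVM, %s kernel (gamma = %g), %s, %d classes, %d pair machine(s)>\n",
              x$variant, x$kernel$kind, x$kernel$gamma, par,
              length(x$classes), length(x$pairs)))
  invisible(x)
}

#' Hyperparameter grid
#'
#' Default search grid for [grid_search()]: both `C` and `gamma` range
#' over \eqn{2^{-9}, 2^{-8}, \ldots, 2^{9}, 2^{10}} (20 values each, hence
#' 400 combinations), and `nu` over 0.05 to 0.5 in steps of 0.05.
#'
#' @param C_values Positive penalty candidates.
#' @param gamma_values Positive RBF width candidates.
#' @param nu_values Candidates in (0, 1).
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(C_values = 2^(-9:10), gamma_values = 2^(-9:10),
                       nu_values = seq(0.05, 0.5, by = 0.05)) {
  stopifnot(all(C_values > 0), all(gamma_values > 0),
            all(nu_values > 0 & nu_values < 1))
  structure(list(C_values = C_values, gamma_values = gamma_values,
                 nu_values = nu_values), class = "param_grid")
}

#' Cross-validated grid search over (C or nu, gamma)
#'
#' Evaluates every combination of penalty and RBF width by stratified
#' k-fold accuracy and returns the argmax. Ties are broken by smaller
#' penalty (C or nu), then smaller gamma. Folds are fixed once per call so
#' all combinations see identical splits.
#'
#' @param train A [labeled_dataset()].
#' @param variant `"c"` or `"nu"`.
#' @param grid A [param_grid()].
#' @param folds Number of folds (>= 2; every class must have at least
#'   `folds` members).
#' @param seed Integer seed making the folds reproducible.
#' @return A list with `best` (named list `C_or_nu`, `gamma`,
#'   `mean_accuracy`) and `table` (a data frame with one row per evaluated
#'   combination).
#' @export
grid_search <- function(train, variant = c("c", "nu"), grid = param_grid(),
                        folds = 5L, seed = 1L) {
  train <- as_labeled_dataset(train)
  variant <- match.arg(variant)
  stopifnot(inherits(grid, "param_grid"))
  fold_sets <- kfold_split(train, k = folds, seed = seed)
  pvals <- if (variant == "c") grid$C_values else grid$nu_values
  combos <- expand.grid(C_or_nu = pvals, gamma = grid$gamma_values,
                        KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fold_acc <- vapply(fold_sets, function(test_idx) {
      tr <- labeled_dataset(train$X[-test_idx, , drop = FALSE],
                            train$y[-test_idx], classes = train$classes)
      m <- train_svm(tr, variant, rbf_kernel(combos$gamma[i]),
                     cost = combos$C_or_nu[i], nu = combos$C_or_nu[i])
      mean(predict(m, train$X[test_idx, , drop = FALSE]) == train$y[test_idx])
    }, numeric(1))
    acc[i] <- mean(fold_acc)
  }
  combos$mean_accuracy <- acc
  # argmax with ties -> smaller C (or nu), then smaller gamma
  ord <- order(-combos$mean_accuracy, combos$C_or_nu, combos$gamma)
  best <- combos[ord[1L], ]
  list(best = list(C_or_nu = best$C_or_nu, gamma = best$gamma,
                   mean_accuracy = best$mean_accuracy),
       table = combos)
}
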