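#' Kernel specification
#'
#' Bundles a kernel family with its hyperparameters. The spec is used both
#' for similarity evaluation ([kernel_eval()], [kernel_matrix()]) and for
#' the kernel-induced metric ([induced_distance()]) that the self-advising
#' layers use to measure neighborhood lengths in feature space.
#'
#' Kernel forms follow the libsvm conventions so that a spec is
#' interchangeable between this package's own evaluations and the
#' delegated SVM solver:
#' \itemize{
#'   \item \code{rbf}: \eqn{k(u,v) = \exp(-\gamma \|u-v\|^2)}
#'   \item \code{linear}: \eqn{k(u,v) = \langle u,v \rangle}
#'   \item \code{polynomial}: \eqn{k(u,v) = (\gamma \langle u,v \rangle + c_0)^{deg}}
#'   \item \code{sigmoid}: \eqn{k(u,v) = \tanh(\gamma \langle u,v \rangle + c_0)}
#' }
#'
#' `gamma` is always explicit in the spec (and hence in every serialized
#' model record); no silent `1/d` default is applied.
#'
#' @param kind Kernel family, one of `"rbf"`, `"linear"`, `"polynomial"`,
#'   `"sigmoid"`. The default everywhere in this package is RBF.
#' @param gamma Positive kernel width / scale parameter. Required for the
#'   RBF kernel; defaults to 1 for polynomial and sigmoid.
#' @param degree Positive integer degree (polynomial only).
#' @param coef0 Additive constant (polynomial and sigmoid only).
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- rbf_kernel(gamma = 1)
#' kernel_eval(k, c(0, 0), c(1, 0)) # exp(-1)
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = NULL, degree = 3L, coef0 = 0) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(gamma) || !is.finite(gamma) || gamma <= 0) {
      stop("`gamma` must be a positive real for the RBF kernel", call. = FALSE)
    }
  }
  if (is.null(gamma)) gamma <- 1
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  degree <- as.integer(degree)
  if (degree < 1L) stop("`degree` must be a positive integer", call. = FALSE)
  structure(
    list(kind = kind, gamma = as.numeric(gamma), degree = degree,
         coef0 = as.numeric(coef0)),
    class = "kernel_spec"
  )
}

#' @rdname kernel_spec
#' @export
rbf_kernel <- function(gamma) kernel_spec("rbf", gamma = gamma)

#' @rdname kernel_spec
#' @export
linear_kernel <- function() kernel_spec("linear")

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
    rbf = sprintf("gamma = %g", x$gamma),
    linear = "",
    polynomial = sprintf("gamma = %g, degree = %d, coef0 = %g",
                         x$gamma, x$degree, x$coef0),
    sigmoid = sprintf("gamma = %g, coef0 = %g", x$gamma, x$coef0)
  )
  cat(sprintf("<kernel_spec: %s%s>\n", x$kind,
              if (nzchar(extra)) paste0(" (", extra, ")") else ""))
  invisible(x)
}

as_row_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Evaluate a kernel between two vectors
#'
#' @param spec A [kernel_spec()].
#' @param u,v Numeric feature vectors of equal dimension.
#' @return The scalar kernel value \eqn{k(u, v)}. For the RBF kernel the
#'   value lies in \eqn{(0, 1]} with \eqn{k(u,u) = 1}.
#' @export
kernel_eval <- function(spec, u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) {
    stop(sprintf("dimension mismatch: u has %d coordinates, v has %d",
                 length(u), length(v)), call. = FALSE)
  }
  kernel_matrix(spec, matrix(u, 1L), matrix(v, 1L))[1L, 1L]
}

#' Pairwise kernel matrix
#'
#' Computes the n x m Gram matrix with entry (i, j) equal to
#' `kernel_eval(spec, A[i, ], B[j, ])`, vectorized over rows.
#'
#' @param spec A [kernel_spec()].
#' @param A,B Numeric matrices with one observation per row and a shared
#'   feature dimension. Empty inputs yield an empty matrix of consistent
#'   shape.
#' @return An `nrow(A)` x `nrow(B)` numeric matrix.
#' @export
kernel_matrix <- function(spec, A, B = A) {
  stopifnot(inherits(spec, "kernel_spec"))
  A <- as_row_matrix(A); B <- as_row_matrix(B)
  if (ncol(A) != ncol(B)) {
    stop(sprintf("dimension mismatch: A has %d columns, B has %d",
                 ncol(A), ncol(B)), call. = FALSE)
  }
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(matrix(numeric(0), nrow = nrow(A), ncol = nrow(B)))
  }
  G <- A %*% t(B)
  switch(spec$kind,
    linear = G,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      d2[d2 < 0] <- 0 # floating-point guard
      exp(-spec$gamma * d2)
    },
    polynomial = (spec$gamma * G + spec$coef0)^spec$degree,
    sigmoid = tanh(spec$gamma * G + spec$coef0)
  )
}

#' Kernel-induced distance
#'
#' The metric induced by a kernel on its feature space,
#' \eqn{d(u,v) = \sqrt{k(u,u) + k(v,v) - 2 k(u,v)}}. For the linear kernel
#' this is exactly the Euclidean distance; for the RBF kernel it is a
#' strictly increasing function of \eqn{\|u-v\|} bounded above by
#' \eqn{\sqrt 2}. The radicand is clamped at zero before the square root to
#' absorb floating-point negatives.
#'
#' @inheritParams kernel_eval
#' @return A nonnegative scalar distance.
#' @export
induced_distance <- function(spec, u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) {
    stop(sprintf("dimension mismatch: u has %d coordinates, v has %d",
                 length(u), length(v)), call. = FALSE)
  }
  induced_distance_matrix(spec, matrix(u, 1L), matrix(v, 1L))[1L, 1L]
}

# Pairwise induced distances between rows of A and rows of B.
induced_distance_matrix <- function(spec, A, B) {
  A <- as_row_matrix(A); B <- as_row_matrix(B)
  K <- kernel_matrix(spec, A, B)
  if (spec$kind == "rbf") {
    r <- 2 - 2 * K # k(u,u) = 1 for RBF
  } else {
    ka <- vapply(seq_len(nrow(A)), function(i) {
      sum_self_kernel(spec, A[i, ])
    }, numeric(1))
    kb <- vapply(seq_len(nrow(B)), function(j) {
      sum_self_kernel(spec, B[j, ])
    }, numeric(1))
    r <- outer(ka, kb, "+") - 2 * K
  }
  r[r < 0] <- 0
  sqrt(r)
}

sum_self_kernel <- function(spec, u) {
  s <- sum(u * u)
  switch(spec$kind,
    linear = s,
    rbf = 1,
    polynomial = (spec$gamma * s + spec$coef0)^spec$degree,
    sigmoid = tanh(spec$gamma * s + spec$coef0)
  )
}
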