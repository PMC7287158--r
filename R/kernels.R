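#' Kernel specifications and kernel matrices
#'
#' Kernels turn linear models into non-linear ones by evaluating inner
#' products in an implicit feature space: \code{k(x, x') = <phi(x),
#' phi(x')>}. Supported kinds: \code{linear} (\code{x . x'}),
#' \code{polynomial} (\code{(gamma x . x' + coef0)^degree}), \code{rbf}
#' (\code{exp(-gamma ||x - x'||^2)}), and \code{precomputed} (the caller
#' supplies the kernel matrix).
#'
#' @param kind kernel kind.
#' @param gamma RBF width / polynomial scale; default \code{1/p} filled in
#'   at training time when NULL.
#' @param degree polynomial degree (integer >= 1).
#' @param coef0 polynomial offset.
#' @return an object of class \code{kernelSpec}.
#' @examples
#' k <- kernelSpec("polynomial", gamma = 1, degree = 2, coef0 = 0)
#' kernelEval(k, c(1, 2), c(3, 4))  # (3 + 8)^2 = 121
#' @export
kernelSpec <- function(kind = c("linear", "polynomial", "rbf", "precomputed"),
                       gamma = NULL, degree = 2L, coef0 = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf" && !is.null(gamma) && gamma <= 0)
    stopf("rbf kernel requires gamma > 0")
  if (kind == "polynomial" && (degree < 1L || degree != round(degree)))
    stopf("polynomial kernel requires integer degree >= 1")
  structure(list(kind = kind, gamma = gamma, degree = as.integer(degree),
                 coef0 = coef0), class = "kernelSpec")
}

# fill data-dependent defaults (gamma = 1/p)
resolveKernel <- function(spec, p) {
  if (is.null(spec)) spec <- kernelSpec("linear")
  if (is.character(spec)) spec <- kernelSpec(spec)
  if (spec$kind %in% c("rbf", "polynomial") && is.null(spec$gamma))
    spec$gamma <- 1 / p
  spec
}

#' @rdname kernelSpec
#' @param spec a kernelSpec.
#' @param x,y numeric feature vectors of equal length.
#' @export
kernelEval <- function(spec, x, y) {
  if (length(x) != length(y)) stopf("feature lengths differ")
  drop(computeKernelMatrix(spec, matrix(x, 1L), matrix(y, 1L)))
}

#' Compute a kernel matrix
#'
#' Pairwise kernel evaluations between the rows of \code{X} and \code{X2}
#' (default: \code{X} itself, giving the symmetric self-kernel).
#'
#' @param spec a \code{\link{kernelSpec}}.
#' @param X n x p matrix; @param X2 optional m x p matrix.
#' @return n x m kernel matrix.
#' @export
computeKernelMatrix <- function(spec, X, X2 = NULL) {
  X <- asMatrix(X)
  self <- is.null(X2)
  X2 <- if (self) X else asMatrix(X2)
  if (ncol(X) != ncol(X2)) stopf("feature counts differ (%d vs %d)",
                                 ncol(X), ncol(X2))
  spec <- resolveKernel(spec, ncol(X))
  G <- tcrossprod(X, X2)
  K <- switch(spec$kind,
    linear = G,
    polynomial = (spec$gamma * G + spec$coef0)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * G
      d2[d2 < 0] <- 0
      exp(-spec$gamma * d2)
    },
    precomputed = stopf("precomputed kernel: supply the matrix directly"))
  if (self) K <- (K + t(K)) / 2  # enforce exact symmetry
  K
}

# Resolve kernel input for trainers: returns list(K = train kernel matrix,
# X = stored training samples or NULL, spec). `X` may itself be a
# precomputed square kernel matrix when spec$kind == "precomputed".
kernelInput <- function(spec, X) {
  if (!is.null(spec) && !is.character(spec) && spec$kind == "precomputed") {
    K <- asMatrix(X)
    if (nrow(K) != ncol(K)) stopf("precomputed kernel matrix must be square")
    return(list(K = K, X = NULL, spec = spec))
  }
  X <- asMatrix(X)
  spec <- resolveKernel(spec, ncol(X))
  list(K = computeKernelMatrix(spec, X), X = X, spec = spec)
}
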