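#' Kernel Fisher discriminant analysis (two classes)
#'
#' Kernelized Fisher discriminant: maximizes between-class separation over
#' within-class scatter in the kernel-induced feature space. With kernel
#' matrix \code{K}, class kernel means \code{M_i = (1/n_i) sum over class-i
#' columns of K} and within-class kernel scatter \code{N = sum_c K_c (I -
#' 11'/n_c) K_c'}, the dual weights solve \code{(N + lambda I) alpha = M1 -
#' M2} (ridge regularization of N). Decision values are \code{dval(x) =
#' sum_i alpha_i k(x_i, x) + b} with the bias placing the projected class
#' means symmetrically about zero.
#'
#' @param param list: \code{lambda} ridge regularization (> 0 recommended;
#'   default 0.01), \code{kernel} a \code{\link{kernelSpec}} or kind name
#'   (default linear; \code{"precomputed"} accepts an n x n kernel matrix
#'   as \code{X}).
#' @param X n x p training data, or precomputed kernel matrix.
#' @param clabel two-class labels.
#' @return object of class \code{kernelFdaModel}: \code{alpha}, \code{b},
#'   stored training samples, \code{kernel}, \code{lambdaUsed}.
#' @references Mika et al. (1999), Fisher discriminant analysis with
#'   kernels.
#' @export
trainKernelFDA <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  clabel <- v$targets
  if (v$K != 2L) stopf("kernel FDA requires 2 classes")
  lambda <- if (is.null(param$lambda)) 0.01 else as.numeric(param$lambda)
  if (lambda < 0) stopf("lambda must be >= 0")
  ki <- kernelInput(param$kernel, dataValues(v$X))
  K <- ki$K
  n <- nrow(K)
  M <- matrix(0, n, 2L)
  N <- matrix(0, n, n)
  for (cl in 1:2) {
    idx <- which(clabel == cl)
    nc <- length(idx)
    Kc <- K[, idx, drop = FALSE]
    M[, cl] <- rowMeans(Kc)
    Kcc <- Kc - rowMeans(Kc)           # Kc (I - 11'/nc)
    N <- N + tcrossprod(Kcc, Kc)       # Kc (I - 11'/nc) Kc'
  }
  alpha <- tryCatch(drop(solve(N + diag(lambda, n), M[, 1L] - M[, 2L])),
    error = function(e) stopf(
      "within-class kernel scatter singular at lambda = %g; increase lambda",
      lambda))
  b <- -sum(alpha * (M[, 1L] + M[, 2L])) / 2
  structure(list(alpha = alpha, b = b, Xtrain = ki$X, kernel = ki$spec,
                 lambdaUsed = lambda, mapping = v$mapping),
            class = c("kernelFdaModel", "mvModel"))
}

#' @rdname trainKernelFDA
#' @param model a fitted \code{kernelFdaModel}.
#' @return \code{predictKernelFDA}: list with \code{clabel} and \code{dval}
#'   (projected class means have opposite-sign dvals by construction).
#' @export
predictKernelFDA <- function(model, X) {
  Ktest <- if (model$kernel$kind == "precomputed") asMatrix(X)
           else computeKernelMatrix(model$kernel, asMatrix(X), model$Xtrain)
  dval <- drop(Ktest %*% model$alpha) + model$b
  list(clabel = ifelse(dval >= 0, 1L, 2L), dval = dval, prob = NULL)
}
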