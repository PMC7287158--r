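#' Ridge regression with automatic primal/dual switching
#'
#' Minimizes \code{||y - X w||^2 + lambda ||w||^2}. The intercept is
#' realized as a constant column appended to \code{X} and penalized with
#' the rest of the coefficients (the model formalism treats the intercept
#' as an ordinary coefficient); set \code{param$centerIntercept = TRUE} to
#' instead center X and y and leave the intercept unpenalized (common
#' practice). Two algebraically equivalent closed forms exist: the primal
#' solution \code{w = (X'X + lambda I_p)^-1 X'y} (cost grows with the
#' feature count) and the dual solution \code{w = X'(XX' + lambda I_n)^-1
#' y} (cost grows with the sample count). \code{form = "auto"} picks the
#' primal when \code{n >= p} and the dual otherwise; the choice never
#' changes predictions. \code{lambda = 0} reduces to ordinary least
#' squares.
#'
#' @param param list: \code{lambda} >= 0 (default 0), \code{form}
#'   ("auto", "primal", "dual"), \code{intercept} logical (default TRUE),
#'   \code{centerIntercept} logical (default FALSE).
#' @param X n x p training data; @param y numeric responses.
#' @return object of class \code{ridgeModel}: \code{w} (p-vector),
#'   \code{b} (intercept), \code{formUsed}, \code{lambdaUsed}.
#' @export
trainRidge <- function(param = list(), X, y) {
  v <- validateInputs(X, y, type = "regression")
  X <- asMatrix(v$X); y <- v$targets
  lambda <- if (is.null(param$lambda)) 0 else as.numeric(param$lambda)
  if (lambda < 0) stopf("lambda must be >= 0")
  form <- if (is.null(param$form)) "auto" else param$form
  if (!form %in% c("auto", "primal", "dual")) stopf("unknown form '%s'", form)
  intercept <- if (is.null(param$intercept)) TRUE else isTRUE(param$intercept)
  center <- isTRUE(param$centerIntercept)
  p0 <- ncol(X)
  if (intercept && center) {
    xm <- colMeans(X); ym <- mean(y)
    Xa <- sweep(X, 2L, xm); ya <- y - ym
  } else if (intercept) {
    Xa <- cbind(X, 1); ya <- y
  } else { Xa <- X; ya <- y }
  n <- nrow(Xa); p <- ncol(Xa)
  if (form == "auto") form <- if (n >= p) "primal" else "dual"
  wa <- tryCatch({
    if (form == "primal")
      drop(solve(crossprod(Xa) + diag(lambda, p), crossprod(Xa, ya)))
    else
      drop(crossprod(Xa, solve(tcrossprod(Xa) + diag(lambda, n), ya)))
  }, error = function(e)
    stopf("singular system at lambda = %g; increase lambda", lambda))
  if (intercept && center) {
    w <- wa; b <- ym - sum(xm * wa)
  } else if (intercept) {
    w <- wa[seq_len(p0)]; b <- wa[p0 + 1L]
  } else { w <- wa; b <- 0 }
  structure(list(w = w, b = b, formUsed = form, lambdaUsed = lambda,
                 intercept = intercept),
            class = c("ridgeModel", "mvModel"))
}

#' @rdname trainRidge
#' @param model a fitted \code{ridgeModel}.
#' @return \code{predictRidge}: numeric vector of predicted responses
#'   \code{X w + b}.
#' @export
predictRidge <- function(model, X) {
  X <- asMatrix(X)
  if (ncol(X) != length(model$w)) stopf("feature count mismatch")
  drop(X %*% model$w) + model$b
}

#' Kernel ridge regression
#'
#' The dual form of ridge regression written entirely in kernel
#' evaluations: dual weights \code{alpha = (K + lambda I_n)^-1 y} and
#' predictions \code{f(x) = sum_i alpha_i k(x_i, x)}. With a linear kernel
#' this reproduces dual-form linear ridge (without intercept).
#'
#' @param param list: \code{lambda} >= 0 (default 0; > 0 required when K
#'   is singular), \code{kernel} a \code{\link{kernelSpec}} or kind name
#'   (\code{"precomputed"} accepts an n x n kernel matrix as \code{X}).
#' @param X n x p training data or precomputed kernel matrix.
#' @param y numeric responses.
#' @return object of class \code{kernelRidgeModel}: \code{alpha}, stored
#'   training samples, \code{kernel}, \code{lambdaUsed}.
#' @export
trainKernelRidge <- function(param = list(), X, y) {
  lambda <- if (is.null(param$lambda)) 0 else as.numeric(param$lambda)
  if (lambda < 0) stopf("lambda must be >= 0")
  ki <- kernelInput(param$kernel, X)
  v <- validateInputs(matrix(0, nrow(ki$K), 1), y, type = "regression")
  y <- v$targets
  alpha <- tryCatch(drop(solve(ki$K + diag(lambda, nrow(ki$K)), y)),
    error = function(e)
      stopf("K + lambda I singular at lambda = %g; increase lambda", lambda))
  structure(list(alpha = alpha, Xtrain = ki$X, kernel = ki$spec,
                 lambdaUsed = lambda),
            class = c("kernelRidgeModel", "mvModel"))
}

#' @rdname trainKernelRidge
#' @param model a fitted \code{kernelRidgeModel}.
#' @export
predictKernelRidge <- function(model, X) {
  Ktest <- if (model$kernel$kind == "precomputed") asMatrix(X)
           else computeKernelMatrix(model$kernel, asMatrix(X), model$Xtrain)
  drop(Ktest %*% model$alpha)
}
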