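#' Ledoit-Wolf shrinkage estimate
#'
#' Closed-form estimate of the optimal shrinkage intensity for blending an
#' empirical covariance matrix with a scaled-identity target, computed from
#' (class-)centered samples. Writing \code{S} for the empirical covariance,
#' \code{m = tr(S)/p} for the target scale, \code{d2 = ||S - m I||_F^2} for
#' the dispersion of \code{S} around the target and \code{b2} for the
#' (capped) sampling variance of the entries of \code{S}, the estimate is
#' \code{lambda = b2 / d2}, clipped to [0, 1]. Zero dispersion (e.g. zero
#' scatter) yields 1, the pure target.
#'
#' @param Xc n x p matrix of centered samples (for classification, each
#'   sample centered on its own class mean).
#' @return shrinkage value in [0, 1].
#' @references Ledoit & Wolf (2004), J. Multivariate Analysis 88:365-411.
#' @export
ledoitWolfLambda <- function(Xc) {
  Xc <- asMatrix(Xc)
  n <- nrow(Xc); p <- ncol(Xc)
  if (n < 2L) stopf("need at least 2 samples for shrinkage estimation")
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2)
  if (d2 <= .Machine$double.eps * p) return(1)
  # b2bar = (1/n^2) sum_k || x_k x_k' - S ||_F^2
  X2 <- Xc^2
  sumSq <- sum(crossprod(X2))          # sum_k sum_ij (x_ki x_kj)^2
  b2bar <- (sumSq / n - sum(S^2)) / n
  b2 <- min(b2bar, d2)
  min(1, max(0, b2 / d2))
}

# pooled within-class covariance pieces shared by LDA variants:
# returns within-class centered data, class means, counts
classScatter <- function(X, clabel, K) {
  means <- matrix(0, K, ncol(X))
  Xc <- X
  for (k in seq_len(K)) {
    idx <- clabel == k
    means[k, ] <- colMeans(X[idx, , drop = FALSE])
    Xc[idx, ] <- sweep(X[idx, , drop = FALSE], 2L, means[k, ])
  }
  list(Xc = Xc, means = means, counts = classCounts(clabel, K))
}

# shrinkage-regularized covariance: (1-lambda) Semp + lambda * nu * I,
# nu = trace(Semp)/p (preserves total variance)
shrinkCovariance <- function(Semp, lambda) {
  p <- ncol(Semp)
  nu <- sum(diag(Semp)) / p
  (1 - lambda) * Semp + diag(lambda * nu, p)
}

resolveLambda <- function(lambda, Xc) {
  if (is.null(lambda) || identical(lambda, "auto"))
    return(ledoitWolfLambda(Xc))
  lambda <- as.numeric(lambda)
  if (lambda < 0 || lambda > 1)
    stopf("shrinkage lambda must lie in [0, 1], got %g", lambda)
  lambda
}

#' Train a binary LDA classifier with shrinkage regularization
#'
#' Fits linear discriminant analysis for two classes under the
#' equal-covariance Gaussian model: class means \code{m1, m2} and a pooled
#' covariance estimated from within-class centered samples (denominator
#' \code{n - 2}), regularized by shrinkage toward a scaled identity,
#' \code{Sreg = (1 - lambda) Semp + lambda nu I} with \code{nu =
#' trace(Semp)/p}. The weight vector is \code{w = Sreg^-1 (m1 - m2)} and
#' the bias places the boundary at the prior-weighted midpoint:
#' \code{b = -w.(m1 + m2)/2 + log(P1/P2)}.
#'
#' @param param list of hyperparameters: \code{lambda} in [0,1] or
#'   \code{"auto"} (Ledoit-Wolf, the default); \code{prior}
#'   \code{"empirical"} (default) or \code{"equal"}.
#' @param X n x p training data.
#' @param clabel class labels (two classes; canonicalized internally).
#' @return an object of class \code{ldaModel}: \code{w}, \code{b},
#'   \code{means}, \code{covReg}, \code{lambdaUsed}, \code{priors}.
#' @examples
#' g <- genGaussianClasses(20, p = 3, K = 2, separation = 4, seed = 1)
#' m <- trainLDA(list(), g$X, g$clabel)
#' p <- predictLDA(m, g$X)
#' mean(p$clabel == g$clabel)
#' @export
trainLDA <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets
  if (v$K != 2L) stopf("binary LDA requires exactly 2 classes, got %d", v$K)
  sc <- classScatter(X, clabel, 2L)
  lambda <- resolveLambda(param$lambda, sc$Xc)
  n <- nrow(X); p <- ncol(X)
  Semp <- crossprod(sc$Xc) / (n - 2L)
  Sreg <- shrinkCovariance(Semp, lambda)
  md <- sc$means[1L, ] - sc$means[2L, ]
  w <- tryCatch(drop(solve(Sreg, md)),
    error = function(e) stopf(paste0(
      "regularized covariance is singular (lambda = %g); ",
      "increase lambda or use lambda = 'auto'"), lambda))
  priors <- classPriors(clabel, 2L, equal = identical(param$prior, "equal"))
  b <- -sum(w * (sc$means[1L, ] + sc$means[2L, ])) / 2 +
    log(priors[1L] / priors[2L])
  structure(list(w = w, b = b, means = sc$means, covReg = Sreg,
                 lambdaUsed = lambda, priors = priors, mapping = v$mapping),
            class = c("ldaModel", "mvModel"))
}

#' @rdname trainLDA
#' @param model a fitted \code{ldaModel}.
#' @return \code{predictLDA}: a list with \code{clabel} (1/2), \code{dval}
#'   (\code{w.x + b}, positive for class 1) and \code{prob} (posterior
#'   probability of class 1 under the Gaussian model).
#' @export
predictLDA <- function(model, X) {
  X <- asMatrix(X)
  if (ncol(X) != length(model$w))
    stopf("feature count (%d) does not match training (%d)",
          ncol(X), length(model$w))
  dval <- drop(X %*% model$w) + model$b
  list(clabel = ifelse(dval >= 0, 1L, 2L), dval = dval,
       prob = stats::plogis(dval))
}

#' Train multi-class LDA
#'
#' Discriminant subspace via the generalized eigendecomposition of
#' between-class scatter against the shrinkage-regularized within-class
#' scatter. The data are projected onto the leading K-1 discriminant
#' directions, scaled so that the within-class covariance in the subspace
#' is the identity; prediction follows the maximum a posteriori rule with
#' equal-covariance Gaussians around the projected class centroids.
#'
#' @inheritParams trainLDA
#' @param clabel class labels, K >= 3 classes.
#' @return an object of class \code{multiclassLdaModel}: \code{subspace}
#'   (p x (K-1)), \code{centroids} (K x (K-1)), \code{priors},
#'   \code{lambdaUsed}.
#' @export
trainMulticlassLDA <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets; K <- v$K
  if (K < 3L) stopf("multiclass LDA requires K >= 3; use binary LDA for 2 classes")
  n <- nrow(X); p <- ncol(X)
  sc <- classScatter(X, clabel, K)
  lambda <- resolveLambda(param$lambda, sc$Xc)
  Sw <- shrinkCovariance(crossprod(sc$Xc) / (n - K), lambda)
  gm <- colMeans(X)
  Mc <- sweep(sc$means, 2L, gm)
  Sb <- crossprod(Mc * sqrt(sc$counts)) / n
  # whiten Sw, then eigendecompose the whitened between-class scatter
  ew <- eigen(Sw, symmetric = TRUE)
  if (min(ew$values) <= 0)
    stopf("within-class scatter not positive definite; increase lambda")
  Wh <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  eb <- eigen(Wh %*% Sb %*% Wh, symmetric = TRUE)
  ncomp <- K - 1L
  P <- Wh %*% eb$vectors[, seq_len(ncomp), drop = FALSE]  # P' Sw P = I
  centroids <- sc$means %*% P
  priors <- classPriors(clabel, K, equal = identical(param$prior, "equal"))
  structure(list(subspace = P, centroids = centroids, priors = priors,
                 lambdaUsed = lambda, K = K, mapping = v$mapping),
            class = c("multiclassLdaModel", "mvModel"))
}

#' @rdname trainMulticlassLDA
#' @param model a fitted \code{multiclassLdaModel}.
#' @return \code{predictMulticlassLDA}: list with \code{clabel} (MAP class)
#'   and \code{prob} (n x K posterior matrix).
#' @export
predictMulticlassLDA <- function(model, X) {
  X <- asMatrix(X)
  if (ncol(X) != nrow(model$subspace))
    stopf("feature count mismatch")
  Z <- X %*% model$subspace
  K <- model$K
  # identity within-class covariance in the subspace: MAP score is
  # -||z - c_k||^2 / 2 + log prior
  scores <- sapply(seq_len(K), function(k)
    -rowSums(sweep(Z, 2L, model$centroids[k, ])^2) / 2 +
      log(model$priors[k]))
  scores <- matrix(scores, ncol = K)
  mx <- apply(scores, 1L, max)
  pr <- exp(scores - mx)
  pr <- pr / rowSums(pr)
  list(clabel = max.col(scores, ties.method = "first"), dval = NULL,
       prob = pr)
}

#' Train Gaussian naive Bayes
#'
#' Assumes features conditionally independent given the class, each with a
#' univariate Gaussian density \code{N(m_ij, s2_ij)} for class i, feature
#' j. Posteriors are computed in the log domain via Bayes' theorem and the
#' prediction is the maximum a posteriori class. Zero variances are floored
#' at \code{1e-10} times the mean feature variance (with a warning).
#'
#' @inheritParams trainLDA
#' @return an object of class \code{naiveBayesModel}: \code{means} and
#'   \code{vars} (K x p), \code{priors}.
#' @export
trainNaiveBayes <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets; K <- v$K
  cnt <- classCounts(clabel, K)
  if (any(cnt < 2L)) stopf("naive Bayes needs >= 2 samples per class")
  p <- ncol(X)
  means <- matrix(0, K, p); vars <- matrix(0, K, p)
  for (k in seq_len(K)) {
    Xi <- X[clabel == k, , drop = FALSE]
    means[k, ] <- colMeans(Xi)
    vars[k, ] <- apply(Xi, 2L, stats::var)
  }
  floorv <- 1e-10 * mean(apply(X, 2L, stats::var))
  if (floorv <= 0) floorv <- 1e-12
  if (any(vars < floorv)) {
    warnf("zero-variance feature(s) floored in naive Bayes")
    vars <- pmax(vars, floorv)
  }
  priors <- classPriors(clabel, K, equal = identical(param$prior, "equal"))
  structure(list(means = means, vars = vars, priors = priors, K = K,
                 mapping = v$mapping),
            class = c("naiveBayesModel", "mvModel"))
}

#' @rdname trainNaiveBayes
#' @param model a fitted \code{naiveBayesModel}.
#' @return \code{predictNaiveBayes}: list with \code{clabel}, \code{prob}
#'   (n x K posteriors summing to 1 per row) and, for two classes,
#'   \code{dval} (posterior log-odds of class 1).
#' @export
predictNaiveBayes <- function(model, X) {
  X <- asMatrix(X)
  if (ncol(X) != ncol(model$means)) stopf("feature count mismatch")
  K <- model$K
  logpost <- sapply(seq_len(K), function(k) {
    rowSums(stats::dnorm(X, mean = matrix(model$means[k, ], nrow(X),
                                          ncol(X), byrow = TRUE),
                         sd = matrix(sqrt(model$vars[k, ]), nrow(X),
                                     ncol(X), byrow = TRUE), log = TRUE)) +
      log(model$priors[k])
  })
  logpost <- matrix(logpost, ncol = K)
  mx <- apply(logpost, 1L, max)
  pr <- exp(logpost - mx)
  pr <- pr / rowSums(pr)
  dval <- if (K == 2L) logpost[, 1L] - logpost[, 2L] else NULL
  list(clabel = max.col(logpost, ties.method = "first"), dval = dval,
       prob = pr)
}
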