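#' Train penalized logistic regression
#'
#' Two-class logistic regression minimizing the logistic loss
#' \code{sum_i log(1 + exp(-y_i (w.x_i + b)))} (classes coded +1/-1) plus a
#' penalty on the weights. The default \code{reg = "logf"} imposes the
#' log-F(1,1) prior on each weight (penalty \code{log(1 + exp(w_j)) -
#' w_j/2}, maximal prior density at 0); it has no tuning parameter and
#' keeps weights finite even on separable data. \code{reg = "l2"} adds
#' \code{lambda ||w||^2}. The bias is never penalized. Optimization is
#' Newton's method with backtracking line search; convergence is declared
#' when the gradient norm drops below \code{tol}.
#'
#' @param param list: \code{reg} ("logf" or "l2"), \code{lambda} (>= 0, l2
#'   only; default 0.1), \code{tol} (gradient norm, default 1e-6),
#'   \code{maxIter} (default 200).
#' @param X n x p training data; @param clabel two-class labels.
#' @return object of class \code{logregModel}: \code{w}, \code{b},
#'   \code{reg}, \code{lambdaUsed}, \code{converged}, \code{nIter}.
#' @export
trainLogreg <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets
  if (v$K != 2L) stopf("logistic regression requires 2 classes")
  reg <- if (is.null(param$reg)) "logf" else param$reg
  if (!reg %in% c("logf", "l2")) stopf("unknown regularization '%s'", reg)
  lambda <- if (is.null(param$lambda)) 0.1 else as.numeric(param$lambda)
  if (reg == "l2" && lambda < 0) stopf("lambda must be >= 0")
  tol <- if (is.null(param$tol)) 1e-6 else param$tol
  maxIter <- if (is.null(param$maxIter)) 200L else param$maxIter
  y <- ifelse(clabel == 1L, 1, -1)
  n <- nrow(X); p <- ncol(X)
  Xt <- cbind(X, 1)             # bias as last coordinate, unpenalized
  theta <- numeric(p + 1L)

  objective <- function(theta) {
    f <- drop(Xt %*% theta)
    loss <- sum(log1p(exp(-abs(y * f))) + pmax(-y * f, 0))
    pen <- switch(reg,
      logf = sum(log1p(exp(-abs(theta[1:p]))) + pmax(theta[1:p], 0) -
                 theta[1:p] / 2),
      l2 = lambda * sum(theta[1:p]^2))
    loss + pen
  }
  gradHess <- function(theta) {
    f <- drop(Xt %*% theta)
    s <- stats::plogis(-y * f)          # P(misclassified)
    g <- -drop(crossprod(Xt, y * s))
    Wdiag <- s * (1 - s)
    H <- crossprod(Xt * Wdiag, Xt)
    if (reg == "logf") {
      sj <- stats::plogis(theta[1:p])
      g[1:p] <- g[1:p] + (sj - 0.5)
      diag(H)[1:p] <- diag(H)[1:p] + sj * (1 - sj)
    } else {
      g[1:p] <- g[1:p] + 2 * lambda * theta[1:p]
      diag(H)[1:p] <- diag(H)[1:p] + 2 * lambda
    }
    list(g = g, H = H)
  }

  converged <- FALSE; it <- 0L
  obj <- objective(theta)
  while (it < maxIter) {
    it <- it + 1L
    gh <- gradHess(theta)
    if (sqrt(sum(gh$g^2)) <= tol) { converged <- TRUE; break }
    d <- tryCatch(-solve(gh$H + diag(1e-10, p + 1L), gh$g),
                  error = function(e) -gh$g)
    # backtracking line search (Armijo)
    step <- 1; armijo <- 1e-4 * sum(gh$g * d)
    repeat {
      cand <- theta + step * d
      objc <- objective(cand)
      if (objc <= obj + step * armijo || step < 1e-12) break
      step <- step / 2
    }
    if (objc > obj && step < 1e-12) break  # no descent possible
    theta <- theta + step * d; obj <- objc
  }
  if (!converged) {
    gh <- gradHess(theta)
    converged <- sqrt(sum(gh$g^2)) <= tol
    if (!converged) warnf("logistic regression did not converge in %d iterations", maxIter)
  }
  structure(list(w = theta[1:p], b = theta[p + 1L], reg = reg,
                 lambdaUsed = if (reg == "l2") lambda else NULL,
                 converged = converged, nIter = it, mapping = v$mapping),
            class = c("logregModel", "mvModel"))
}

#' @rdname trainLogreg
#' @param model a fitted \code{logregModel}.
#' @return \code{predictLogreg}: list with \code{clabel}, \code{dval}
#'   (\code{w.x + b}) and \code{prob} (logistic of dval).
#' @export
predictLogreg <- function(model, X) {
  X <- asMatrix(X)
  if (ncol(X) != length(model$w)) stopf("feature count mismatch")
  dval <- drop(X %*% model$w) + model$b
  list(clabel = ifelse(dval >= 0, 1L, 2L), dval = dval,
       prob = stats::plogis(dval))
}

#' Train a support vector machine by dual coordinate descent
#'
#' Two-class L1 soft-margin SVM. The primal problem (maximize the margin
#' subject to \code{y_i (w.x_i + b) >= 1 - xi_i}, slack penalty \code{c sum
#' xi_i}) is solved in its dual form: maximize \code{sum(alpha) - 1/2
#' alpha' Q alpha} with \code{Q_ij = y_i y_j k(x_i, x_j)} subject to \code{0
#' <= alpha_i <= c}. The bias is absorbed by augmenting the kernel with a
#' constant feature (\code{k + 1}), which keeps the dual box-constrained
#' only; each coordinate update is then available in closed form with
#' clipping. Iteration stops when the largest projected-gradient violation
#' in a sweep falls below \code{tol}.
#'
#' @param param list: \code{c} box constraint (> 0, default 1),
#'   \code{kernel} a \code{\link{kernelSpec}} or kind name (default
#'   linear), \code{prob} logical: fit Platt calibration on the training
#'   decision values (default FALSE), \code{tol} (default 1e-3),
#'   \code{maxIter} maximal sweeps (default 1000).
#' @param X n x p training data, or an n x n precomputed kernel matrix when
#'   \code{param$kernel$kind == "precomputed"}.
#' @param clabel two-class labels.
#' @return object of class \code{svmModel}: \code{alpha}, \code{support}
#'   (indices with alpha > 0), \code{w} (linear kernel only), \code{b},
#'   \code{y}, stored support samples, \code{kernel}, \code{platt}.
#' @export
trainSVM <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  clabel <- v$targets
  if (v$K != 2L) stopf("SVM requires 2 classes")
  cc <- if (is.null(param$c)) 1 else as.numeric(param$c)
  if (cc <= 0) stopf("box constraint c must be > 0")
  tol <- if (is.null(param$tol)) 1e-3 else param$tol
  maxIter <- if (is.null(param$maxIter)) 1000L else param$maxIter
  ki <- kernelInput(param$kernel, if (is(v$X, "DecodingData")) dataValues(v$X) else X)
  K <- ki$K
  n <- nrow(K)
  y <- ifelse(clabel == 1L, 1, -1)
  Kaug <- K + 1                        # constant-feature augmentation
  Qdiag <- diag(Kaug)
  alpha <- numeric(n)
  f <- numeric(n)                      # f_i = sum_j alpha_j y_j Kaug_ij
  it <- 0L
  repeat {
    it <- it + 1L
    maxViol <- 0
    for (i in seq_len(n)) {
      G <- y[i] * f[i] - 1
      PG <- if (alpha[i] <= 0) min(G, 0) else if (alpha[i] >= cc) max(G, 0) else G
      if (abs(PG) > maxViol) maxViol <- abs(PG)
      if (abs(PG) > 1e-14) {
        aNew <- min(max(alpha[i] - G / Qdiag[i], 0), cc)
        d <- aNew - alpha[i]
        if (d != 0) {
          f <- f + d * y[i] * Kaug[, i]
          alpha[i] <- aNew
        }
      }
    }
    if (maxViol <= tol || it >= maxIter) break
  }
  b <- sum(alpha * y)                  # augmentation constant's weight
  sv <- which(alpha > 1e-12)
  w <- if (ki$spec$kind == "linear")
    drop(crossprod(ki$X, alpha * y)) else NULL
  model <- structure(list(alpha = alpha, support = sv, y = y,
                          Xtrain = ki$X, w = w, b = b, c = cc,
                          kernel = ki$spec, nIter = it, platt = NULL,
                          mapping = v$mapping),
                     class = c("svmModel", "mvModel"))
  if (isTRUE(param$prob)) {
    dv <- svmDval(model, Xtest = ki$X, Ktest = K)
    model$platt <- fitPlatt(dv, clabel)
  }
  model
}

# decision values given test data (or test-kernel rows against training)
svmDval <- function(model, Xtest = NULL, Ktest = NULL) {
  if (is.null(Ktest)) {
    if (model$kernel$kind == "precomputed")
      stopf("precomputed-kernel SVM needs a test x train kernel matrix")
    Ktest <- computeKernelMatrix(model$kernel, asMatrix(Xtest), model$Xtrain)
  }
  drop(Ktest %*% (model$alpha * model$y)) + model$b
}

#' @rdname trainSVM
#' @param model a fitted \code{svmModel}.
#' @return \code{predictSVM}: list with \code{clabel}, \code{dval}, and
#'   \code{prob} (only when Platt calibration was fitted).
#' @export
predictSVM <- function(model, X) {
  if (model$kernel$kind == "precomputed") {
    dval <- svmDval(model, Ktest = asMatrix(X))
  } else {
    X <- asMatrix(X)
    if (!is.null(model$w) && ncol(X) != length(model$w))
      stopf("feature count mismatch")
    dval <- svmDval(model, Xtest = X)
  }
  prob <- if (!is.null(model$platt)) plattProb(model$platt, dval) else NULL
  list(clabel = ifelse(dval >= 0, 1L, 2L), dval = dval, prob = prob)
}

#' Platt probability calibration
#'
#' Fits the sigmoid \code{P(class 1 | dval) = 1 / (1 + exp(A dval + B))} to
#' decision values by regularized maximum likelihood with the standard
#' smoothed targets \code{(N1 + 1)/(N1 + 2)} and \code{1/(N2 + 2)} (N1, N2
#' the class counts), so fitted probabilities never reach 0 or 1 even for
#' perfectly separated inputs. Optimized by Newton's method with
#' backtracking.
#'
#' @param dval numeric decision values (positive toward class 1).
#' @param clabel two-class labels aligned with \code{dval}.
#' @return list with elements \code{A}, \code{B}.
#' @references Platt (1999); Lin, Lin & Weng (2007) for the stable
#'   pseudo-code followed here.
#' @export
fitPlatt <- function(dval, clabel) {
  v <- if (all(clabel %in% c(1L, 2L))) list(targets = as.integer(clabel))
       else validateInputs(matrix(0, length(clabel), 1), clabel)["targets"]
  clabel <- v$targets
  if (length(unique(clabel)) < 2L) stopf("both classes required for calibration")
  if (max(dval) - min(dval) < 1e-12)
    stopf("degenerate decision values: all equal, cannot calibrate")
  n1 <- sum(clabel == 1L); n2 <- sum(clabel == 2L)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n2 + 2)
  t <- ifelse(clabel == 1L, hi, lo)
  A <- 0; B <- log((n2 + 1) / (n1 + 1))
  fApB <- A * dval + B
  objfun <- function(fApB)
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  obj <- objfun(fApB)
  for (it in 1:100) {
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(dval * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(dval * dval * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(dval * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      fNew <- (A + step * dA) * dval + (B + step * dB)
      objNew <- objfun(fNew)
      if (objNew < obj + 1e-4 * step * gd || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    fApB <- fNew; obj <- objNew
  }
  list(A = A, B = B)
}

plattProb <- function(platt, dval) {
  fApB <- platt$A * dval + platt$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train an ensemble of classifiers on random sample/feature subsets
#'
#' Trains \code{nLearners} base classifiers, each on a seeded random subset
#' of \code{nsamples} training samples and \code{nfeatures} features. At
#' test time, \code{strategy = "vote"} selects the class with the most
#' votes (ties broken toward the smallest class index); \code{strategy =
#' "dval"} averages raw decision values and takes the sign (two classes,
#' dval-capable learners only).
#'
#' @param param list: \code{learner} model name (default "lda"),
#'   \code{learnerParam} hyperparameters passed to each learner,
#'   \code{nLearners} (default 50), \code{nsamples} (default n/2 rounded
#'   up), \code{nfeatures} (default p/2 rounded up), \code{strategy}
#'   ("vote" or "dval"), \code{seed}.
#' @param X training data; @param clabel class labels.
#' @return object of class \code{ensembleModel}.
#' @export
trainEnsemble <- function(param = list(), X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets
  learner <- if (is.null(param$learner)) "lda" else param$learner
  strategy <- if (is.null(param$strategy)) "vote" else param$strategy
  if (!strategy %in% c("vote", "dval")) stopf("unknown strategy '%s'", strategy)
  nL <- if (is.null(param$nLearners)) 50L else as.integer(param$nLearners)
  n <- nrow(X); p <- ncol(X)
  ns <- if (is.null(param$nsamples)) ceiling(n / 2) else as.integer(param$nsamples)
  nf <- if (is.null(param$nfeatures)) ceiling(p / 2) else as.integer(param$nfeatures)
  if (ns > n || nf > p) stopf("subset sizes exceed data size")
  seed <- if (is.null(param$seed)) 1L else param$seed
  lp <- if (is.null(param$learnerParam)) list() else param$learnerParam
  learners <- vector("list", nL)
  sampleIdx <- vector("list", nL); featureIdx <- vector("list", nL)
  for (l in seq_len(nL)) {
    si <- withSeed(childSeed(seed, "ensemble-sample", l), sort(sample.int(n, ns)))
    fi <- withSeed(childSeed(seed, "ensemble-feature", l), sort(sample.int(p, nf)))
    # guard: subset must retain both classes; redraw deterministically if not
    tries <- 0L
    while (length(unique(clabel[si])) < 2L && tries < 100L) {
      tries <- tries + 1L
      si <- withSeed(childSeed(seed, "ensemble-sample", l, tries),
                     sort(sample.int(n, ns)))
    }
    learners[[l]] <- trainModel(learner, lp, X[si, fi, drop = FALSE],
                                clabel[si])
    sampleIdx[[l]] <- si; featureIdx[[l]] <- fi
  }
  structure(list(learners = learners, learner = learner,
                 sampleIdx = sampleIdx, featureIdx = featureIdx,
                 strategy = strategy, K = v$K, mapping = v$mapping),
            class = c("ensembleModel", "mvModel"))
}

#' @rdname trainEnsemble
#' @param model a fitted \code{ensembleModel}.
#' @export
predictEnsemble <- function(model, X) {
  X <- asMatrix(X)
  preds <- lapply(seq_along(model$learners), function(l)
    predictModel(model$learner, model$learners[[l]],
                 X[, model$featureIdx[[l]], drop = FALSE]))
  if (model$strategy == "dval") {
    dv <- lapply(preds, `[[`, "dval")
    if (any(vapply(dv, is.null, logical(1))))
      stopf("strategy 'dval' requires dval-capable learners")
    dval <- rowMeans(do.call(cbind, dv))
    return(list(clabel = ifelse(dval >= 0, 1L, 2L), dval = dval,
                prob = NULL))
  }
  votes <- do.call(cbind, lapply(preds, `[[`, "clabel"))
  clabel <- apply(votes, 1L, function(vv) {
    tb <- tabulate(vv, nbins = model$K)
    which.max(tb)                      # ties -> smallest class index
  })
  list(clabel = as.integer(clabel), dval = NULL, prob = NULL)
}
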