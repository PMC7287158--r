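# Independent oracle implementations used to verify the package's
# closed-form and iterative solvers. These deliberately follow different
# computational routes than the package code.

# Ledoit-Wolf shrinkage intensity, transcribed step by step with explicit
# loops over the sample outer products (no shared code with the package).
oracleLedoitWolf <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- matrix(0, p, p)
  for (k in seq_len(n)) S <- S + tcrossprod(Xc[k, ])
  S <- S / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2)
  if (d2 < 1e-300) return(1)
  b2bar <- 0
  for (k in seq_len(n)) b2bar <- b2bar + sum((tcrossprod(Xc[k, ]) - S)^2)
  b2bar <- b2bar / n^2
  min(1, max(0, min(b2bar, d2) / d2))
}

# generic convex-optimizer solution of the penalized logistic objective
oracleLogregL2 <- function(X, y, lambda) {
  p <- ncol(X)
  obj <- function(theta) {
    f <- drop(cbind(X, 1) %*% theta)
    sum(log1p(exp(-y * f))) + lambda * sum(theta[1:p]^2)
  }
  stats::optim(numeric(p + 1), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# box-constrained QP oracle for the SVM dual (bias via kernel
# augmentation): maximize sum(a) - a' Q a / 2, 0 <= a <= c
oracleSvmDual <- function(K, y, c) {
  n <- length(y)
  Q <- (K + 1) * tcrossprod(y)
  negDual <- function(a) -(sum(a) - 0.5 * drop(a %*% Q %*% a))
  negGrad <- function(a) -(1 - drop(Q %*% a))
  stats::optim(rep(c / 2, n), negDual, negGrad, method = "L-BFGS-B",
               lower = 0, upper = c,
               control = list(maxit = 5000, factr = 1e1))$par
}

# regularized-MLE Platt sigmoid via a generic optimizer
oraclePlatt <- function(dval, clabel) {
  n1 <- sum(clabel == 1); n2 <- sum(clabel == 2)
  t <- ifelse(clabel == 1, (n1 + 1) / (n1 + 2), 1 / (n2 + 2))
  obj <- function(ab) {
    f <- ab[1] * dval + ab[2]
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)),
               (t - 1) * f + log1p(exp(f))))
  }
  stats::optim(c(0, 0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# brute-force pairwise AUC with ties counted 1/2
oracleAuc <- function(dval, truth) {
  d1 <- dval[truth == 1]; d2 <- dval[truth == 2]
  tot <- 0
  for (a in d1) for (b in d2)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(d1) * length(d2))
}

# two-cloud toy set reused across classifier tests
makeTwoClass <- function(n = 40, p = 4, sep = 3, seed = 1)
  genGaussianClasses(n, p = p, K = 2, separation = sep, seed = seed)

# concentric-circles data: radius decides the class (not linearly
# separable)
makeCircles <- function(nPerClass = 60, noise = 0.05, seed = 1) {
  set.seed(seed)
  th <- runif(2 * nPerClass, 0, 2 * pi)
  r <- rep(c(1, 2.5), each = nPerClass) + rnorm(2 * nPerClass, sd = noise)
  list(X = cbind(r * cos(th), r * sin(th)),
       clabel = rep(1:2, each = nPerClass))
}
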