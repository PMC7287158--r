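test_that("Ledoit-Wolf estimate matches an independent transcription and clips", {
  set.seed(42)
  Xc <- scale(matrix(rnorm(500), 50, 10), scale = FALSE)
  expect_equal(ledoitWolfLambda(Xc), oracleLedoitWolf(Xc), tolerance = 1e-12)
  # several shapes, always in [0, 1]
  for (s in 1:5) {
    set.seed(s)
    Xc <- scale(matrix(rnorm(15 * 8), 15, 8), scale = FALSE)
    lam <- ledoitWolfLambda(Xc)
    expect_gte(lam, 0); expect_lte(lam, 1)
    expect_equal(lam, oracleLedoitWolf(Xc), tolerance = 1e-12)
  }
  # zero scatter (two identical centered rows) -> pure target
  expect_equal(ledoitWolfLambda(matrix(0, 2, 3)), 1)
  expect_error(ledoitWolfLambda(matrix(1, 1, 3)), "2 samples")
})

test_that("LDA recovers symmetric geometry", {
  # classes mirrored through the origin with equal sizes -> b = 0
  set.seed(1)
  X1 <- matrix(rnorm(40), 20, 2) + matrix(c(2, 1), 20, 2, byrow = TRUE)
  X <- rbind(X1, -X1)
  lab <- rep(1:2, each = 20)
  m <- trainLDA(list(lambda = 0.1), X, lab)
  expect_equal(m$b, 0, tolerance = 1e-10)

  # lambda = 1 (identity-shaped covariance): w parallel to m1 - m2
  g <- genGaussianClasses(50, p = 2, K = 2, separation = 2, seed = 2)
  m1 <- trainLDA(list(lambda = 1), g$X, g$clabel)
  md <- colMeans(g$X[g$clabel == 1, ]) - colMeans(g$X[g$clabel == 2, ])
  cosang <- sum(m1$w * md) / sqrt(sum(m1$w^2) * sum(md^2))
  expect_equal(cosang, 1, tolerance = 1e-12)

  # regularized covariance is symmetric positive definite
  expect_true(isSymmetric(m1$covReg))
  expect_gt(min(eigen(m1$covReg, symmetric = TRUE)$values), 0)
})

test_that("LDA predictions agree with least-squares on +/-1-coded labels", {
  for (s in 1:3) {
    g <- makeTwoClass(n = 25, p = 4, sep = 1.5, seed = s)
    m <- trainLDA(list(lambda = 0), g$X, g$clabel)
    pred <- predictLDA(m, g$X)
    fit <- lm.fit(cbind(1, g$X), ifelse(g$clabel == 1, 1, -1))
    olsSign <- sign(drop(cbind(1, g$X) %*% fit$coefficients))
    expect_equal(sign(pred$dval), olsSign)
  }
})

test_that("LDA decision values and posteriors follow the linear rule", {
  # hand-built model: w = Sigma^-1 (m1 - m2) = (2, 0), b = 0
  model <- structure(list(w = c(2, 0), b = 0), class = "ldaModel")
  pr <- predictLDA(model, matrix(c(2, 0), 1))
  expect_equal(pr$dval, 4)           # w.x + b = 2*2
  expect_equal(pr$clabel, 1L)        # dval > 0 -> first class

  # midpoint of the class means with equal priors -> prob 0.5
  g <- makeTwoClass(seed = 4)
  m <- trainLDA(list(prior = "equal"), g$X, g$clabel)
  mid <- (m$means[1, ] + m$means[2, ]) / 2
  pm <- predictLDA(m, matrix(mid, 1))
  expect_equal(pm$prob, 0.5, tolerance = 1e-12)
  expect_error(predictLDA(m, matrix(0, 2, 7)), "feature count")
})

test_that("shrinkage moves the covariance monotonically toward the scaled identity", {
  g <- makeTwoClass(n = 30, p = 6, seed = 5)
  lams <- seq(0, 1, by = 0.2)
  covs <- lapply(lams, function(l)
    trainLDA(list(lambda = l), g$X, g$clabel)$covReg)
  p <- 6
  nu <- sum(diag(covs[[1]])) / p
  dists <- vapply(covs, function(S) sqrt(sum((S - diag(nu, p))^2)),
                  numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
  expect_equal(dists[length(dists)], 0, tolerance = 1e-12)
})

test_that("LDA decision values are invariant under sample permutation", {
  g <- makeTwoClass(seed = 6)
  m1 <- trainLDA(list(lambda = 0.2), g$X, g$clabel)
  set.seed(9); perm <- sample(nrow(g$X))
  m2 <- trainLDA(list(lambda = 0.2), g$X[perm, ], g$clabel[perm])
  Xt <- matrix(rnorm(20), 10, 4)
  expect_equal(predictLDA(m1, Xt)$dval, predictLDA(m2, Xt)$dval,
               tolerance = 1e-10)
})

test_that("multiclass LDA spans K-1 discriminants and recovers centroids", {
  g <- genGaussianClasses(30, p = 5, K = 3, separation = 8, seed = 7)
  m <- trainMulticlassLDA(list(), g$X, g$clabel)
  expect_equal(ncol(m$subspace), 2L)
  # test points at the empirical class centroids go to their own class
  centro <- t(sapply(1:3, function(k) colMeans(g$X[g$clabel == k, ])))
  pr <- predictMulticlassLDA(m, centro)
  expect_equal(pr$clabel, 1:3)
  expect_equal(rowSums(pr$prob), rep(1, 3), tolerance = 1e-12)
  expect_error(trainMulticlassLDA(list(), g$X,
                                  ifelse(g$clabel == 3, 1, g$clabel)),
               "binary LDA")
})

test_that("naive Bayes posteriors equal the hand-computed product of densities", {
  # 2 features, tiny hand-checkable set
  X <- rbind(c(0, 0), c(1, 1), c(0.5, 0), c(4, 4), c(5, 5), c(4.5, 4))
  lab <- c(1, 1, 1, 2, 2, 2)
  m <- trainNaiveBayes(list(), X, lab)
  xt <- matrix(c(1, 2), 1)
  pr <- predictNaiveBayes(m, xt)
  lik <- sapply(1:2, function(k)
    prod(dnorm(xt, m$means[k, ], sqrt(m$vars[k, ]))) * m$priors[k])
  expect_equal(pr$prob[1, ], lik / sum(lik), tolerance = 1e-10)

  # posterior rows always sum to 1
  g <- genGaussianClasses(20, p = 3, K = 3, separation = 2, seed = 8)
  m3 <- trainNaiveBayes(list(), g$X, g$clabel)
  pr3 <- predictNaiveBayes(m3, g$X)
  expect_equal(rowSums(pr3$prob), rep(1, nrow(g$X)), tolerance = 1e-12)
})

test_that("naive Bayes with one feature thresholds at the symmetric midpoint", {
  set.seed(10)
  X <- matrix(c(rnorm(200, 1), rnorm(200, -1)))
  lab <- rep(1:2, each = 200)
  m <- trainNaiveBayes(list(prior = "equal"), X, lab)
  expect_equal(predictNaiveBayes(m, matrix(2))$clabel, 1L)
  expect_equal(predictNaiveBayes(m, matrix(-2))$clabel, 2L)
  # decision boundary near 0: probabilities flip across it
  b <- uniroot(function(x)
    predictNaiveBayes(m, matrix(x))$prob[1, 1] - 0.5, c(-1, 1))$root
  expect_lt(abs(b), 0.15)
})

test_that("naive Bayes approaches LDA when covariances are diagonal and equal", {
  g <- genGaussianClasses(1500, p = 4, K = 2, separation = 2,
                          covariance = "diagonal", seed = 11)
  nb <- trainNaiveBayes(list(), g$X, g$clabel)
  ld <- trainLDA(list(lambda = 0), g$X, g$clabel)
  Xt <- genGaussianClasses(100, p = 4, K = 2, separation = 2,
                           covariance = "diagonal", seed = 12)$X
  agree <- mean(predictNaiveBayes(nb, Xt)$clabel ==
                predictLDA(ld, Xt)$clabel)
  expect_gt(agree, 0.95)
})

test_that("zero-variance features are floored with a warning", {
  X <- cbind(c(1, 1, 5, 5, 1, 5), rnorm(6))
  lab <- c(1, 1, 2, 2, 1, 2)
  expect_warning(m <- trainNaiveBayes(list(), X, lab), "floored")
  expect_true(all(m$vars > 0))
})
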