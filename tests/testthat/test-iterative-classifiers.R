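test_that("log-F penalized logistic regression stays finite on separable data", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3))
  lab <- c(2, 2, 2, 1, 1, 1)
  m <- trainLogreg(list(reg = "logf"), X, lab)
  expect_true(all(is.finite(m$w)))
  expect_true(m$converged)
  # data symmetric under (x, y) -> (-x, -y): b = 0 at the optimum
  expect_equal(m$b, 0, tolerance = 1e-6)
})

test_that("L2 logistic regression matches a generic convex optimizer", {
  g <- makeTwoClass(n = 15, p = 3, sep = 1, seed = 21)
  y <- ifelse(g$clabel == 1, 1, -1)
  m <- trainLogreg(list(reg = "l2", lambda = 1), g$X, g$clabel)
  theta <- oracleLogregL2(g$X, y, lambda = 1)
  expect_equal(c(m$w, m$b), theta, tolerance = 1e-6)
  expect_error(trainLogreg(list(reg = "l2", lambda = -1), g$X, g$clabel),
               ">= 0")
})

test_that("logistic predictions evaluate the sigmoid of w.x + b", {
  m <- structure(list(w = c(2), b = -1), class = "logregModel")
  pr <- predictLogreg(m, matrix(1))
  expect_equal(pr$dval, 1)
  expect_equal(pr$prob, 1 / (1 + exp(-1)), tolerance = 1e-12)
  m0 <- structure(list(w = c(1, 0), b = 0), class = "logregModel")
  pr0 <- predictLogreg(m0, matrix(c(0, 0), 1))
  expect_equal(pr0$dval, 0)
  expect_equal(pr0$prob, 0.5)
})

test_that("SVM solves the two-point problem exactly", {
  X <- rbind(c(1, 0), c(-1, 0))
  lab <- c(1, 2)
  m <- trainSVM(list(c = 100), X, lab)
  expect_equal(m$w, c(1, 0), tolerance = 1e-3)
  expect_equal(m$b, 0, tolerance = 1e-3)
  expect_equal(predictSVM(m, matrix(c(1, 0), 1))$dval, 1, tolerance = 1e-3)
  expect_error(trainSVM(list(c = -1), X, lab), "c must be")
})

test_that("SVM dual solutions are feasible and satisfy complementary slackness", {
  for (s in 1:3) {
    g <- makeTwoClass(n = 12, p = 3, sep = 2, seed = 30 + s)
    m <- trainSVM(list(c = 1, tol = 1e-6), g$X, g$clabel)
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= 1 + 1e-12))
    # samples strictly outside the margin carry zero dual weight
    marg <- m$y * predictSVM(m, g$X)$dval
    outside <- which(marg > 1 + 1e-4)
    expect_true(all(m$alpha[outside] < 1e-6))
  }
})

test_that("SVM coordinate descent agrees with an exhaustive QP oracle", {
  for (s in 1:2) {
    g <- makeTwoClass(n = 6, p = 2, sep = 1.5, seed = 40 + s)  # n = 12
    y <- ifelse(g$clabel == 1, 1, -1)
    K <- tcrossprod(g$X)
    m <- trainSVM(list(c = 1, tol = 1e-8, maxIter = 5000), g$X, g$clabel)
    aStar <- oracleSvmDual(K, y, c = 1)
    dual <- function(a) { Q <- (K + 1) * tcrossprod(y)
                          sum(a) - 0.5 * drop(a %*% Q %*% a) }
    expect_equal(dual(m$alpha), dual(aStar), tolerance = 1e-5)
    expect_equal(m$alpha, aStar, tolerance = 1e-3)
  }
})

test_that("linear-kernel dvals via explicit w equal the dual expansion", {
  g <- makeTwoClass(seed = 50)
  m <- trainSVM(list(c = 0.5), g$X, g$clabel)
  Xt <- matrix(rnorm(40), 10, 4)
  viaW <- drop(Xt %*% m$w) + m$b
  viaDual <- predictSVM(m, Xt)$dval
  expect_equal(viaW, viaDual, tolerance = 1e-8)
})

test_that("RBF kernel with a large width solves XOR on the training set", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c(1, 1, 2, 2)
  mBig <- trainSVM(list(c = 100, kernel = kernelSpec("rbf", gamma = 10)),
                   X, lab)
  expect_equal(predictSVM(mBig, X)$clabel, lab)
  # no linear separator exists for XOR: at most 3 of 4 points correct
  mLin <- trainSVM(list(c = 100), X, lab)
  expect_lte(mean(predictSVM(mLin, X)$clabel == lab), 0.75)
})

test_that("Platt calibration matches the published algorithm's optimum", {
  set.seed(60)
  dval <- c(rnorm(30, 1), rnorm(30, -1))
  lab <- rep(1:2, each = 30)
  fit <- fitPlatt(dval, lab)
  ab <- oraclePlatt(dval, lab)
  expect_equal(c(fit$A, fit$B), ab, tolerance = 1e-4)
  expect_lt(fit$A, 0)  # probability increases with dval
})

test_that("Platt probabilities are smoothed away from 0 and 1", {
  dval <- c(5, 6, 7, -5, -6, -7)
  lab <- c(1, 1, 1, 2, 2, 2)
  fit <- fitPlatt(dval, lab)
  m <- trainSVM(list(c = 10, prob = TRUE), matrix(dval), lab)
  pr <- predictSVM(m, matrix(dval))$prob
  expect_true(all(pr > 0 & pr < 1))
  # monotone in dval when A < 0
  expect_true(all(diff(pr[order(dval)]) >= 0))
  expect_error(fitPlatt(rep(1, 6), lab), "degenerate")
})

test_that("degenerate ensemble reproduces its base learner", {
  g <- makeTwoClass(seed = 70)
  e <- trainEnsemble(list(learner = "lda", nLearners = 1L,
                          nsamples = nrow(g$X), nfeatures = ncol(g$X),
                          strategy = "dval", seed = 3),
                     g$X, g$clabel)
  base <- trainLDA(list(), g$X, g$clabel)
  Xt <- matrix(rnorm(40), 10, 4)
  expect_equal(predictEnsemble(e, Xt)$dval, predictLDA(base, Xt)$dval,
               tolerance = 1e-10)
})

test_that("ensemble voting uses plurality with deterministic ties", {
  fake <- list(learners = list(NULL, NULL, NULL),
               learner = "stub", featureIdx = list(1, 1, 1),
               strategy = "vote", K = 2L)
  class(fake) <- c("ensembleModel", "mvModel")
  votes <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  registerModel("stub",
                train = function(param, X, t) list(),
                predict = local({ i <- 0
                  function(model, X) { i <<- i + 1
                    list(clabel = votes[[i]], dval = NULL) } }),
                task = "classification")
  pr <- predictEnsemble(fake, matrix(0, 2, 1))
  expect_equal(pr$clabel[1], 1L)  # votes 1,1,2 -> 1
  expect_equal(pr$clabel[2], 2L)  # votes 1,2,2 -> 2
  # two-learner tie goes to the smallest class index
  fake2 <- fake; fake2$learners <- list(NULL, NULL)
  fake2$featureIdx <- list(1, 1)
  votes2 <- list(1L, 2L)
  registerModel("stub",
                train = function(param, X, t) list(),
                predict = local({ i <- 0
                  function(model, X) { i <<- i + 1
                    list(clabel = votes2[[i]], dval = NULL) } }),
                task = "classification")
  expect_equal(predictEnsemble(fake2, matrix(0, 1, 1))$clabel, 1L)
  # dval strategy requires dval-capable learners
  registerModel("stub", train = function(param, X, t) list(),
                predict = function(model, X)
                  list(clabel = 1L, dval = NULL),
                task = "classification")
  expect_error(predictEnsemble(local({f <- fake2; f$strategy <- "dval"; f}),
                               matrix(0, 1, 1)),
               "dval")
})
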