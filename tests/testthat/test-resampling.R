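test_that("k-fold plans partition the samples with balanced sizes", {
  plan <- makeFolds("kfold", n = 10, k = 5, seed = 1)
  sets <- plan$testSets[[1]]
  expect_length(sets, 5)
  expect_equal(sort(unlist(sets)), 1:10)
  expect_true(all(lengths(sets) == 2))
  # uneven n: sizes differ by at most 1
  plan2 <- makeFolds("kfold", n = 11, k = 3, seed = 2)
  expect_lte(diff(range(lengths(plan2$testSets[[1]]))), 1)
  expect_error(makeFolds("kfold", n = 4, k = 5), "exceeds")
})

test_that("stratified folds preserve class proportions", {
  labels <- rep(c(1, 2), c(6, 4))
  plan <- makeFolds("kfold", n = 10, k = 2, labels = labels,
                    stratify = TRUE, seed = 3)
  for (te in plan$testSets[[1]]) {
    expect_equal(sum(labels[te] == 1), 3)
    expect_equal(sum(labels[te] == 2), 2)
  }
  # per-class counts across folds never differ by more than 1
  labels2 <- rep(1:3, c(10, 7, 5))
  plan2 <- makeFolds("kfold", n = 22, k = 4, labels = labels2,
                     stratify = TRUE, seed = 4)
  for (cl in 1:3) {
    cnts <- vapply(plan2$testSets[[1]], function(te)
      sum(labels2[te] == cl), numeric(1))
    expect_lte(diff(range(cnts)), 1)
  }
})

test_that("leaveout, holdout, predefined and none behave as defined", {
  lo <- makeFolds("leaveout", n = 7)
  expect_length(lo$testSets[[1]], 7)
  expect_true(all(lengths(lo$testSets[[1]]) == 1))

  ho <- makeFolds("holdout", n = 20, p = 0.25, seed = 5)
  expect_length(ho$testSets[[1]][[1]], 5)
  expect_error(makeFolds("holdout", n = 20, p = 1.2), "\\(0, 1\\)")

  pd <- makeFolds("predefined", n = 6, fold = c(1, 1, 2, 2, 3, 3))
  expect_equal(pd$testSets[[1]], list(1:2, 3:4, 5:6))
  expect_error(makeFolds("predefined", n = 6, fold = c(1, 2)), "length")

  no <- makeFolds("none", n = 5)
  expect_equal(no$testSets[[1]][[1]], 1:5)
})

test_that("cross-validation is reproducible and hits expected regimes", {
  g0 <- genGaussianClasses(40, p = 5, K = 2, separation = 0, seed = 10)
  cfg <- list(model = "lda", metric = "accuracy", k = 5, `repeat` = 3,
              seed = 11)
  r1 <- crossValidate(cfg, g0$X, g0$clabel)
  r2 <- crossValidate(cfg, g0$X, g0$clabel)
  expect_identical(metricValues(r1), metricValues(r2))
  expect_lt(abs(metricValues(r1) - 0.5), 0.15)   # chance level
  gs <- genGaussianClasses(40, p = 5, K = 2, separation = 8, seed = 12)
  rs <- crossValidate(cfg, gs$X, gs$clabel)
  expect_gt(metricValues(rs), 0.95)              # separable limit
})

test_that("equal-sized folds make the weighted average a pooled mean", {
  g <- genGaussianClasses(20, p = 3, K = 2, separation = 2, seed = 13)
  r <- crossValidate(list(model = "lda", metric = "accuracy", k = 4,
                          seed = 14), g$X, g$clabel)
  acc <- vapply(r@perFold, function(f) f$values$accuracy, numeric(1))
  expect_equal(metricValues(r), mean(acc), tolerance = 1e-12)
})

test_that("training-set evaluation is optimistic relative to cross-validation", {
  deltas <- vapply(1:10, function(s) {
    g <- genGaussianClasses(15, p = 10, K = 2, separation = 1, seed = s)
    tr <- crossValidate(list(model = "lda", metric = "accuracy",
                             cv = "none"), g$X, g$clabel)
    cv <- crossValidate(list(model = "lda", metric = "accuracy", k = 5,
                             seed = s), g$X, g$clabel)
    metricValues(tr) - metricValues(cv)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("grid search selects the inner-CV argmax and respects grid order", {
  g <- genRegression(25, p = 40, noiseSd = 2, seed = 20)  # p >> n
  cfg <- list(model = "ridge", tuneK = 4, seed = 21)
  grid <- list(lambda = c(0.001, 0.01, 0.1, 1, 10))
  best <- tuneHyperparameters(grid, cfg, g$X, g$y)
  # the winner scores at least as well as every other candidate
  scoreOf <- function(lam) {
    icfg <- list(model = "ridge", hyperparameter = list(lambda = lam),
                 metric = "mse", cv = "kfold", k = 4,
                 seed = childSeed(21, "tune"), stratify = FALSE)
    plan <- makeFolds("kfold", n = nrow(g$X), k = 4, stratify = FALSE,
                      seed = childSeed(21, "tune"))
    icfg$foldPlan <- plan
    metricValues(crossValidate(icfg, g$X, g$y), "mse")
  }
  scores <- vapply(grid$lambda, scoreOf, numeric(1))
  expect_equal(best$lambda, grid$lambda[which.min(scores)])
  # single candidate returned untouched
  one <- tuneHyperparameters(list(lambda = 0.5), cfg, g$X, g$y)
  expect_equal(one$lambda, 0.5)
})

test_that("tuning and training never see the test fold", {
  g <- genGaussianClasses(30, p = 4, K = 2, separation = 1, seed = 30)
  plan <- makeFolds("kfold", n = 60, k = 5, labels = g$clabel,
                    stratify = TRUE, seed = 31)
  te <- plan$testSets[[1]][[1]]
  cfg <- resolveCfg(list(model = "lda",
                         hyperparameter = list(lambda = c(0, 0.1, 0.5)),
                         metric = "accuracy", seed = 31,
                         foldPlan = plan))
  fit1 <- mvdecode:::cvFitFold(cfg, g$X, g$clabel, plan, 1, 1,
                               "classification", 2L)
  # arbitrary perturbation of test-fold rows
  Xp <- g$X; Xp[te, ] <- matrix(rnorm(length(te) * 4, sd = 50),
                                length(te))
  fit2 <- mvdecode:::cvFitFold(cfg, Xp, g$clabel, plan, 1, 1,
                               "classification", 2L)
  expect_identical(fit1$tunedParam, fit2$tunedParam)
  expect_identical(fit1$model$w, fit2$model$w)
  expect_identical(fit1$model$b, fit2$model$b)
})
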