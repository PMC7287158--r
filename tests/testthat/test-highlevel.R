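test_that("shape contracts: search dims give vectors, generalization gives matrices", {
  e <- genErpLike(10, nChannels = 4, nTime = 5, amplitude = 0, seed = 1)
  cfg <- list(model = "lda", metric = "accuracy", k = 5, seed = 2)
  r <- mvClassify(cfg, e$X, e$clabel)
  expect_length(metricValues(r), 5)
  tt <- mvClassifyTimextime(cfg, e$X, e$clabel)
  expect_equal(dim(metricValues(tt)), c(5L, 5L))
  e2 <- genErpLike(10, nChannels = 4, nTime = 2, amplitude = 1, seed = 3)
  tt2 <- mvClassifyTimextime(cfg, e2$X, e2$clabel)
  expect_equal(dim(metricValues(tt2)), c(2L, 2L))
  expect_error(mvClassifyAcrossTime(cfg, matrix(0, 4, 4), rep(1:2, 2)),
               "3-D")
})

test_that("specialized drivers equal the general driver under matched seeds", {
  e <- genErpLike(12, nChannels = 4, nTime = 4, amplitude = 1.5, seed = 4)
  cfg <- list(model = "lda", metric = "accuracy", k = 4, seed = 5)
  rAT <- mvClassifyAcrossTime(cfg, e$X, e$clabel)
  rGen <- mvClassify(cfg, DecodingData(e$X), e$clabel)
  expect_equal(metricValues(rAT), metricValues(rGen))
  # time x time diagonal equals across-time with the shared fold plan
  tt <- mvClassifyTimextime(cfg, e$X, e$clabel)
  expect_equal(diag(metricValues(tt)), as.numeric(metricValues(rAT)),
               tolerance = 1e-12)
  # T = 1 equals a direct crossValidate call
  e1 <- genErpLike(12, nChannels = 4, nTime = 1, amplitude = 1, seed = 6,
                   windows = list(1))
  r1 <- mvClassifyAcrossTime(cfg, e1$X, e1$clabel)
  rd <- crossValidate(cfg, e1$X[, , 1], e1$clabel)
  expect_equal(as.numeric(metricValues(r1)), metricValues(rd))
})

test_that("a planted effect is decodable only inside its window", {
  e <- genErpLike(40, nChannels = 8, nTime = 10, amplitude = 2,
                  windows = list(4:6), seed = 7)
  r <- mvClassifyAcrossTime(list(model = "lda", metric = "accuracy",
                                 k = 5, `repeat` = 2, seed = 8),
                            e$X, e$clabel)
  acc <- as.numeric(metricValues(r))
  expect_gt(mean(acc[4:6]), 0.8)
  expect_lt(mean(acc[-(4:6)]), 0.65)
})

test_that("a pattern shared across two windows generalizes off-diagonal", {
  e <- genErpLike(40, nChannels = 8, nTime = 8, amplitude = 2,
                  windows = list(2:3, 6:7), seed = 9)
  tt <- mvClassifyTimextime(list(model = "lda", metric = "accuracy",
                                 k = 5, seed = 10), e$X, e$clabel)
  M <- metricValues(tt)
  expect_gt(mean(M[2:3, 6:7]), 0.8)   # train early, test late
  expect_gt(mean(M[6:7, 2:3]), 0.8)
  expect_lt(mean(M[c(1, 4, 5, 8), c(1, 4, 5, 8)][upper.tri(diag(4))]), 0.7)
})

test_that("searchlight feature construction follows the neighbourhood", {
  X <- array(seq_len(6 * 2 * 9), c(6, 2, 9))
  nb <- radiusNeighbours(9, 1)
  f5 <- buildSearchlightFeatures(X, 5, nb)
  expect_equal(dim(f5), c(6L, 6L))
  expect_equal(f5, cbind(X[, , 4], X[, , 5], X[, , 6]))
  # boundary: centre 1 sees positions {1, 2} only, no wraparound
  f1 <- buildSearchlightFeatures(X, 1, nb)
  expect_equal(f1, cbind(X[, , 1], X[, , 2]))
  # full-ones neighbourhood: every centre sees all positions
  fAll <- buildSearchlightFeatures(X, 3, matrix(1, 9, 9))
  expect_equal(dim(fAll), c(6L, 18L))
  expect_error(buildSearchlightFeatures(X, 1, matrix(1, 3, 3)), "9 x 9")
  expect_error(checkNeighbours(diag(0, 9), 9), "diagonal")
})

test_that("identity neighbourhood reproduces the plain sweep", {
  e <- genErpLike(12, nChannels = 4, nTime = 4, amplitude = 1, seed = 11)
  cfg <- list(model = "lda", metric = "accuracy", k = 4, seed = 12)
  plain <- mvClassify(cfg, e$X, e$clabel)
  cfgNb <- cfg; cfgNb$neighbours <- diag(4)
  withNb <- mvClassify(cfgNb, e$X, e$clabel)
  expect_equal(metricValues(plain), metricValues(withNb))
  # radius-1 searchlight pools neighbouring time points
  cfgR <- cfg; cfgR$neighbours <- radiusNeighbours(4, 1)
  rR <- mvClassify(cfgR, e$X, e$clabel)
  expect_length(metricValues(rR), 4)
})

test_that("cube neighbourhoods cover the 3x3x3 searchlight with truncation", {
  nb <- cubeNeighbours(c(3, 3, 3), 1)
  expect_equal(dim(nb), c(27L, 27L))
  expect_equal(sum(nb[14, ]), 27)  # centre voxel sees the whole cube
  expect_equal(sum(nb[1, ]), 8)    # corner voxel: 2x2x2 truncated cube
  expect_true(all(diag(nb) == 1))
})

test_that("regression sweeps localize a planted temporal effect", {
  set.seed(13)
  n <- 50; p <- 4; T <- 5
  X <- array(rnorm(n * p * T), c(n, p, T))
  w <- c(2, -1, 0.5, 1)
  y <- drop(X[, , 3] %*% w) + rnorm(n, sd = 0.3)
  r <- mvRegress(list(model = "ridge",
                      hyperparameter = list(lambda = 0.1),
                      metric = c("mse", "r_squared"), k = 5, seed = 14,
                      stratify = FALSE), X, y)
  mse <- as.numeric(metricValues(r, "mse"))
  expect_equal(which.min(mse), 3L)
  r2 <- as.numeric(metricValues(r, "r_squared"))
  expect_lt(max(r2[-3]), 0.3)      # no signal elsewhere
  expect_gt(r2[3], 0.7)
})

test_that("generalization refuses precomputed kernels", {
  e <- genErpLike(10, nChannels = 3, nTime = 3, amplitude = 1, seed = 15)
  cfg <- list(model = "svm",
              hyperparameter = list(kernel = "precomputed"),
              k = 5, seed = 16)
  expect_error(mvClassifyTimextime(cfg, e$X, e$clabel), "precomputed")
})
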