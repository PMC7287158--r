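test_that("binomial test computes exact tails", {
  expect_equal(pValues(binomialTest(1, 10, 0.5)), 2^-10)
  # brute-force tail sum P(X >= 50), n = 100
  pBrute <- sum(dbinom(50:100, 100, 0.5))
  expect_equal(pValues(binomialTest(0.5, 100, 0.5)), pBrute,
               tolerance = 1e-12)
  expect_gt(pValues(binomialTest(0.5, 1000, 0.5)), 0.05)
  expect_error(binomialTest(0.9, 10, 0), "chance")
})

test_that("level-1 permutation p-values respect the add-one rule", {
  g <- genGaussianClasses(15, p = 3, K = 2, separation = 6, seed = 1)
  res <- permutationTestLevel1(list(model = "lda", metric = "accuracy",
                                    k = 5, seed = 2),
                               g$X, g$clabel, nPermutations = 19, seed = 3)
  expect_gte(min(pValues(res)), 1 / 20)
  # strongly separated data: observed beats every permutation
  expect_equal(pValues(res), 1 / 20)
  # reproducible given the seed
  res2 <- permutationTestLevel1(list(model = "lda", metric = "accuracy",
                                     k = 5, seed = 2),
                                g$X, g$clabel, nPermutations = 19, seed = 3)
  expect_identical(pValues(res), pValues(res2))
  expect_identical(nullDistribution(res), nullDistribution(res2))
})

test_that("cluster extraction reproduces the hand example", {
  map <- c(0.5, 0.7, 0.72, 0.5)
  nullMaps <- matrix(0.5, 10, 4)   # permutations never cross threshold
  res <- clusterPermutationTest(map, nullMaps, critical = 0.6, alpha = 0.1)
  recs <- clusterRecords(res)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$members, c(2L, 3L))
  expect_equal(recs[[1]]$statistic, 1.42)
  # smallest attainable p with 10 permutations under the add-one rule
  expect_equal(recs[[1]]$p, 1 / 11)
  expect_equal(which(significanceMask(res)), c(2L, 3L))
  # cluster size as alternative statistic
  resSize <- clusterPermutationTest(map, nullMaps, critical = 0.6,
                                    statistic = "size")
  expect_equal(clusterRecords(resSize)[[1]]$statistic, 2)
})

test_that("maps below threshold yield an empty, valid result", {
  res <- clusterPermutationTest(rep(0.4, 6), matrix(0.4, 5, 6),
                                critical = 0.6)
  expect_length(clusterRecords(res), 0)
  expect_false(any(significanceMask(res)))
})

test_that("grid connectivity joins orthogonal neighbours only", {
  m <- matrix(0, 3, 3)
  m[1, 1] <- 1; m[2, 2] <- 1   # diagonal touch: two separate clusters
  cl <- mvdecode:::findClusters(as.numeric(m), 0.5, c(3, 3))
  expect_length(cl, 2)
  m2 <- matrix(0, 3, 3)
  m2[1, 1] <- 1; m2[2, 1] <- 1  # orthogonal neighbours: one cluster
  cl2 <- mvdecode:::findClusters(as.numeric(m2), 0.5, c(3, 3))
  expect_length(cl2, 1)
  expect_equal(cl2[[1]], c(1L, 2L))
})

test_that("level-2 within design flags a real region and not an exact null", {
  # exact null: all subjects identically at the null value
  flat <- matrix(0.5, 12, 20)
  r0 <- level2PermutationTest(flat, "within", "mean", nullValue = 0.5,
                              nPermutations = 100, seed = 1)
  expect_false(any(significanceMask(r0)))
  # planted region recovered with cluster correction
  maps <- genGroupLevel(16, 50, effect = 0.08, effectRegion = 15:30,
                        sd = 0.04, seed = 2)
  r1 <- level2PermutationTest(maps, "within", "t", nullValue = 0.5,
                              nPermutations = 300, critical = 2,
                              alternative = "greater", seed = 3)
  sig <- which(significanceMask(r1))
  expect_gt(length(intersect(sig, 15:30)), 12)
  expect_lt(length(setdiff(sig, 15:30)), 4)
})

test_that("level-2 between design and statistic guards work", {
  maps <- genGroupLevel(20, 10, sd = 0.05, seed = 4)
  groups <- rep(1:2, each = 10)
  r <- level2PermutationTest(maps, "between", "ranksum", groups = groups,
                             nPermutations = 200, seed = 5)
  expect_true(all(pValues(r) >= 1 / 201))
  expect_error(level2PermutationTest(maps, "between", "wilcoxon",
                                     groups = groups), "within")
  expect_error(level2PermutationTest(maps, "within", "ranksum",
                                     nullValue = 0.5), "between")
  expect_error(level2PermutationTest(maps[1, , drop = FALSE], "within",
                                     nullValue = 0.5), "2 subjects")
})

test_that("cluster correction controls family-wise rejections on null maps", {
  set.seed(6)
  anyCluster <- 0L; anyElement <- 0L
  nSim <- 40
  for (i in seq_len(nSim)) {
    map <- runif(30, 0.45, 0.75)
    nullMaps <- matrix(runif(30 * 60, 0.45, 0.75), 60, 30)
    cres <- clusterPermutationTest(map, nullMaps, critical = 0.6)
    # cluster members always exceed the critical value
    for (rec in clusterRecords(cres))
      expect_true(all(map[rec$members] > 0.6))
    pel <- (1 + colSums(sweep(nullMaps, 2, map, ">="))) / 61
    anyCluster <- anyCluster + any(significanceMask(cres))
    anyElement <- anyElement + any(pel <= 0.05)
  }
  # whole-map false positives: corrected rate stays near alpha while
  # elementwise testing inflates far above it across the 30-element map
  expect_lte(anyCluster, anyElement)
  expect_lte(anyCluster / nSim, 0.15)
  expect_gte(anyElement / nSim, 0.4)
})
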