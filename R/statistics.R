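#' Binomial test for classification accuracy
#'
#' Exact binomial tail test of the null hypothesis that classification
#' accuracy is at chance: with \code{k = round(accuracy * n)} correct test
#' predictions out of \code{n}, \code{p = P(X >= k)} for \code{X ~
#' Binomial(n, chance)}.
#'
#' @param accuracy observed classification accuracy in [0, 1].
#' @param nTest number of test predictions.
#' @param chance chance level in (0, 1), e.g. 1/K.
#' @param alpha significance level.
#' @return a \linkS4class{StatTestResult} with a scalar p-value.
#' @examples
#' pValues(binomialTest(1, 10, 0.5))  # 2^-10
#' @export
binomialTest <- function(accuracy, nTest, chance = 0.5, alpha = 0.05) {
  if (chance <= 0 || chance >= 1) stopf("chance must be in (0, 1)")
  k <- round(accuracy * nTest)
  p <- stats::pbinom(k - 1, nTest, chance, lower.tail = FALSE)
  new("StatTestResult", statistic = accuracy, p = p, mask = p <= alpha,
      nullDistribution = numeric(0), clusters = list(),
      nPermutations = 0L, alpha = alpha, method = "binomial",
      seed = NA_integer_)
}

#' Level-1 permutation test of a decoding analysis
#'
#' Non-parametric test within one dataset: the observed metric map is
#' computed by the standard cross-validated analysis; a null distribution
#' is created by shuffling the class labels (or responses) and repeating
#' the complete analysis for each permutation. Elementwise p-values use
#' the add-one rule \code{p = (1 + #(null >= observed)) / (1 +
#' nPermutations)} for higher-is-better metrics (reversed for mse/mae), so
#' p-values are never smaller than \code{1/(1 + nPermutations)}.
#'
#' @param cfg analysis configuration (see \code{\link{mvClassify}}); the
#'   first entry of \code{cfg$metric} is tested.
#' @param X data matrix, array, or \linkS4class{DecodingData}.
#' @param targets class labels or responses.
#' @param nPermutations number of label permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param alpha significance level.
#' @return a \linkS4class{StatTestResult}; \code{nullDistribution} holds
#'   the permutation metric maps as an [nPermutations x elements] matrix.
#' @export
permutationTestLevel1 <- function(cfg, X, targets, nPermutations = 1000L,
                                  seed = 1L, alpha = 0.05) {
  if (nPermutations < 1L) stopf("need at least one permutation")
  cfg <- resolveCfg(cfg)
  task <- modelTask(cfg$model)
  if (is.null(cfg$metric))
    cfg$metric <- if (task == "regression") "mse" else "accuracy"
  metric <- cfg$metric[1L]
  higher <- metricDirection(metric)
  if (is.na(higher))
    stopf("metric '%s' has no direction; cannot be permutation-tested", metric)
  runOnce <- function(tg) {
    r <- if (length(dim2(X)) > 2L || is(X, "DecodingData"))
      mvDrive(cfg, X, tg, task)
    else crossValidate(cfg, X, tg)
    as.numeric(metricValues(r, metric))
  }
  observed <- runOnce(targets)
  nullMaps <- matrix(NA_real_, nPermutations, length(observed))
  for (b in seq_len(nPermutations)) {
    tg <- withSeed(childSeed(seed, "perm", b), sample(targets))
    nullMaps[b, ] <- runOnce(tg)
  }
  exceed <- if (higher)
    colSums(sweep(nullMaps, 2L, observed, ">=") * 1)
  else colSums(sweep(nullMaps, 2L, observed, "<=") * 1)
  p <- (1 + exceed) / (1 + nPermutations)
  new("StatTestResult", statistic = observed, p = p, mask = p <= alpha,
      nullDistribution = nullMaps, clusters = list(),
      nPermutations = as.integer(nPermutations), alpha = alpha,
      method = "permutation (level 1)", seed = as.integer(seed))
}

dim2 <- function(X) if (is.null(dim(X))) length(X) else dim(X)

# ---- cluster machinery --------------------------------------------------

# connected components of suprathreshold elements. mapDims: the array
# shape of the map (orthogonal-neighbour connectivity: 2-connectivity in
# 1-D, 4 in 2-D, 6 in 3-D). adjacency: optional explicit binary matrix.
findClusters <- function(values, critical, mapDims = length(values),
                         adjacency = NULL) {
  supra <- which(values > critical)
  if (length(supra) == 0L) return(list())
  inSupra <- logical(length(values)); inSupra[supra] <- TRUE
  neighboursOf <- function(i) {
    if (!is.null(adjacency)) return(which(adjacency[i, ] != 0 &
                                          seq_along(values) != i))
    idx <- arrayInd(i, mapDims)
    out <- integer(0)
    for (a in seq_along(mapDims)) {
      for (s in c(-1L, 1L)) {
        nb <- idx; nb[a] <- nb[a] + s
        if (nb[a] >= 1L && nb[a] <= mapDims[a]) {
          stride <- cumprod(c(1L, mapDims[-length(mapDims)]))
          out <- c(out, as.integer(1L + sum((nb - 1L) * stride)))
        }
      }
    }
    out
  }
  seen <- logical(length(values))
  clusters <- list()
  for (s in supra) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      members <- c(members, cur)
      for (nb in neighboursOf(cur)) {
        if (inSupra[nb] && !seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
  }
  clusters
}

clusterStat <- function(values, members, statistic) {
  if (statistic == "size") length(members) else sum(values[members])
}

#' Cluster-based permutation test on a metric map
#'
#' Family-wise-error-controlling test over a multi-element metric map
#' (time points, time-frequency bins, voxels). Elements exceeding
#' \code{critical} are grouped into connected clusters under the adjacency
#' rule (orthogonal grid neighbours by default: 4-connectivity in 2-D, 6
#' in 3-D; or an explicit adjacency matrix). Each cluster's statistic is
#' its mass (sum of member values; \code{statistic = "size"} counts
#' members instead). The null distribution is the maximal cluster
#' statistic of each permutation map; cluster p-values are the
#' add-one-corrected fraction of null maxima at or above the observed
#' cluster statistic.
#'
#' @param map numeric array: observed metric map.
#' @param nullMaps [nPermutations x elements] matrix of permutation metric
#'   maps (e.g. from \code{\link{permutationTestLevel1}}), or a function
#'   \code{function(b)} returning the b-th permutation map.
#' @param critical critical value forming clusters (e.g. 0.6 for
#'   accuracy), an absolute threshold on the metric.
#' @param alpha significance level.
#' @param adjacency optional explicit adjacency matrix.
#' @param statistic "mass" (default) or "size".
#' @param nPermutations required when \code{nullMaps} is a generator
#'   function.
#' @return a \linkS4class{StatTestResult}; \code{clusterRecords} holds the
#'   member indices, statistic and p per cluster, and the mask marks
#'   members of significant clusters.
#' @references Maris & Oostenveld (2007), J. Neurosci. Methods 164:177-190.
#' @export
clusterPermutationTest <- function(map, nullMaps, critical, alpha = 0.05,
                                   adjacency = NULL,
                                   statistic = c("mass", "size"),
                                   nPermutations = NULL) {
  statistic <- match.arg(statistic)
  mapDims <- dim2(map)
  values <- as.numeric(map)
  if (is.function(nullMaps)) {
    if (is.null(nPermutations)) stopf("nPermutations required with a generator")
    gen <- nullMaps
  } else {
    nullMaps <- as.matrix(nullMaps)
    nPermutations <- nrow(nullMaps)
    gen <- function(b) nullMaps[b, ]
  }
  clusters <- findClusters(values, critical, mapDims, adjacency)
  nullMax <- vapply(seq_len(nPermutations), function(b) {
    nm <- as.numeric(gen(b))
    cl <- findClusters(nm, critical, mapDims, adjacency)
    if (length(cl) == 0L) 0
    else max(vapply(cl, function(m) clusterStat(nm, m, statistic),
                    numeric(1)))
  }, numeric(1))
  records <- lapply(clusters, function(m) {
    cs <- clusterStat(values, m, statistic)
    list(members = m, statistic = cs,
         p = (1 + sum(nullMax >= cs)) / (1 + nPermutations))
  })
  mask <- array(FALSE, mapDims)
  p <- array(1, mapDims)
  for (rec in records) {
    p[rec$members] <- rec$p
    if (rec$p <= alpha) mask[rec$members] <- TRUE
  }
  new("StatTestResult", statistic = map, p = p, mask = mask,
      nullDistribution = nullMax, clusters = records,
      nPermutations = as.integer(nPermutations), alpha = alpha,
      method = paste0("cluster permutation (", statistic, ")"),
      seed = NA_integer_)
}

# ---- level 2 (group) tests ----------------------------------------------

level2Statistic <- function(diffs, statistic) {
  # diffs: subjects x elements matrix of per-subject differences
  n <- nrow(diffs)
  switch(statistic,
    mean = colMeans(diffs),
    t = {
      s <- apply(diffs, 2L, stats::sd)
      colMeans(diffs) / (s / sqrt(n))
    },
    wilcoxon = apply(diffs, 2L, function(d) {
      r <- rank(abs(d)); sum(r[d > 0]) - sum(r) / 2   # centered signed-rank
    }),
    stopf("statistic '%s' is not valid for a within-subject design",
          statistic))
}

level2BetweenStatistic <- function(values, groups, statistic) {
  i1 <- groups == 1L; i2 <- groups == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  switch(statistic,
    mean = colMeans(values[i1, , drop = FALSE]) -
           colMeans(values[i2, , drop = FALSE]),
    t = apply(values, 2L, function(x) {
      sp2 <- ((n1 - 1) * stats::var(x[i1]) + (n2 - 1) * stats::var(x[i2])) /
        (n1 + n2 - 2)
      (mean(x[i1]) - mean(x[i2])) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }),
    ranksum = apply(values, 2L, function(x) {
      r <- rank(x)
      sum(r[i1]) - n1 * (n1 + n2 + 1) / 2   # centered rank sum
    }),
    stopf("statistic '%s' is not valid for a between-subjects design",
          statistic))
}

#' Level-2 (group-level) permutation test
#'
#' Tests per-subject metric maps at the group level; no decoding is
#' performed, the level-1 metrics are subjected to a permutation test.
#' Designs:
#' \describe{
#'   \item{within, single value}{each subject contributes one map,
#'     tested against \code{nullValue} (e.g. AUC vs 0.5). The null is
#'     created by randomly swapping each subject's value with its null
#'     value, i.e. a per-subject sign flip of the difference map.
#'     Statistics: "mean", "t", "wilcoxon" (signed rank).}
#'   \item{within, paired}{\code{values2} supplies the paired second
#'     condition (e.g. class-wise mean decision values); the difference
#'     maps are tested against zero with per-subject pair swaps.}
#'   \item{between}{\code{groups} (1/2) partitions subjects; statistics
#'     "mean", "t", "ranksum"; the null randomly reassigns subjects to
#'     groups.}
#' }
#' With \code{critical} set, cluster correction is applied over the map
#' exactly as in \code{\link{clusterPermutationTest}}, the cluster
#' statistic being the mass of the suprathreshold group-level statistic.
#'
#' @param values [subjects x elements] matrix (a vector is treated as one
#'   element per subject... i.e. subjects x 1).
#' @param design "within" or "between".
#' @param statistic "mean", "t", "wilcoxon" (within), "ranksum" (between).
#' @param nullValue scalar null value for the single-value within design.
#' @param values2 paired second-condition maps (within design).
#' @param groups group labels (1/2) for the between design.
#' @param nPermutations number of permutations.
#' @param alpha significance level.
#' @param alternative "two.sided" (default), "greater", or "less".
#' @param critical optional cluster-forming threshold on the statistic
#'   map; enables cluster correction.
#' @param adjacency optional adjacency matrix for cluster formation.
#' @param seed integer seed.
#' @return a \linkS4class{StatTestResult}.
#' @export
level2PermutationTest <- function(values, design = c("within", "between"),
                                  statistic = c("t", "mean", "wilcoxon",
                                                "ranksum"),
                                  nullValue = NULL, values2 = NULL,
                                  groups = NULL, nPermutations = 1000L,
                                  alpha = 0.05,
                                  alternative = c("two.sided", "greater",
                                                  "less"),
                                  critical = NULL, adjacency = NULL,
                                  seed = 1L) {
  design <- match.arg(design)
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  values <- as.matrix(values)
  nSub <- nrow(values)
  if (nSub < 2L) stopf("need at least 2 subjects")
  if (design == "within") {
    if (statistic == "ranksum")
      stopf("ranksum is a between-subjects statistic; use wilcoxon for within")
    if (!is.null(values2)) {
      values2 <- as.matrix(values2)
      if (!all(dim(values2) == dim(values)))
        stopf("paired values must have equal dimensions")
      diffs <- values - values2
    } else {
      if (is.null(nullValue))
        stopf("within design needs either paired values2 or a nullValue")
      diffs <- values - nullValue
    }
    observed <- level2Statistic(diffs, statistic)
    draw <- function(b) {
      signs <- withSeed(childSeed(seed, "l2", b),
                        sample(c(-1, 1), nSub, replace = TRUE))
      level2Statistic(diffs * signs, statistic)
    }
  } else {
    if (statistic == "wilcoxon")
      stopf("wilcoxon signed-rank is a within-subject statistic; use ranksum")
    if (is.null(groups) || length(groups) != nSub)
      stopf("between design needs a group label per subject")
    groups <- as.integer(factor(groups))
    observed <- level2BetweenStatistic(values, groups, statistic)
    draw <- function(b) {
      g <- withSeed(childSeed(seed, "l2", b), sample(groups))
      level2BetweenStatistic(values, g, statistic)
    }
  }
  nullStats <- vapply(seq_len(nPermutations), draw,
                      numeric(length(observed)))
  nullStats <- if (is.null(dim(nullStats))) matrix(nullStats, ncol = 1L)
               else t(nullStats)
  side <- function(x) switch(alternative, two.sided = abs(x),
                             greater = x, less = -x)
  if (!is.null(critical)) {
    res <- clusterPermutationTest(side(observed),
                                  nullMaps = side(nullStats),
                                  critical = critical, alpha = alpha,
                                  adjacency = adjacency)
    return(new("StatTestResult", statistic = observed, p = res@p,
               mask = res@mask, nullDistribution = res@nullDistribution,
               clusters = res@clusters,
               nPermutations = as.integer(nPermutations), alpha = alpha,
               method = paste0("cluster permutation (level 2, ", design,
                               ", ", statistic, ")"),
               seed = as.integer(seed)))
  }
  exceed <- colSums(sweep(side(nullStats), 2L, side(observed), ">=") * 1)
  p <- (1 + exceed) / (1 + nPermutations)
  new("StatTestResult", statistic = observed, p = p, mask = p <= alpha,
      nullDistribution = as.numeric(nullStats), clusters = list(),
      nPermutations = as.integer(nPermutations), alpha = alpha,
      method = paste0("permutation (level 2, ", design, ", ", statistic,
                      ")"),
      seed = as.integer(seed))
}
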