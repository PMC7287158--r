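#' Neighbourhood matrices for searchlight analysis
#'
#' A neighbourhood is a binary [positions x positions] matrix per search
#' dimension: entry (v, u) = 1 if position u belongs to the searchlight
#' centred on v. Every centre belongs to its own searchlight (unit
#' diagonal). \code{radiusNeighbours} builds the 1-D chain neighbourhood
#' (all positions within \code{radius}, truncated at the edges, no
#' wraparound); \code{cubeNeighbours} builds the neighbourhood of a 3-D
#' voxel grid where each searchlight is the cube of half-width
#' \code{halfWidth} (1 gives the 3x3x3 cube), truncated at the volume
#' boundary.
#'
#' @param nPositions number of positions along the dimension.
#' @param radius integer radius.
#' @return binary neighbourhood matrix.
#' @export
radiusNeighbours <- function(nPositions, radius = 1L) {
  outer(seq_len(nPositions), seq_len(nPositions),
        function(v, u) as.numeric(abs(v - u) <= radius))
}

#' @rdname radiusNeighbours
#' @param gridDims integer vector of 3 voxel-grid dimensions.
#' @param halfWidth cube half-width.
#' @export
cubeNeighbours <- function(gridDims, halfWidth = 1L) {
  stopifnot(length(gridDims) == 3L)
  pos <- as.matrix(expand.grid(lapply(gridDims, seq_len)))
  n <- nrow(pos)
  nb <- matrix(0, n, n)
  for (v in seq_len(n)) {
    within <- abs(sweep(pos, 2L, pos[v, ])) <= halfWidth
    nb[v, ] <- as.numeric(rowSums(within) == 3L)
  }
  nb
}

checkNeighbours <- function(nb, len) {
  if (!is.matrix(nb) || nrow(nb) != len || ncol(nb) != len)
    stopf("neighbourhood matrix must be %d x %d", len, len)
  if (any(diag(nb) != 1))
    stopf("neighbourhood diagonal must be all 1 (centre belongs to its own searchlight)")
  nb
}

#' Extract searchlight features for one centre
#'
#' Concatenates the features of all neighbourhood members of \code{centre}
#' along the feature axis of a 3-D [samples x features x positions] array,
#' assigning the result to the centre position.
#'
#' @param X 3-D array [samples x features x positions].
#' @param centre centre position index.
#' @param neighbours binary neighbourhood matrix (positions x positions).
#' @return [samples x (features * members)] matrix.
#' @export
buildSearchlightFeatures <- function(X, centre, neighbours) {
  stopifnot(length(dim(X)) == 3L)
  checkNeighbours(neighbours, dim(X)[3L])
  members <- which(neighbours[centre, ] != 0)
  m <- X[, , members, drop = FALSE]
  dim(m) <- c(dim(X)[1L], dim(X)[2L] * length(members))
  m
}

# ---- internal canonicalization for the general drivers ------------------

# Returns arr3 [n x p x nGrid], grid metadata, and coordinates.
mvPrepare <- function(cfg, X, targets, task) {
  if (!is(X, "DecodingData"))
    X <- DecodingData(as.array(X), dimRoles = cfg$dimRoles,
                      dimCoords = if (is.null(cfg$dimCoords)) list()
                                  else cfg$dimCoords)
  v <- validateInputs(X, targets,
                      type = if (task == "regression") "regression"
                             else "classification")
  arr <- dataValues(v$X); roles <- dimRoles(v$X); coords <- dimCoords(v$X)
  sDim <- which(roles == "sample")
  fDims <- which(roles == "feature")
  srDims <- which(roles == "search")
  gDim <- which(roles == "generalization")
  perm <- c(sDim, fDims, srDims, gDim)
  arr <- aperm(arr, perm)
  d <- dim(arr)
  n <- d[1L]
  p <- prod(d[1L + seq_along(fDims)])
  gridShape <- d[-seq_len(1L + length(fDims))]
  if (length(gridShape) == 0L) gridShape <- integer(0)
  dim(arr) <- c(n, p, max(1L, prod(gridShape)))
  searchShape <- if (length(srDims)) d[1L + length(fDims) + seq_along(srDims)]
                 else integer(0)
  G <- if (length(gDim)) d[length(d)] else 0L
  list(arr3 = arr, n = n, p = p, targets = v$targets, K = v$K,
       searchShape = as.integer(searchShape), G = as.integer(G),
       searchCoords = coords[srDims], genCoord = if (length(gDim)) coords[[gDim]])
}

# linear index into the grid [searchShape, (G)] from a search combo and
# optional generalization index
gridIndex <- function(combo, searchShape, gen = NULL, G = 0L) {
  shape <- c(searchShape, if (G > 0L) G)
  idx <- c(combo, gen)
  if (length(shape) == 0L) return(1L)
  stride <- cumprod(c(1L, shape[-length(shape)]))
  as.integer(1L + sum((idx - 1L) * stride))
}

# features for a search combo (with neighbourhood expansion) at an
# optional generalization index
sliceFeatures <- function(prep, combo, neighbours = NULL, gen = NULL) {
  ss <- prep$searchShape
  if (length(ss) == 0L) {
    li <- gridIndex(integer(0), ss, gen, prep$G)
    return(matrix(prep$arr3[, , li], nrow = prep$n))
  }
  memberSets <- lapply(seq_along(ss), function(a) {
    if (is.null(neighbours)) combo[a]
    else which(neighbours[[a]][combo[a], ] != 0)
  })
  memberCombos <- as.matrix(expand.grid(memberSets))
  cols <- lapply(seq_len(nrow(memberCombos)), function(i) {
    li <- gridIndex(memberCombos[i, ], ss, gen, prep$G)
    prep$arr3[, , li]
  })
  out <- do.call(cbind, cols)
  matrix(out, nrow = prep$n)
}

resolveNeighbours <- function(cfg, searchShape) {
  nb <- cfg$neighbours
  if (is.null(nb)) return(NULL)
  if (is.matrix(nb)) nb <- list(nb)
  if (length(nb) != length(searchShape))
    stopf("need one neighbourhood matrix per search dimension")
  for (a in seq_along(nb)) checkNeighbours(nb[[a]], searchShape[a])
  nb
}

usesPrecomputedKernel <- function(cfg) {
  k <- cfg$hyperparameter$kernel
  (is.character(k) && identical(k, "precomputed")) ||
    (is.list(k) && identical(k$kind, "precomputed"))
}

# shared implementation of mvClassify / mvRegress
mvDrive <- function(cfg, X, targets, task) {
  cfg <- resolveCfg(cfg)
  if (is.null(cfg$metric))
    cfg$metric <- if (task == "regression") "mse" else "accuracy"
  prep <- mvPrepare(cfg, X, targets, task)
  if (prep$G > 0L && usesPrecomputedKernel(cfg))
    stopf("precomputed kernels cannot be combined with a generalization dimension")
  neighbours <- resolveNeighbours(cfg, prep$searchShape)
  plan <- makeFolds(cfg$cv, n = prep$n, k = cfg$k, p = cfg$p,
                    repeats = cfg$`repeat`,
                    labels = if (task == "classification") prep$targets,
                    stratify = if (is.null(cfg$stratify))
                      task == "classification" else isTRUE(cfg$stratify),
                    fold = cfg$fold, seed = cfg$seed)
  cfg$foldPlan <- plan
  nSearch <- max(1L, prod(prep$searchShape))
  combos <- if (length(prep$searchShape))
    as.matrix(expand.grid(lapply(prep$searchShape, seq_len)))
  else matrix(integer(0), 1L, 0L)
  metrics <- cfg$metric
  if (prep$G == 0L) {
    store <- lapply(metrics, function(m) vector("list", nSearch))
    for (gi in seq_len(nSearch)) {
      Xs <- sliceFeatures(prep, combos[gi, ], neighbours)
      out <- cvRun(cfg, Xs, prep$targets, plan, task, K = prep$K)
      for (j in seq_along(metrics))
        store[[j]][[gi]] <- out$metrics[[j]]
    }
    resDims <- prep$searchShape
  } else {
    store <- lapply(metrics, function(m)
      vector("list", nSearch * prep$G * prep$G))
    for (gi in seq_len(nSearch)) {
      M <- mvGeneralize(cfg, prep, combos[gi, ], neighbours, plan, task)
      for (j in seq_along(metrics)) {
        for (v in seq_len(prep$G)) for (u in seq_len(prep$G))
          store[[j]][[gi + nSearch * ((v - 1L) + prep$G * (u - 1L))]] <-
            M[[j]][v, u]
      }
    }
    resDims <- c(prep$searchShape, prep$G, prep$G)
  }
  metricArrays <- lapply(seq_along(metrics), function(j) {
    vals <- store[[j]]
    if (all(vapply(vals, function(x) is.numeric(x) && length(x) == 1L,
                   logical(1)))) {
      a <- unlist(vals)
      if (length(resDims) > 1L) dim(a) <- resDims
      if (length(resDims) == 0L) a <- a[[1L]]
      a
    } else if (length(resDims) == 0L) vals[[1L]] else {
      dim(vals) <- if (length(resDims) > 1L) resDims else NULL
      vals
    }
  })
  new("DecodingResult",
      metrics = stats::setNames(metricArrays, metrics),
      perFold = list(), dims = as.integer(resDims),
      coords = c(prep$searchCoords,
                 if (prep$G > 0L) list(train = prep$genCoord,
                                       test = prep$genCoord)),
      cfg = cfg[setdiff(names(cfg), "foldPlan")])
}

# generalization engine: train at index v, test at every u, inside CV.
# Returns one G x G matrix per metric (test-size weighted across folds,
# averaged across repeats).
mvGeneralize <- function(cfg, prep, combo, neighbours, plan, task) {
  G <- prep$G
  metrics <- cfg$metric
  repAgg <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    nf <- length(plan$testSets[[r]])
    foldMats <- vector("list", nf)
    sizes <- numeric(nf)
    for (f in seq_len(nf)) {
      te <- plan$testSets[[r]][[f]]
      tr <- trainIndices(plan, r, f)
      sizes[f] <- length(te)
      M <- lapply(metrics, function(m) matrix(NA_real_, G, G))
      for (v in seq_len(G)) {
        Xv <- sliceFeatures(prep, combo, neighbours, gen = v)
        pp <- runPipeline(cfg$preprocess, Xv[tr, , drop = FALSE],
                          prep$targets[tr],
                          seed = childSeed(cfg$seed, "pp", r, f))
        param <- cfg$hyperparameter
        if (any(vapply(param, isCandidateList, logical(1))))
          param <- tuneHyperparameters(param, cfg, pp$Xtrain,
                                       pp$targetsTrain)
        model <- trainModel(cfg$model, param, pp$Xtrain, pp$targetsTrain)
        for (u in seq_len(G)) {
          Xu <- sliceFeatures(prep, combo, neighbours, gen = u)
          Xte <- Xu[te, , drop = FALSE]; tte <- prep$targets[te]
          if (length(pp$steps)) {
            for (i in seq_along(pp$steps)) {
              ap <- applyStep(pp$steps[[i]], Xte, tte,
                              seed = childSeed(cfg$seed, "step", i))
              Xte <- ap$X; tte <- ap$targets
            }
          }
          pred <- predictModel(cfg$model, model, Xte)
          for (j in seq_along(metrics))
            M[[j]][v, u] <- computeMetric(metrics[j], pred, tte, task,
                                          prep$K)
        }
      }
      foldMats[[f]] <- M
    }
    repAgg[[r]] <- lapply(seq_along(metrics), function(j)
      weightedFoldAverage(lapply(foldMats, `[[`, j), sizes))
  }
  lapply(seq_along(metrics), function(j)
    Reduce(`+`, lapply(repAgg, `[[`, j)) / plan$repeats)
}

#' General-purpose decoding over arbitrary data dimensions
#'
#' Sweeps cross-validated classification over every combination of the
#' search dimensions of the data (with optional searchlight expansion via
#' \code{cfg$neighbours}), and handles one generalization dimension by
#' training at each index and testing at all indices (e.g. time-by-time
#' decoding). Fold plans are generated once and shared across all grid
#' points, so specialized drivers agree with this function elementwise
#' under matched seeds.
#'
#' @param cfg configuration list as for \code{\link{crossValidate}}, plus
#'   \code{dimRoles}/\code{dimCoords} (when \code{X} is a raw array) and
#'   \code{neighbours} (matrix or list of per-search-dimension matrices).
#' @param X a \linkS4class{DecodingData} or numeric array (axis 1 samples,
#'   axis 2 features, further axes search by default).
#' @param clabel class labels.
#' @return a \linkS4class{DecodingResult} whose metric arrays have the
#'   shape of the search grid (a generalization dimension appears twice,
#'   train x test).
#' @examples
#' g <- genErpLike(15, nChannels = 6, nTime = 8, amplitude = 2, seed = 1)
#' r <- mvClassify(list(model = "lda", metric = "accuracy", k = 5,
#'                      seed = 1), g$X, g$clabel)
#' dim(metricValues(r, "accuracy"))  # length-8 vector over time
#' @export
mvClassify <- function(cfg, X, clabel) mvDrive(cfg, X, clabel,
                                               "classification")

#' Decoding at every time point of a 3-D dataset
#'
#' Convenience driver for [samples x features x time] arrays: runs
#' cross-validated classification at each time point, returning a vector
#' of metrics over time. Identical to \code{\link{mvClassify}} with the
#' third axis tagged as a search dimension.
#'
#' @inheritParams mvClassify
#' @param X 3-D array [samples x features x time].
#' @export
mvClassifyAcrossTime <- function(cfg, X, clabel) {
  if (length(dim(X)) != 3L) stopf("expected a 3-D [samples x features x time] array")
  cfg$dimRoles <- c("sample", "feature", "search")
  mvClassify(cfg, if (is(X, "DecodingData")) dataValues(X) else X, clabel)
}

#' Temporal generalization (time-by-time decoding)
#'
#' For [samples x features x time] data, trains at every time point and
#' tests at every time point within the cross-validation scheme, producing
#' a [train time x test time] metric matrix. The diagonal equals
#' \code{\link{mvClassifyAcrossTime}} under matched folds and seeds.
#'
#' @inheritParams mvClassifyAcrossTime
#' @export
mvClassifyTimextime <- function(cfg, X, clabel) {
  if (length(dim(X)) != 3L) stopf("expected a 3-D [samples x features x time] array")
  cfg$dimRoles <- c("sample", "feature", "generalization")
  mvClassify(cfg, if (is(X, "DecodingData")) dataValues(X) else X, clabel)
}

#' General-purpose regression over arbitrary data dimensions
#'
#' The regression counterpart of \code{\link{mvClassify}}: same search,
#' searchlight and generalization semantics with regression models and
#' metrics.
#'
#' @inheritParams mvClassify
#' @param y numeric responses.
#' @export
mvRegress <- function(cfg, X, y) mvDrive(cfg, X, y, "regression")
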