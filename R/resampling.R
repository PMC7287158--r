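#' Build a cross-validation fold plan
#'
#' Constructs seeded, reproducible fold assignments. Kinds: \code{"kfold"}
#' (k folds with sizes differing by at most 1; stratified assignment keeps
#' per-class fold counts within 1 of each other), \code{"leaveout"}
#' (leave-one-sample-out), \code{"holdout"} (a single test set holding a
#' fraction \code{p} of the samples), \code{"predefined"} (a user-supplied
#' integer assignment vector, honored verbatim; covers designs such as
#' leave-one-run-out), and \code{"none"} (train and test on all samples;
#' the resulting metric is an optimistically biased training-set metric).
#'
#' @param cv cross-validation kind.
#' @param n sample count.
#' @param k number of folds (kfold).
#' @param p test fraction in (0, 1) (holdout).
#' @param repeats number of repetitions with freshly randomized folds.
#' @param labels class labels, required for stratification.
#' @param stratify preserve class proportions per fold (classification
#'   default).
#' @param fold integer vector of predefined fold assignments.
#' @param seed integer seed.
#' @return object of class \code{foldPlan}: per-repeat lists of test-index
#'   sets plus the assignment vectors.
#' @export
makeFolds <- function(cv = c("kfold", "leaveout", "holdout", "predefined",
                             "none"),
                      n, k = 5L, p = 0.2, repeats = 1L, labels = NULL,
                      stratify = !is.null(labels), fold = NULL,
                      seed = NULL) {
  cv <- match.arg(cv)
  testSets <- vector("list", repeats)
  assignment <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rs <- childSeed(seed, "folds", r)
    if (cv == "kfold") {
      if (k > n) stopf("k (%d) exceeds sample count (%d)", k, n)
      av <- integer(n)
      if (stratify && !is.null(labels)) {
        off <- 0L
        for (cl in sort(unique(labels))) {
          idx <- which(labels == cl)
          idx <- withSeed(childSeed(rs, "class", cl), sample(idx))
          av[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
          off <- off + length(idx)
        }
      } else {
        av[withSeed(rs, sample.int(n))] <- rep_len(seq_len(k), n)
      }
      assignment[[r]] <- av
      testSets[[r]] <- lapply(seq_len(k), function(f) which(av == f))
    } else if (cv == "leaveout") {
      assignment[[r]] <- seq_len(n)
      testSets[[r]] <- as.list(seq_len(n))
    } else if (cv == "holdout") {
      if (p <= 0 || p >= 1) stopf("holdout fraction p must be in (0, 1)")
      nTest <- max(1L, round(p * n))
      te <- withSeed(rs, sort(sample.int(n, nTest)))
      av <- integer(n); av[te] <- 1L
      assignment[[r]] <- av
      testSets[[r]] <- list(te)
    } else if (cv == "predefined") {
      if (is.null(fold) || length(fold) != n)
        stopf("predefined cv requires a fold vector of length n")
      assignment[[r]] <- as.integer(fold)
      testSets[[r]] <- lapply(sort(unique(fold)), function(f)
        which(fold == f))
    } else { # none
      assignment[[r]] <- rep(1L, n)
      testSets[[r]] <- list(seq_len(n))
    }
  }
  structure(list(cv = cv, k = k, p = p, repeats = repeats,
                 stratified = isTRUE(stratify), seed = seed,
                 assignment = assignment, testSets = testSets, n = n),
            class = "foldPlan")
}

# train indices for a test set under a plan kind
trainIndices <- function(plan, r, f) {
  te <- plan$testSets[[r]][[f]]
  if (plan$cv == "none") seq_len(plan$n) else setdiff(seq_len(plan$n), te)
}

# does a hyperparameter entry denote a candidate list?
isCandidateList <- function(x) is.atomic(x) && length(x) > 1L

#' Cross-validated model evaluation
#'
#' The core engine: for every repetition and fold, the preprocessing
#' pipeline is fitted on the training fold and applied to the test fold,
#' hyperparameters with candidate lists are tuned by nested
#' cross-validation on the training fold only, the model is trained and
#' applied to the test fold, and the requested metrics are computed per
#' fold. Metrics are aggregated by a test-size-weighted average across
#' folds, then averaged across repetitions.
#'
#' @param cfg configuration list:
#'   \describe{
#'     \item{model}{registered model name (default "lda").}
#'     \item{hyperparameter}{list; entries that are atomic vectors of
#'       length > 1 are treated as tuning candidate lists.}
#'     \item{metric}{character vector of metric names (default "accuracy"
#'       for classification, "mse" for regression).}
#'     \item{preprocess}{list of \code{\link{preprocessStep}}s or names.}
#'     \item{cv, k, repeat, p, fold, stratify}{fold-plan controls, see
#'       \code{\link{makeFolds}}; \code{cv} defaults to "kfold", k = 5,
#'       repeat = 1, stratify = TRUE for classification.}
#'     \item{seed}{integer seed for fold assignment and seeded steps.}
#'     \item{tuneK, tuneMetric}{inner-CV controls for tuning.}
#'   }
#' @param X [samples x features] matrix (or DecodingData with one feature
#'   dimension).
#' @param targets class labels or responses.
#' @return a \linkS4class{DecodingResult}.
#' @examples
#' g <- genGaussianClasses(30, p = 5, K = 2, separation = 3, seed = 3)
#' r <- crossValidate(list(model = "lda", metric = "accuracy",
#'                         cv = "kfold", k = 5, seed = 1), g$X, g$clabel)
#' metricValues(r, "accuracy")
#' @export
crossValidate <- function(cfg, X, targets) {
  cfg <- resolveCfg(cfg)
  task <- modelTask(cfg$model)
  v <- validateInputs(X, targets,
                      type = if (task == "regression") "regression"
                             else "classification")
  X <- asMatrix(v$X); targets <- v$targets
  if (is.null(cfg$metric))
    cfg$metric <- if (task == "regression") "mse" else "accuracy"
  plan <- cfg$foldPlan
  if (is.null(plan))
    plan <- makeFolds(cfg$cv, n = nrow(X), k = cfg$k, p = cfg$p,
                      repeats = cfg$`repeat`,
                      labels = if (task == "classification") targets,
                      stratify = if (is.null(cfg$stratify))
                        task == "classification" else isTRUE(cfg$stratify),
                      fold = cfg$fold, seed = cfg$seed)
  out <- cvRun(cfg, X, targets, plan, task, K = v$K)
  new("DecodingResult", metrics = out$metrics, perFold = out$perFold,
      dims = integer(0), coords = list(), cfg = cfg)
}

# fill cfg defaults once
resolveCfg <- function(cfg) {
  defaults <- list(model = "lda", hyperparameter = list(), metric = NULL,
                   preprocess = list(), cv = "kfold", k = 5L,
                   `repeat` = 1L, p = 0.2, fold = NULL, stratify = NULL,
                   seed = NULL, tuneK = 5L, tuneMetric = NULL,
                   foldPlan = NULL)
  cfg <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  cfg
}

# inner loop shared by crossValidate and the high-level drivers; X is a
# plain [n x p] matrix here.
cvRun <- function(cfg, X, targets, plan, task, K = NULL) {
  metrics <- cfg$metric
  perFold <- list()
  repAgg <- vector("list", plan$repeats)
  for (r in seq_len(plan$repeats)) {
    nf <- length(plan$testSets[[r]])
    foldVals <- vector("list", nf)
    sizes <- numeric(nf)
    for (f in seq_len(nf)) {
      sp <- cvFitFold(cfg, X, targets, plan, r, f, task, K)
      sizes[f] <- length(sp$truth)
      foldVals[[f]] <- lapply(metrics, function(m)
        computeMetric(m, sp$prediction, sp$truth, task, K))
      perFold[[length(perFold) + 1L]] <-
        list(repeat_ = r, fold = f, size = sizes[f],
             values = stats::setNames(foldVals[[f]], metrics))
    }
    repAgg[[r]] <- lapply(seq_along(metrics), function(j) {
      if (metrics[j] == "none") return(NULL)
      weightedFoldAverage(lapply(foldVals, `[[`, j), sizes)
    })
  }
  agg <- lapply(seq_along(metrics), function(j) {
    if (metrics[j] == "none") return(NULL)
    Reduce(`+`, lapply(repAgg, `[[`, j)) / plan$repeats
  })
  list(metrics = stats::setNames(agg, metrics), perFold = perFold)
}

computeMetric <- function(name, prediction, truth, task, K) {
  if (task == "regression") regressionMetric(name, prediction, truth)
  else classificationMetric(name, prediction, truth, K = K)
}

# preprocess + tune + train + predict for one fold; returns test-fold
# prediction and truth
cvFitFold <- function(cfg, X, targets, plan, r, f, task, K) {
  te <- plan$testSets[[r]][[f]]
  tr <- trainIndices(plan, r, f)
  if (task == "classification" &&
      length(unique(targets[tr])) < K)
    warnf("training fold lost a class entirely; results may be degenerate")
  pp <- runPipeline(cfg$preprocess, X[tr, , drop = FALSE], targets[tr],
                    X[te, , drop = FALSE], targets[te],
                    seed = childSeed(cfg$seed, "pp", r, f))
  param <- cfg$hyperparameter
  if (any(vapply(param, isCandidateList, logical(1)))) {
    param <- tuneHyperparameters(param, cfg, pp$Xtrain, pp$targetsTrain)
  }
  model <- trainModel(cfg$model, param, pp$Xtrain, pp$targetsTrain)
  prediction <- predictModel(cfg$model, model, pp$Xtest)
  list(prediction = prediction, truth = pp$targetsTest, model = model,
       tunedParam = param)
}

#' Nested hyperparameter grid search
#'
#' Scores the Cartesian product of all candidate lists in \code{grid} by
#' inner cross-validation (default 5-fold) on the supplied training data
#' only, and returns the best combination (ties broken by grid order).
#' The caller retrains the winner on the full training fold.
#'
#' @param grid hyperparameter list; atomic entries of length > 1 are
#'   candidate lists.
#' @param cfg configuration (model, tuneK, tuneMetric, seed).
#' @param X,targets the training fold.
#' @return hyperparameter list with every candidate list replaced by the
#'   selected value.
#' @export
tuneHyperparameters <- function(grid, cfg, X, targets) {
  cfg <- resolveCfg(cfg)
  tunable <- names(grid)[vapply(grid, isCandidateList, logical(1))]
  if (length(tunable) == 0L) return(grid)
  for (nm in tunable)
    if (length(grid[[nm]]) < 1L) stopf("empty candidate list for '%s'", nm)
  combos <- expand.grid(grid[tunable], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 1L) {
    for (nm in tunable) grid[[nm]] <- combos[[nm]][1L]
    return(grid)
  }
  task <- modelTask(cfg$model)
  metric <- cfg$tuneMetric
  if (is.null(metric))
    metric <- if (task == "regression") "mse" else "accuracy"
  higher <- metricDirection(metric)
  if (is.na(higher)) stopf("metric '%s' has no tuning direction", metric)
  v <- validateInputs(X, targets,
                      type = if (task == "regression") "regression"
                             else "classification")
  Xm <- asMatrix(v$X); tg <- v$targets
  plan <- makeFolds("kfold", n = nrow(Xm), k = min(cfg$tuneK, nrow(Xm)),
                    labels = if (task == "classification") tg,
                    stratify = task == "classification",
                    seed = childSeed(cfg$seed, "tune"))
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    param <- grid
    for (nm in tunable) param[[nm]] <- combos[[nm]][i]
    icfg <- utils::modifyList(cfg, list(hyperparameter = param,
                                        metric = metric, foldPlan = plan,
                                        preprocess = list()))
    res <- cvRun(icfg, Xm, tg, plan, task, K = v$K)
    scores[i] <- res$metrics[[metric]]
  }
  best <- if (higher) which.max(scores) else which.min(scores)
  for (nm in tunable) grid[[nm]] <- combos[[nm]][best]
  grid
}
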