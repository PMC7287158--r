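#' Nested preprocessing steps
#'
#' Preprocessing operations are fitted on the training fold only and then
#' applied to the test fold with the parameters estimated from training
#' (fit-on-train / apply-to-test), so no test-fold information leaks into
#' the fitted state. Available steps:
#' \describe{
#'   \item{zscore}{per-feature standardization with train means/sds (zero
#'     sds floored to 1 with a warning).}
#'   \item{demean}{per-feature centering with train means.}
#'   \item{pca}{projection on the leading principal components of the
#'     train covariance (\code{n_components}, clipped to the rank).}
#'   \item{undersample}{train-only: classes reduced to the minority count
#'     by seeded random deletion; test fold untouched.}
#'   \item{oversample}{train-only: minority classes duplicated up to the
#'     majority count; test fold untouched.}
#'   \item{average_samples}{within-class random groups of
#'     \code{group_size} samples are averaged to raise the
#'     signal-to-noise ratio; applied to train and test folds separately
#'     (fresh groups on each side); remainder samples form a smaller
#'     final group.}
#'   \item{average_kernel}{like average_samples but operating on a
#'     precomputed kernel matrix: group-block means of rows and columns.}
#' }
#'
#' @param name step name.
#' @param params named list of step parameters (\code{n_components},
#'   \code{group_size}, ...).
#' @return an unfitted \code{preprocessStep}.
#' @export
preprocessStep <- function(name, params = list()) {
  valid <- c("zscore", "demean", "pca", "undersample", "oversample",
             "average_samples", "average_kernel")
  if (!name %in% valid)
    stopf("unknown preprocessing step '%s'; available: %s", name,
          paste(valid, collapse = ", "))
  structure(list(name = name, params = params, fitted = NULL),
            class = "preprocessStep")
}

# group indices for sample averaging: seeded random groups within class
averagingGroups <- function(clabel, groupSize, seed) {
  groups <- list()
  for (k in sort(unique(clabel))) {
    idx <- which(clabel == k)
    if (groupSize > length(idx))
      stopf("group_size (%d) exceeds class size (%d)", groupSize,
            length(idx))
    idx <- withSeed(seed, sample(idx))
    splits <- split(idx, ceiling(seq_along(idx) / groupSize))
    groups <- c(groups, splits)
  }
  groups
}

averageByGroups <- function(X, groups) {
  out <- vapply(groups, function(g) colMeans(X[g, , drop = FALSE]),
                numeric(ncol(X)))
  if (is.null(dim(out))) matrix(out, ncol = 1L) else t(out)
}

#' @rdname preprocessStep
#' @param step a \code{preprocessStep}.
#' @param X training fold ([samples x features], or kernel matrix for
#'   average_kernel).
#' @param targets training labels/responses.
#' @param seed integer seed for the sampling/averaging steps.
#' @return \code{fitStep}: list with the fitted \code{step} and the
#'   transformed \code{X} and \code{targets}.
#' @export
fitStep <- function(step, X, targets, seed = NULL) {
  X <- asMatrix(X)
  p <- step$params
  switch(step$name,
    zscore = {
      mu <- colMeans(X); sdv <- apply(X, 2L, stats::sd)
      if (any(sdv == 0)) {
        warnf("zero-variance feature(s) in zscore; sd floored to 1")
        sdv[sdv == 0] <- 1
      }
      step$fitted <- list(mean = mu, sd = sdv)
      list(step = step, X = sweep(sweep(X, 2L, mu), 2L, sdv, "/"),
           targets = targets)
    },
    demean = {
      mu <- colMeans(X)
      step$fitted <- list(mean = mu)
      list(step = step, X = sweep(X, 2L, mu), targets = targets)
    },
    pca = {
      nc <- if (is.null(p$n_components)) min(dim(X)) else p$n_components
      mu <- colMeans(X)
      Xc <- sweep(X, 2L, mu)
      sv <- svd(Xc, nu = 0)
      rank <- sum(sv$d > sv$d[1L] * 1e-12)
      if (nc > rank) {
        warnf("pca n_components clipped from %d to rank %d", nc, rank)
        nc <- rank
      }
      comp <- sv$v[, seq_len(nc), drop = FALSE]
      step$fitted <- list(mean = mu, components = comp)
      list(step = step, X = Xc %*% comp, targets = targets)
    },
    undersample = {
      cnt <- table(targets)
      m <- min(cnt)
      keep <- unlist(lapply(names(cnt), function(k) {
        idx <- which(targets == as.integer(k))
        if (length(idx) > m) withSeed(childSeed(seed, "under", k),
                                      sample(idx, m)) else idx
      }))
      keep <- sort(keep)
      step$fitted <- list(done = TRUE)
      list(step = step, X = X[keep, , drop = FALSE], targets = targets[keep])
    },
    oversample = {
      cnt <- table(targets)
      m <- max(cnt)
      idxAll <- seq_along(targets)
      extra <- unlist(lapply(names(cnt), function(k) {
        idx <- which(targets == as.integer(k))
        need <- m - length(idx)
        if (need > 0) withSeed(childSeed(seed, "over", k),
                               sample(idx, need, replace = TRUE))
        else integer(0)
      }))
      keep <- c(idxAll, extra)
      step$fitted <- list(done = TRUE)
      list(step = step, X = X[keep, , drop = FALSE], targets = targets[keep])
    },
    average_samples = {
      gs <- if (is.null(p$group_size)) 2L else as.integer(p$group_size)
      groups <- averagingGroups(targets, gs, childSeed(seed, "avg-train"))
      step$fitted <- list(group_size = gs)
      list(step = step, X = averageByGroups(X, groups),
           targets = unname(vapply(groups, function(g) targets[g[1L]],
                                   numeric(1))))
    },
    average_kernel = {
      gs <- if (is.null(p$group_size)) 2L else as.integer(p$group_size)
      groups <- averagingGroups(targets, gs, childSeed(seed, "avgk-train"))
      G <- length(groups)
      Kavg <- matrix(0, G, G)
      for (a in seq_len(G)) for (b in seq_len(G))
        Kavg[a, b] <- mean(X[groups[[a]], groups[[b]]])
      step$fitted <- list(group_size = gs, trainGroups = groups)
      list(step = step, X = Kavg,
           targets = unname(vapply(groups, function(g) targets[g[1L]],
                                   numeric(1))))
    })
}

#' @rdname preprocessStep
#' @return \code{applyStep}: list with transformed test \code{X} and
#'   \code{targets}. Sampling steps are the identity on the test fold.
#' @export
applyStep <- function(step, X, targets, seed = NULL) {
  if (is.null(step$fitted)) stopf("step '%s' has not been fitted", step$name)
  X <- asMatrix(X)
  f <- step$fitted
  switch(step$name,
    zscore = list(X = sweep(sweep(X, 2L, f$mean), 2L, f$sd, "/"),
                  targets = targets),
    demean = list(X = sweep(X, 2L, f$mean), targets = targets),
    pca = list(X = sweep(X, 2L, f$mean) %*% f$components, targets = targets),
    undersample = list(X = X, targets = targets),
    oversample = list(X = X, targets = targets),
    average_samples = {
      groups <- averagingGroups(targets, min(f$group_size,
                                             min(table(targets))),
                                childSeed(seed, "avg-test"))
      list(X = averageByGroups(X, groups),
           targets = unname(vapply(groups, function(g) targets[g[1L]],
                                   numeric(1))))
    },
    average_kernel = {
      # X is the test x train kernel matrix; average test rows by fresh
      # test-side groups, train columns by the fitted train groups
      groups <- averagingGroups(targets, min(f$group_size,
                                             min(table(targets))),
                                childSeed(seed, "avgk-test"))
      G <- length(groups); H <- length(f$trainGroups)
      Kavg <- matrix(0, G, H)
      for (a in seq_len(G)) for (b in seq_len(H))
        Kavg[a, b] <- mean(X[groups[[a]], f$trainGroups[[b]]])
      list(X = Kavg,
           targets = unname(vapply(groups, function(g) targets[g[1L]],
                                   numeric(1))))
    })
}

#' Run a preprocessing pipeline on a train/test fold pair
#'
#' Steps are applied in order; each is fitted on the (already transformed)
#' training fold and applied to the test fold.
#'
#' @param steps list of \code{\link{preprocessStep}}s (or step names).
#' @param Xtrain,targetsTrain training fold.
#' @param Xtest,targetsTest test fold.
#' @param seed integer seed for the sampling steps.
#' @return list with \code{Xtrain}, \code{targetsTrain}, \code{Xtest},
#'   \code{targetsTest}, and the fitted \code{steps}.
#' @export
runPipeline <- function(steps, Xtrain, targetsTrain, Xtest = NULL,
                        targetsTest = NULL, seed = NULL) {
  fitted <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (is.character(st)) st <- preprocessStep(st)
    ft <- fitStep(st, Xtrain, targetsTrain, seed = childSeed(seed, "step", i))
    Xtrain <- ft$X; targetsTrain <- ft$targets
    fitted[[i]] <- ft$step
    if (!is.null(Xtest)) {
      ap <- applyStep(ft$step, Xtest, targetsTest,
                      seed = childSeed(seed, "step", i))
      Xtest <- ap$X; targetsTest <- ap$targets
    }
  }
  list(Xtrain = Xtrain, targetsTrain = targetsTrain, Xtest = Xtest,
       targetsTest = targetsTest, steps = fitted)
}
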