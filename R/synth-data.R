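#' Synthetic data generators
#'
#' Seeded generators producing data with the statistical structure the
#' decoding analyses assume: Gaussian class clouds with controllable
#' separation and covariance, epoched ERP-like trials (samples x channels x
#' time with a class-dependent spatiotemporal effect), linear-model
#' regression data, and multi-subject metric maps for group-level tests.
#' All generators are pure functions of their arguments: the same spec and
#' seed yield bit-identical data.
#'
#' @name synthData
NULL

# random SPD matrix: A A'/p + small ridge, scaled to unit average variance
randomSPD <- function(p) {
  A <- matrix(rnorm(p * p), p, p)
  S <- tcrossprod(A) / p + diag(0.1, p)
  S / mean(diag(S))
}

#' Gaussian class clouds
#'
#' Draws \code{K} multivariate-Gaussian classes sharing one covariance
#' matrix. Class means are placed at \code{separation/2} times unit vectors
#' along distinct axes (class k along axis k, wrapping if K > p), so
#' \code{separation} is the Euclidean distance between adjacent class means
#' in units of the (unit) noise scale.
#'
#' @param nPerClass integer or vector of length K: samples per class.
#' @param p number of features.
#' @param K number of classes.
#' @param separation distance scale between class means; 0 gives
#'   label-independent data (chance-level decoding).
#' @param covariance \code{"isotropic"}, \code{"diagonal"}, or
#'   \code{"randomSPD"}.
#' @param seed integer seed.
#' @return list with \code{X} (n x p matrix), \code{clabel} (1..K), and
#'   \code{means} (K x p matrix of true class means).
#' @examples
#' g <- genGaussianClasses(20, p = 4, K = 2, separation = 3, seed = 1)
#' table(g$clabel)
#' @export
genGaussianClasses <- function(nPerClass, p = 10, K = 2, separation = 0,
                               covariance = c("isotropic", "diagonal",
                                              "randomSPD"),
                               seed = NULL) {
  covariance <- match.arg(covariance)
  if (length(nPerClass) == 1L) nPerClass <- rep(nPerClass, K)
  stopifnot(length(nPerClass) == K, all(nPerClass >= 1))
  withSeed(seed, {
    means <- matrix(0, K, p)
    for (k in seq_len(K))
      means[k, ((k - 1L) %% p) + 1L] <- separation / 2
    Sig <- switch(covariance,
      isotropic = diag(p),
      diagonal  = diag(runif(p, 0.5, 1.5)),
      randomSPD = randomSPD(p))
    R <- chol(Sig)
    n <- sum(nPerClass)
    clabel <- rep(seq_len(K), nPerClass)
    X <- matrix(rnorm(n * p), n, p) %*% R + means[clabel, , drop = FALSE]
    list(X = X, clabel = clabel, means = means)
  })
}

#' ERP-like epoched trials
#'
#' Generates trials of shape [samples x channels x time] as white Gaussian
#' noise (optionally smoothed over time with a moving average to mimic
#' temporal autocorrelation), plus a class-dependent spatial pattern added
#' inside one or more effect windows. Class 1 receives \code{+amplitude *
#' pattern}, class 2 \code{-amplitude * pattern} (multi-class: class k gets
#' a pattern along channel k). Windows sharing a single pattern produce
#' off-diagonal blocks in time-by-time generalization.
#'
#' @param nPerClass samples per class (scalar or length-K vector).
#' @param nChannels number of channels (features per time point).
#' @param nTime number of time points.
#' @param K number of classes.
#' @param amplitude effect amplitude in noise-sd units; 0 gives
#'   chance-level data everywhere.
#' @param windows list of integer vectors, each a set of time indices
#'   forming one effect window; default: the middle fifth of the epoch.
#' @param pattern optional nChannels vector (shared spatial pattern);
#'   default is a smooth random pattern drawn once per call.
#' @param noiseSd noise standard deviation.
#' @param smooth integer half-width of a temporal moving-average filter
#'   applied to the noise (0 = white noise).
#' @param seed integer seed.
#' @return list with \code{X} (n x nChannels x nTime array), \code{clabel},
#'   \code{pattern}, \code{windows}.
#' @export
genErpLike <- function(nPerClass, nChannels = 16, nTime = 40, K = 2,
                       amplitude = 1,
                       windows = NULL,
                       pattern = NULL, noiseSd = 1, smooth = 0,
                       seed = NULL) {
  if (is.null(windows))
    windows <- list(seq(max(1L, round(nTime * 0.4)),
                        max(1L, round(nTime * 0.6))))
  if (length(nPerClass) == 1L) nPerClass <- rep(nPerClass, K)
  stopifnot(length(nPerClass) == K)
  for (w in windows)
    if (any(w < 1L | w > nTime)) stopf("effect window outside [1, %d]", nTime)
  if (noiseSd < 0) stopf("noiseSd must be >= 0")
  withSeed(seed, {
    n <- sum(nPerClass)
    clabel <- rep(seq_len(K), nPerClass)
    X <- array(rnorm(n * nChannels * nTime, sd = noiseSd),
               dim = c(n, nChannels, nTime))
    if (smooth > 0L) {
      kern <- rep(1, 2L * smooth + 1L)
      kern <- kern / sqrt(sum(kern^2))  # preserve noise variance
      for (i in seq_len(n)) for (ch in seq_len(nChannels))
        X[i, ch, ] <- stats::filter(X[i, ch, ], kern, sides = 2L,
                                    circular = TRUE)
    }
    if (is.null(pattern)) {
      pattern <- rnorm(nChannels)
      pattern <- pattern / sqrt(sum(pattern^2))
    }
    # class-dependent sign (K=2) or per-class channel loading (K>2)
    for (i in seq_len(n)) {
      if (K == 2L) {
        eff <- amplitude * pattern * (if (clabel[i] == 1L) 1 else -1)
      } else {
        eff <- numeric(nChannels)
        eff[((clabel[i] - 1L) %% nChannels) + 1L] <- amplitude
      }
      for (w in windows) X[i, , w] <- X[i, , w] + eff
    }
    list(X = X, clabel = clabel, pattern = pattern, windows = windows)
  })
}

#' Linear-model regression data
#'
#' \code{y = X w + noise} with standard-normal features.
#'
#' @param n samples; @param p features.
#' @param wTrue true coefficient vector (length p); default standard normal.
#' @param noiseSd residual standard deviation.
#' @param seed integer seed.
#' @return list with \code{X}, \code{y}, \code{wTrue}.
#' @export
genRegression <- function(n, p = 10, wTrue = NULL, noiseSd = 1, seed = NULL) {
  if (noiseSd < 0) stopf("noiseSd must be >= 0")
  withSeed(seed, {
    if (is.null(wTrue)) wTrue <- rnorm(p)
    stopifnot(length(wTrue) == p)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% wTrue) + rnorm(n, sd = noiseSd)
    list(X = X, y = y, wTrue = wTrue)
  })
}

#' Multi-subject metric maps for group-level tests
#'
#' Each subject's map is \code{nullValue} plus between-subject noise, with
#' an optional additive effect confined to a region of the map.
#'
#' @param nSubjects number of subjects.
#' @param mapLength number of map elements (e.g. time points).
#' @param nullValue chance-level metric value (e.g. 0.5 for AUC).
#' @param effect additive effect size inside \code{effectRegion}.
#' @param effectRegion integer indices receiving the effect.
#' @param sd between-subject noise standard deviation.
#' @param seed integer seed.
#' @return nSubjects x mapLength matrix.
#' @export
genGroupLevel <- function(nSubjects, mapLength = 50, nullValue = 0.5,
                          effect = 0, effectRegion = integer(0), sd = 0.05,
                          seed = NULL) {
  if (sd < 0) stopf("sd must be >= 0")
  withSeed(seed, {
    maps <- matrix(rnorm(nSubjects * mapLength, mean = nullValue, sd = sd),
                   nSubjects, mapLength)
    if (length(effectRegion))
      maps[, effectRegion] <- maps[, effectRegion] + effect
    maps
  })
}
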