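#' @import methods
NULL

#' DecodingData: an N-dimensional data array with declared dimension roles
#'
#' The central data container. Holds a numeric array with at least two
#' dimensions together with a role tag per dimension: exactly one
#' \code{"sample"} dimension, at least one \code{"feature"} dimension, and
#' optionally \code{"search"} dimensions (swept by the high-level drivers,
#' e.g. time points) and at most one \code{"generalization"} dimension
#' (train-at-one-index / test-at-all-indices designs such as time-by-time
#' decoding).
#'
#' @slot values numeric array, N >= 2 dimensions, all finite.
#' @slot dimRoles character vector, one of \code{"sample"}, \code{"feature"},
#'   \code{"search"}, \code{"generalization"} per dimension.
#' @slot dimCoords list of per-dimension coordinate labels (possibly NULL
#'   entries), e.g. time points in seconds or channel names.
#' @export
setClass("DecodingData",
  representation(values = "array", dimRoles = "character", dimCoords = "list"))

setValidity("DecodingData", function(object) {
  v <- object@values
  roles <- object@dimRoles
  msgs <- character(0)
  if (length(dim(v)) < 2L)
    msgs <- c(msgs, "values must have at least 2 dimensions")
  if (length(roles) != length(dim(v)))
    msgs <- c(msgs, "dimRoles length must equal the number of array dimensions")
  ok <- roles %in% c("sample", "feature", "search", "generalization")
  if (!all(ok))
    msgs <- c(msgs, paste0("unknown dimension role(s): ",
                           paste(unique(roles[!ok]), collapse = ", ")))
  if (sum(roles == "sample") != 1L)
    msgs <- c(msgs, "exactly one dimension must be tagged 'sample'")
  if (!any(roles == "feature"))
    msgs <- c(msgs, "at least one dimension must be tagged 'feature'")
  if (sum(roles == "generalization") > 1L)
    msgs <- c(msgs, "at most one generalization dimension is supported")
  if (!all(is.finite(v)))
    msgs <- c(msgs, "all values must be finite")
  if (sum(roles == "sample") == 1L && dim(v)[roles == "sample"] < 2L)
    msgs <- c(msgs, "need at least 2 samples")
  if (length(object@dimCoords) != 0L &&
      length(object@dimCoords) != length(dim(v)))
    msgs <- c(msgs, "dimCoords must be empty or one entry per dimension")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DecodingData object
#'
#' @param values numeric matrix or array (samples first by default).
#' @param dimRoles optional character vector of roles; defaults to
#'   \code{"sample"} for axis 1, \code{"feature"} for axis 2, \code{"search"}
#'   for any further axes.
#' @param dimCoords optional list of per-dimension coordinates.
#' @return A \linkS4class{DecodingData} object.
#' @examples
#' d <- DecodingData(matrix(rnorm(20), 10, 2))
#' nSamples(d)
#' @export
DecodingData <- function(values, dimRoles = NULL, dimCoords = list()) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (is.null(dimRoles)) {
    dimRoles <- c("sample", "feature", rep("search", max(0L, nd - 2L)))[seq_len(nd)]
  }
  if (length(dimCoords) == 0L) dimCoords <- vector("list", nd)
  new("DecodingData", values = values, dimRoles = dimRoles,
      dimCoords = dimCoords)
}

#' @rdname DecodingData
#' @param x a DecodingData object.
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "DecodingData"))
  dim(x@values)[x@dimRoles == "sample"]
}

#' @rdname DecodingData
#' @export
nFeatures <- function(x) {
  stopifnot(is(x, "DecodingData"))
  prod(dim(x@values)[x@dimRoles == "feature"])
}

#' @rdname DecodingData
#' @export
dimRoles <- function(x) x@dimRoles

#' @rdname DecodingData
#' @export
dimCoords <- function(x) x@dimCoords

#' @rdname DecodingData
#' @export
dataValues <- function(x) x@values

setMethod("show", "DecodingData", function(object) {
  d <- dim(object@values)
  cat("DecodingData:", paste(d, collapse = " x "), "\n")
  cat("  roles: ", paste(object@dimRoles, collapse = ", "), "\n", sep = "")
})

#' DecodingResult: metric values laid out over search dimensions
#'
#' Result container returned by the cross-validation engine and the
#' high-level drivers. For each requested metric it stores an array shaped
#' like the search grid (a generalization dimension appears twice, as
#' train x test), plus per-fold raw values and an echo of the configuration.
#'
#' @slot metrics named list, one array (possibly 0-dimensional, i.e. a
#'   scalar) per metric.
#' @slot perFold named list of per-fold / per-repeat metric records.
#' @slot dims integer vector: the search-grid shape (empty for plain CV).
#' @slot coords list of coordinates for the search grid axes.
#' @slot cfg list: configuration echo.
#' @export
setClass("DecodingResult",
  representation(metrics = "list", perFold = "list", dims = "integer",
                 coords = "list", cfg = "list"))

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult\n")
  for (nm in names(object@metrics)) {
    m <- object@metrics[[nm]]
    if (is.null(dim(m)) && length(m) == 1L) {
      cat(sprintf("  %s: %.4g\n", nm, m))
    } else {
      cat(sprintf("  %s: [%s]\n", nm,
                  paste(if (is.null(dim(m))) length(m) else dim(m),
                        collapse = " x ")))
    }
  }
})

#' @rdname DecodingResult-class
#' @param x a DecodingResult.
#' @param metric metric name; defaults to the first stored metric.
#' @export
metricValues <- function(x, metric = NULL) {
  stopifnot(is(x, "DecodingResult"))
  if (is.null(metric)) metric <- names(x@metrics)[1L]
  x@metrics[[metric]]
}

#' @rdname DecodingResult-class
#' @export
resultCfg <- function(x) x@cfg

#' StatTestResult: outcome of a significance test on a metric map
#'
#' @slot statistic numeric array: observed statistic map.
#' @slot p numeric array: p-value per map element (or scalar).
#' @slot mask logical array: significance at the configured alpha (cluster
#'   tests: elements of significant clusters).
#' @slot nullDistribution numeric vector or matrix: samples of the null
#'   distribution (for level-1 tests an [nPermutations x elements] matrix
#'   of permutation maps; for cluster tests the permutation maxima).
#' @slot clusters list of cluster records (members, statistic, p).
#' @slot nPermutations integer.
#' @slot alpha numeric.
#' @slot method character.
#' @slot seed integer seed used for permutation draws.
#' @export
setClass("StatTestResult",
  representation(statistic = "ANY", p = "ANY", mask = "ANY",
                 nullDistribution = "ANY", clusters = "list",
                 nPermutations = "integer", alpha = "numeric",
                 method = "character", seed = "integer"))

setMethod("show", "StatTestResult", function(object) {
  cat("StatTestResult:", object@method, "\n")
  cat("  alpha:", object@alpha, "\n")
  if (length(object@p) == 1L) {
    cat(sprintf("  p = %.4g\n", object@p))
  } else {
    cat(sprintf("  %d map elements, %d significant\n",
                length(object@p), sum(object@mask)))
  }
  if (length(object@clusters))
    cat("  clusters:", length(object@clusters), "\n")
})

#' @rdname StatTestResult-class
#' @param x a StatTestResult.
#' @export
pValues <- function(x) x@p

#' @rdname StatTestResult-class
#' @export
significanceMask <- function(x) x@mask

#' @rdname StatTestResult-class
#' @export
nullDistribution <- function(x) x@nullDistribution

#' @rdname StatTestResult-class
#' @export
clusterRecords <- function(x) x@clusters
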