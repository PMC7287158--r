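#' Validate and canonicalize data and targets
#'
#' Checks a data array against its class labels (classification) or
#' real-valued responses (regression), and canonicalizes the pair: labels
#' supplied as arbitrary distinct integers (or factors) are re-coded to
#' contiguous \code{1..K}, with the mapping recorded so predictions can be
#' translated back.
#'
#' @param X a \linkS4class{DecodingData}, matrix, or array (samples on the
#'   first axis for raw arrays).
#' @param targets integer class labels or numeric responses, length equal to
#'   the number of samples.
#' @param type \code{"classification"} or \code{"regression"}.
#' @return A list with elements \code{X} (DecodingData), \code{targets}
#'   (canonical labels 1..K or numeric responses), \code{K} (class count,
#'   classification only), and \code{mapping} (named integer vector,
#'   original value -> canonical label).
#' @details Validation is idempotent: applying it to its own output returns
#'   an identical pair. Errors: length mismatch, non-finite values, or (for
#'   classification) fewer than two distinct classes.
#' @examples
#' v <- validateInputs(matrix(rnorm(8), 4, 2), c(5, 9, 5, 9))
#' v$targets   # 1 2 1 2
#' v$mapping   # 5 -> 1, 9 -> 2
#' @export
validateInputs <- function(X, targets,
                           type = c("classification", "regression")) {
  type <- match.arg(type)
  if (!is(X, "DecodingData")) X <- DecodingData(as.array(X))
  n <- nSamples(X)
  if (length(targets) != n)
    stopf("targets length (%d) does not match sample count (%d)",
          length(targets), n)
  if (type == "regression") {
    targets <- as.numeric(targets)
    if (!all(is.finite(targets))) stopf("responses must be finite")
    return(list(X = X, targets = targets, K = NULL, mapping = NULL))
  }
  if (is.factor(targets)) targets <- as.integer(targets)
  if (!all(is.finite(targets)) || any(targets != round(targets)))
    stopf("class labels must be finite integers")
  targets <- as.integer(targets)
  lev <- sort(unique(targets))
  K <- length(lev)
  if (K < 2L) stopf("need at least two classes; found %d", K)
  mapping <- seq_len(K)
  names(mapping) <- as.character(lev)
  clabel <- match(targets, lev)
  list(X = X, targets = clabel, K = K, mapping = mapping)
}

# class counts for canonical 1..K labels
classCounts <- function(clabel, K = max(clabel)) {
  tabulate(clabel, nbins = K)
}

# class priors: empirical frequencies or equal, per the prior flag
classPriors <- function(clabel, K, equal = FALSE) {
  if (equal) rep(1 / K, K) else classCounts(clabel, K) / length(clabel)
}
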