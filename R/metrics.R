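#' Classification performance metrics
#'
#' Computes a performance metric from a prediction (list with
#' \code{clabel} and optionally \code{dval}/\code{prob}) against true
#' class labels. Available metrics:
#' \describe{
#'   \item{accuracy}{fraction of correctly predicted class labels.}
#'   \item{auc}{two classes only; rank-based (Mann-Whitney) probability
#'     that a class-1 output exceeds a class-2 output, ties counted 1/2.
#'     Requires continuous output (dval or prob). More robust to
#'     imbalanced classes than accuracy; 0.5 is chance, 1 perfect.}
#'   \item{confusion}{K x K matrix; entry (i, j) is the proportion of
#'     class-i samples predicted as class j (rows = true class). Raw
#'     counts in attribute \code{"counts"}.}
#'   \item{dval}{two classes only; mean decision value per class.}
#'   \item{f1}{harmonic mean of precision and recall, 2 PR R/(PR + R);
#'     multi-class: unweighted macro average, per-class values in
#'     attribute \code{"perClass"}.}
#'   \item{kappa}{Cohen's kappa, (p_o - p_e)/(1 - p_e).}
#'   \item{precision}{TP/(TP + FP); multi-class per class from the
#'     confusion matrix, macro-averaged.}
#'   \item{recall}{TP/(TP + FN); multi-class as for precision.}
#'   \item{tval}{two classes only; pooled-variance two-sample t statistic
#'     (class 1 minus class 2) on decision values.}
#'   \item{none}{the raw prediction passed through.}
#' }
#'
#' @param name metric name.
#' @param prediction list with \code{clabel} (1..K) and optionally
#'   \code{dval}, \code{prob}.
#' @param truth true class labels (1..K).
#' @param K class count (default \code{max(truth)}).
#' @return metric value: scalar, per-class vector, matrix (confusion), or
#'   the raw prediction for \code{"none"}.
#' @examples
#' classificationMetric("auc",
#'   list(clabel = c(1, 1, 1, 2), dval = c(0.9, 0.4, 0.8, 0.3)),
#'   truth = c(1, 1, 2, 2))  # 0.75
#' @export
classificationMetric <- function(name, prediction, truth,
                                 K = max(truth)) {
  truth <- as.integer(truth)
  clabel <- prediction$clabel
  if (name == "none") return(prediction)
  if (name %in% c("auc", "dval", "tval")) {
    if (K > 2L) stopf("metric '%s' is defined for two classes only", name)
    out <- if (!is.null(prediction$dval)) prediction$dval
           else if (!is.null(prediction$prob)) {
             pr <- prediction$prob
             if (is.matrix(pr)) pr[, 1L] else pr
           } else stopf("metric '%s' needs decision values or probabilities",
                        name)
  }
  switch(name,
    accuracy = mean(clabel == truth),
    auc = {
      i1 <- truth == 1L; i2 <- truth == 2L
      n1 <- sum(i1); n2 <- sum(i2)
      if (n1 == 0L || n2 == 0L) stopf("auc needs both classes in the test set")
      r <- rank(out, ties.method = "average")
      (sum(r[i1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    },
    confusion = {
      counts <- matrix(0L, K, K)
      for (i in seq_along(truth))
        counts[truth[i], clabel[i]] <- counts[truth[i], clabel[i]] + 1L
      rs <- rowSums(counts)
      norm <- counts / ifelse(rs > 0, rs, 1)
      structure(norm, counts = counts)
    },
    dval = c(class1 = mean(out[truth == 1L]), class2 = mean(out[truth == 2L])),
    f1 = {
      pr <- perClassPrecisionRecall(clabel, truth, K)
      f1 <- 2 * pr$precision * pr$recall / (pr$precision + pr$recall)
      f1[!is.finite(f1)] <- 0
      if (K == 2L) f1[1L] else structure(mean(f1), perClass = f1)
    },
    kappa = {
      counts <- attr(classificationMetric("confusion", prediction, truth, K),
                     "counts")
      n <- sum(counts)
      po <- sum(diag(counts)) / n
      pe <- sum(rowSums(counts) * colSums(counts)) / n^2
      (po - pe) / (1 - pe)
    },
    precision = {
      pr <- perClassPrecisionRecall(clabel, truth, K)
      if (K == 2L) pr$precision[1L]
      else structure(mean(pr$precision), perClass = pr$precision)
    },
    recall = {
      pr <- perClassPrecisionRecall(clabel, truth, K)
      if (K == 2L) pr$recall[1L]
      else structure(mean(pr$recall), perClass = pr$recall)
    },
    tval = {
      x1 <- out[truth == 1L]; x2 <- out[truth == 2L]
      n1 <- length(x1); n2 <- length(x2)
      sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
        (n1 + n2 - 2)
      (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    },
    stopf("unknown classification metric '%s'", name))
}

perClassPrecisionRecall <- function(clabel, truth, K) {
  precision <- recall <- numeric(K)
  for (k in seq_len(K)) {
    tp <- sum(clabel == k & truth == k)
    fp <- sum(clabel == k & truth != k)
    fn <- sum(clabel != k & truth == k)
    precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  list(precision = precision, recall = recall)
}

#' Regression performance metrics
#'
#' \code{mae} = mean absolute error, \code{mse} = mean squared error,
#' \code{r_squared} = 1 - SS_res/SS_tot (fraction of variance explained;
#' can be negative for models worse than the mean).
#'
#' @param name metric name; @param predicted predicted responses;
#' @param truth true responses.
#' @return scalar metric value.
#' @export
regressionMetric <- function(name, predicted, truth) {
  if (name == "none") return(predicted)
  if (length(predicted) != length(truth)) stopf("length mismatch")
  switch(name,
    mae = mean(abs(truth - predicted)),
    mse = mean((truth - predicted)^2),
    r_squared = {
      sst <- sum((truth - mean(truth))^2)
      if (sst <= 0) {
        warnf("r_squared undefined for zero-variance truth")
        return(NA_real_)
      }
      1 - sum((truth - predicted)^2) / sst
    },
    stopf("unknown regression metric '%s'", name))
}

#' Test-size-weighted average of per-fold metric values
#'
#' Cross-validated metrics are first computed per test fold, then averaged
#' with weights proportional to the test-fold sizes (larger test sets get
#' larger weight), elementwise for vector- or matrix-valued metrics.
#'
#' @param values list of per-fold metric values (scalars, vectors, or
#'   matrices of identical shape).
#' @param sizes numeric vector of test-fold sizes.
#' @return the weighted average, same shape as the inputs.
#' @examples
#' weightedFoldAverage(list(0.9, 0.4), c(3, 2))  # 0.7
#' @export
weightedFoldAverage <- function(values, sizes) {
  if (length(values) == 0L) stopf("empty fold list")
  if (length(values) != length(sizes)) stopf("values/sizes length mismatch")
  w <- sizes / sum(sizes)
  out <- values[[1L]] * w[1L]
  for (i in seq_along(values)[-1L]) out <- out + values[[i]] * w[i]
  out
}

# direction for tuning: TRUE if larger is better, FALSE if smaller,
# NA if not orderable
metricDirection <- function(name) {
  if (name %in% c("accuracy", "auc", "f1", "kappa", "precision", "recall",
                  "r_squared", "tval")) TRUE
  else if (name %in% c("mae", "mse")) FALSE
  else NA
}

# chance level of a metric, used for statistics defaults
metricChance <- function(name, K) {
  switch(name, accuracy = 1 / K, auc = 0.5, NA_real_)
}
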