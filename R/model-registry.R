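# Model registry: maps model names to train/predict functions, default
# hyperparameters and capabilities. Custom models plug in through
# registerModel(), mirroring how train/test function pairs extend the
# toolbox.

.modelRegistry <- new.env(parent = emptyenv())

#' Register a model with the decoding engine
#'
#' Extension point for custom classifiers and regression models: supply a
#' train function \code{function(param, X, targets) -> model} and a predict
#' function \code{function(model, Xtest)} returning (classification) a list
#' with \code{clabel} and optionally \code{dval}/\code{prob}, or
#' (regression) a numeric vector. Registered models are available to
#' \code{\link{crossValidate}} and all high-level drivers by name.
#'
#' @param name model name.
#' @param train,predict the train/predict function pair.
#' @param task "classification" or "regression".
#' @param defaults named list of default hyperparameters.
#' @param output the richest output the model produces:
#'   "prob", "dval", or "clabel".
#' @examples
#' # a nearest-centroid prototype classifier ships as model "prototype"
#' listModels()
#' @export
registerModel <- function(name, train, predict,
                          task = c("classification", "regression"),
                          defaults = list(), output = "clabel") {
  task <- match.arg(task)
  assign(name, list(train = train, predict = predict, task = task,
                    defaults = defaults, output = output),
         envir = .modelRegistry)
  invisible(name)
}

#' @rdname registerModel
#' @export
listModels <- function() sort(ls(.modelRegistry))

getModel <- function(name) {
  if (!exists(name, envir = .modelRegistry, inherits = FALSE))
    stopf("unknown model '%s'; available: %s", name,
          paste(listModels(), collapse = ", "))
  get(name, envir = .modelRegistry, inherits = FALSE)
}

#' Default hyperparameters for a model
#'
#' @param name model name.
#' @return named list of defaults (possibly empty).
#' @export
getHyperparameter <- function(name) getModel(name)$defaults

#' Train / predict by model name
#'
#' Low-level dispatch into the model registry; the cross-validation engine
#' and high-level drivers go through these.
#'
#' @param name registered model name.
#' @param param hyperparameter list (defaults filled in).
#' @param X training or test data; @param targets labels or responses.
#' @export
trainModel <- function(name, param = list(), X, targets) {
  m <- getModel(name)
  param <- utils::modifyList(m$defaults, param)
  m$train(param, X, targets)
}

#' @rdname trainModel
#' @param model a fitted model object.
#' @export
predictModel <- function(name, model, X) getModel(name)$predict(model, X)

modelTask <- function(name) getModel(name)$task

# nearest-centroid prototype classifier: the worked example of a custom
# model. Assigns each sample to the closest class centroid; dval (2
# classes) is the difference of squared distances.
trainPrototype <- function(param, X, clabel) {
  v <- validateInputs(X, clabel)
  X <- asMatrix(v$X); clabel <- v$targets
  centroids <- t(sapply(seq_len(v$K), function(k)
    colMeans(X[clabel == k, , drop = FALSE])))
  structure(list(centroids = centroids, K = v$K, mapping = v$mapping),
            class = c("prototypeModel", "mvModel"))
}

predictPrototype <- function(model, X) {
  X <- asMatrix(X)
  d2 <- sapply(seq_len(model$K), function(k)
    rowSums(sweep(X, 2L, model$centroids[k, ])^2))
  d2 <- matrix(d2, ncol = model$K)
  dval <- if (model$K == 2L) (d2[, 2L] - d2[, 1L]) / 2 else NULL
  list(clabel = max.col(-d2, ties.method = "first"), dval = dval,
       prob = NULL)
}

# populated at load time
registerBuiltinModels <- function() {
  registerModel("lda", trainLDA, predictLDA, "classification",
                defaults = list(lambda = "auto", prior = "empirical"),
                output = "prob")
  registerModel("multiclass_lda", trainMulticlassLDA, predictMulticlassLDA,
                "classification",
                defaults = list(lambda = "auto", prior = "empirical"),
                output = "prob")
  registerModel("naive_bayes", trainNaiveBayes, predictNaiveBayes,
                "classification",
                defaults = list(prior = "empirical"), output = "prob")
  registerModel("logreg", trainLogreg, predictLogreg, "classification",
                defaults = list(reg = "logf", lambda = 0.1, tol = 1e-6,
                                maxIter = 200L), output = "prob")
  registerModel("svm", trainSVM, predictSVM, "classification",
                defaults = list(c = 1, kernel = "linear", prob = FALSE,
                                tol = 1e-3, maxIter = 1000L),
                output = "dval")
  registerModel("kernel_fda", trainKernelFDA, predictKernelFDA,
                "classification",
                defaults = list(lambda = 0.01, kernel = "linear"),
                output = "dval")
  registerModel("ensemble", trainEnsemble, predictEnsemble,
                "classification",
                defaults = list(learner = "lda", strategy = "vote",
                                nLearners = 50L, seed = 1L),
                output = "clabel")
  registerModel("prototype", trainPrototype, predictPrototype,
                "classification", defaults = list(), output = "dval")
  registerModel("ridge", trainRidge, predictRidge, "regression",
                defaults = list(lambda = 0, form = "auto",
                                intercept = TRUE))
  registerModel("kernel_ridge", trainKernelRidge, predictKernelRidge,
                "regression",
                defaults = list(lambda = 0, kernel = "linear"))
}

.onLoad <- function(libname, pkgname) registerBuiltinModels()
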