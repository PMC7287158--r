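# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded operations in the package
# go through this so that library calls never disturb user RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream labels; keeps independent
# randomness streams (folds, permutations, generators) decoupled while
# remaining a pure function of the base seed. Result is kept < 2^31.
childSeed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  s <- as.numeric(seed)
  for (p in parts) s <- (s * 69069 + p * 2654435761) %% 2147483647
  as.integer(s)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# coerce matrix-like input to a plain numeric matrix
asMatrix <- function(X) {
  if (is(X, "DecodingData")) X <- dataValues(X)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (length(dim(X)) != 2L) stopf("expected 2-D [samples x features] input")
  storage.mode(X) <- "double"
  X
}
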