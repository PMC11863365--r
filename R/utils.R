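#' @importFrom stats coef lm median optimize quantile rlnorm rnorm runif sd var setNames predict mad
#' @importFrom utils read.csv write.csv head
#' @importFrom e1071 svm
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic k-fold assignment of n items.
cv_folds <- function(n, k, seed) {
  k <- min(k, n)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
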