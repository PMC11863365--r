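# Internal SVR machinery: training-only standardization, recursive feature
# elimination with a linear-kernel surrogate ranker, and hyperparameter
# tuning by k-fold cross-validation. All randomness (fold assignment) is
# derived from explicit seeds.

# Center/scale parameters from training rows only.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

svr_fit <- function(X, y, kernel = "radial", cost = 1, gamma = 1 / ncol(X),
                    epsilon = 0.1) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
             cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

# Feature weights of a linear-kernel SVR: w = t(alpha) %*% SV.
linear_svr_weights <- function(X, y, cost = 1, epsilon = 0.1) {
  fit <- svr_fit(X, y, kernel = "linear", cost = cost, epsilon = epsilon)
  as.numeric(crossprod(fit$coefs, fit$SV))
}

cv_mae <- function(X, y, folds, ...) {
  errs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
    fit <- svr_fit(X[tr, , drop = FALSE], y[tr], ...)
    mean(abs(predict(fit, X[!tr, , drop = FALSE]) - y[!tr]))
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}

# SVM-RFE: rank features with a linear-kernel SVR on the current set, drop
# the worst fraction (default 25% per step) down to `floor_n`; the retained
# set is the candidate with the lowest k-fold CV MAE (ties -> fewer
# features).
rfe_select <- function(X, y, folds, floor_n = 4, step_frac = 0.75,
                       cost = 1, epsilon = 0.01) {
  current <- colnames(X)
  candidates <- list(current)
  while (length(current) > floor_n) {
    w <- linear_svr_weights(X[, current, drop = FALSE], y, cost, epsilon)
    keep_n <- max(floor_n, min(length(current) - 1L,
                               ceiling(length(current) * step_frac)))
    current <- current[order(-abs(w))][seq_len(keep_n)]
    candidates <- c(candidates, list(current))
  }
  scores <- vapply(candidates, function(set) {
    cv_mae(X[, set, drop = FALSE], y, folds, kernel = "radial",
           gamma = 1 / length(set), cost = 1, epsilon = epsilon)
  }, numeric(1))
  sizes <- lengths(candidates)
  best <- order(scores, sizes)[1]
  selected <- candidates[[best]]
  if (length(selected) == 0) {
    warning("RFE selected zero features; falling back to all", call. = FALSE)
    selected <- colnames(X)
  }
  selected
}

default_svr_grid <- function() {
  rbind(
    expand.grid(kernel = "radial", cost = c(1, 10, 100),
                gamma_mult = c(0.3, 1, 3), epsilon = c(0.1, 0.01),
                stringsAsFactors = FALSE),
    expand.grid(kernel = "linear", cost = c(1, 10), gamma_mult = 1,
                epsilon = c(0.1, 0.01), stringsAsFactors = FALSE)
  )
}

# Grid search by k-fold CV MAE; deterministic tie-break on grid order.
tune_svr <- function(X, y, folds, grid = default_svr_grid()) {
  p <- ncol(X)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    cv_mae(X, y, folds, kernel = grid$kernel[g], cost = grid$cost[g],
           gamma = grid$gamma_mult[g] / p, epsilon = grid$epsilon[g])
  }, numeric(1))
  best <- which.min(scores)
  list(kernel = grid$kernel[best], cost = grid$cost[best],
       gamma = grid$gamma_mult[best] / p, epsilon = grid$epsilon[best],
       cv_mae = scores[best])
}
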