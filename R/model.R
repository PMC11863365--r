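# The sensitivity model: Box-Cox target transform + training-only
# standardization + SVM-RFE feature selection + CV-tuned support vector
# regression, trained over many random 80:20 train/test iterations with
# median-error model selection.

#' Train one sensitivity-model iteration
#'
#' Randomly splits the lipids into a training and a held-out portion
#' (`split_fraction` to training), then — on the training portion only —
#' optionally Box-Cox transforms the relative sensitivities, standardizes
#' the descriptors (center/scale from training rows), optionally runs
#' recursive feature elimination with a linear-kernel SVR ranker, and tunes
#' an SVR by `k`-fold cross-validation. Held-out error is computed on
#' back-transformed predictions.
#'
#' `split_fraction = 1` trains on every lipid (used by the hold-out
#' validators, which bring their own test set); held-out metrics are then
#' `NA`.
#'
#' @param X Cleaned numeric descriptor matrix (lipids x descriptors), row
#'   names = lipid ids.
#' @param y Strictly positive relative sensitivities (`m_R`), aligned with
#'   the rows of `X`.
#' @param seed Integer seed controlling the split and the CV folds.
#' @param split_fraction Fraction of lipids used for training (default 0.8).
#' @param use_rfe,use_boxcox Toggle the two workflow components.
#' @param n_folds Cross-validation folds for tuning (default 5).
#' @param grid Hyperparameter grid (see `default_svr_grid`); a data.frame
#'   with columns `kernel`, `cost`, `gamma_mult`, `epsilon`.
#' @param rfe_floor Smallest candidate feature-set size for RFE.
#' @param compute_cv_r2 Also compute the R-squared of cross-validated
#'   predictions on the training portion (slightly slower). Default `FALSE`.
#' @return A `sensitivity_model` object.
#' @export
train_sensitivity_model <- function(X, y, seed, split_fraction = 0.8,
                                    use_rfe = TRUE, use_boxcox = TRUE,
                                    n_folds = 5, grid = default_svr_grid(),
                                    rfe_floor = 4, compute_cv_r2 = FALSE) {
  abort_if(!is.matrix(X) || is.null(rownames(X)), "X must be a matrix with row names")
  abort_if(length(y) != nrow(X), "y must align with rows of X")
  abort_if(any(y <= 0), "m_R values must be strictly positive")
  abort_if(split_fraction <= 0 || split_fraction > 1,
           "split_fraction must be in (0, 1]")
  n <- nrow(X)
  ids <- rownames(X)
  if (split_fraction < 1) {
    n_train <- round(split_fraction * n)
    abort_if(n_train < 5, "training portion too small")
    tr_idx <- with_seed(seed, sort(sample(n, n_train)))
  } else {
    tr_idx <- seq_len(n)
  }
  te_idx <- setdiff(seq_len(n), tr_idx)

  y_tr <- y[tr_idx]
  if (use_boxcox) {
    bc <- boxcox_fit(y_tr)
    lambda <- bc$lambda
    z_tr <- bc$transformed
  } else {
    lambda <- NA_real_
    z_tr <- y_tr
  }

  scaler <- fit_scaler(X[tr_idx, , drop = FALSE])
  Xs_tr <- apply_scaler(X[tr_idx, , drop = FALSE], scaler)

  folds <- cv_folds(length(tr_idx), n_folds, seed + 10000L)
  selected <- if (use_rfe) {
    rfe_select(Xs_tr, z_tr, folds, floor_n = rfe_floor)
  } else colnames(X)

  tuned <- tune_svr(Xs_tr[, selected, drop = FALSE], z_tr, folds, grid)
  fit <- svr_fit(Xs_tr[, selected, drop = FALSE], z_tr,
                 kernel = tuned$kernel, cost = tuned$cost,
                 gamma = tuned$gamma, epsilon = tuned$epsilon)

  model <- structure(list(
    lambda = lambda, use_boxcox = use_boxcox, use_rfe = use_rfe,
    scaler = scaler, selected_descriptors = selected, fit = fit,
    hyperparameters = tuned, seed = seed,
    train_ids = ids[tr_idx], test_ids = ids[te_idx],
    test_mae = NA_real_, test_mdape = NA_real_, test_mean_ape = NA_real_,
    cv_r2 = NA_real_
  ), class = "sensitivity_model")

  if (length(te_idx) > 0) {
    pred <- predict_mR(model, X[te_idx, , drop = FALSE])
    ape <- 100 * abs(pred - y[te_idx]) / y[te_idx]
    model$test_mae <- mean(abs(pred - y[te_idx]))
    model$test_mdape <- median(ape)
    model$test_mean_ape <- mean(ape)
  }
  if (compute_cv_r2) {
    zhat <- numeric(length(tr_idx))
    for (f in sort(unique(folds))) {
      infold <- folds == f
      cvfit <- svr_fit(Xs_tr[!infold, selected, drop = FALSE], z_tr[!infold],
                       kernel = tuned$kernel, cost = tuned$cost,
                       gamma = tuned$gamma, epsilon = tuned$epsilon)
      zhat[infold] <- predict(cvfit, Xs_tr[infold, selected, drop = FALSE])
    }
    yhat <- if (use_boxcox) boxcox_inverse(zhat, lambda) else zhat
    model$cv_r2 <- 1 - sum((y_tr - yhat)^2) / sum((y_tr - mean(y_tr))^2)
  }
  model
}

#' Predict relative sensitivity for new lipids
#'
#' Applies the model's standardization, regressor and inverse Box-Cox
#' transform. Output is finite and strictly positive.
#'
#' @param model A `sensitivity_model`.
#' @param newdata Numeric matrix (or single row) containing at least the
#'   model's selected descriptors as columns.
#' @return Named numeric vector of predicted `m_R` values.
#' @export
predict_mR <- function(model, newdata) {
  abort_if(!inherits(model, "sensitivity_model"), "not a sensitivity_model")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  missing_cols <- setdiff(model$selected_descriptors, colnames(newdata))
  abort_if(length(missing_cols) > 0, "missing descriptor(s): ",
           paste(missing_cols, collapse = ", "))
  sel <- model$selected_descriptors
  scaler <- list(center = model$scaler$center[sel], scale = model$scaler$scale[sel])
  Xs <- apply_scaler(newdata[, sel, drop = FALSE], scaler)
  z <- predict(model$fit, Xs)
  out <- if (model$use_boxcox) boxcox_inverse(z, model$lambda) else pmax(z, 1e-12)
  setNames(as.numeric(out), rownames(newdata))
}

#' Train an ensemble of model iterations and select the median model
#'
#' Runs `n_iterations` independent train/test iterations (iteration `i`
#' uses seed `base_seed + i`) and selects the model whose held-out error is
#' the median of the iteration errors (lower median for an even count; ties
#' broken by the lower seed). Mitigates the sensitivity of a small lipid
#' panel to any single train/test allocation.
#'
#' @inheritParams train_sensitivity_model
#' @param n_iterations Number of iterations (odd recommended; default 1101).
#' @param base_seed Base seed; iteration `i` uses `base_seed + i`.
#' @param metric Selection metric: `"mae"` (mean absolute error of predicted
#'   `m_R` on the held-out lipids, the default) or `"mdape"`.
#' @param ... Passed on to [train_sensitivity_model()].
#' @return A `sensitivity_ensemble`: list with `models`, `errors`,
#'   `selected_index`, `selected_model`, `n_failed`.
#' @export
run_ensemble <- function(X, y, n_iterations = 1101, base_seed = 0,
                         metric = c("mae", "mdape"), ...) {
  metric <- match.arg(metric)
  abort_if(n_iterations < 1, "n_iterations must be >= 1")
  models <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    models[[i]] <- tryCatch(
      train_sensitivity_model(X, y, seed = base_seed + i, ...),
      error = function(e) {
        warning("iteration ", i, " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  ok <- !vapply(models, is.null, logical(1))
  abort_if(!any(ok), "every ensemble iteration failed")
  models <- models[ok]
  errors <- vapply(models, function(m)
    if (metric == "mae") m$test_mae else m$test_mdape, numeric(1))
  seeds <- vapply(models, function(m) m$seed, numeric(1))
  ord <- order(errors, seeds)
  sel <- ord[floor((length(ord) + 1) / 2)]   # lower median
  structure(list(
    models = models, errors = errors, seeds = seeds,
    selected_index = sel, selected_model = models[[sel]],
    n_iterations = n_iterations, n_failed = sum(!ok),
    base_seed = base_seed, metric = metric
  ), class = "sensitivity_ensemble")
}

#' Learning curve over train/test split fractions
#'
#' For each split fraction, trains a small ensemble and summarizes held-out
#' error (median of per-iteration MdAPE, mean of per-iteration mean APE),
#' the diagnostic used to choose the operating split ratio.
#'
#' @inheritParams run_ensemble
#' @param split_fractions Fractions in (0.1, 0.95).
#' @param n_iterations_per_point Iterations per fraction (default 25).
#' @return data.frame with columns `split_fraction`, `mdape`, `mean_ape`,
#'   `n_test`.
#' @export
learning_curve <- function(X, y, split_fractions = c(0.5, 0.6, 0.7, 0.8, 0.9),
                           n_iterations_per_point = 25, base_seed = 0, ...) {
  abort_if(any(split_fractions <= 0.1 | split_fractions >= 0.95),
           "split fractions must lie in (0.1, 0.95)")
  rows <- lapply(split_fractions, function(f) {
    n_test <- nrow(X) - round(f * nrow(X))
    if (n_test < 2) {
      warning("fraction ", f, " leaves fewer than 2 test lipids; skipped",
              call. = FALSE)
      return(NULL)
    }
    ens <- run_ensemble(X, y, n_iterations = n_iterations_per_point,
                        base_seed = base_seed, split_fraction = f, ...)
    mdapes <- vapply(ens$models, `[[`, numeric(1), "test_mdape")
    mapes <- vapply(ens$models, `[[`, numeric(1), "test_mean_ape")
    data.frame(split_fraction = f, mdape = median(mdapes),
               mean_ape = mean(mapes), n_test = n_test)
  })
  do.call(rbind, rows)
}

#' Descriptor selection frequency across ensemble iterations
#'
#' How often each descriptor survived feature elimination, and the same
#' aggregated by descriptor family (e.g. all Geary `GATS*` descriptors
#' together) — the model-interpretability summary.
#'
#' @param ensemble A `sensitivity_ensemble`.
#' @return List with `by_descriptor` (descriptor, family, frequency in
#'   [0, 1], sorted decreasing) and `by_family` (mean selection frequency of
#'   the family's members that were ever selected, plus total selections).
#' @export
descriptor_importance <- function(ensemble) {
  abort_if(!inherits(ensemble, "sensitivity_ensemble"), "not an ensemble")
  sel <- unlist(lapply(ensemble$models, `[[`, "selected_descriptors"))
  tab <- table(sel) / length(ensemble$models)
  fam <- ifelse(grepl("^(ATS|AATS|ATSC|MATS|GATS)\\d", names(tab)),
                sub("^(ATS|AATS|ATSC|MATS|GATS).*$", "\\1", names(tab)),
                "constitutional")
  by_desc <- data.frame(descriptor = names(tab), family = fam,
                        frequency = as.numeric(tab), stringsAsFactors = FALSE)
  by_desc <- by_desc[order(-by_desc$frequency, by_desc$descriptor), ]
  rownames(by_desc) <- NULL
  agg <- aggregate(frequency ~ family, by_desc, mean)
  agg$total_selections <- as.numeric(
    tapply(by_desc$frequency, by_desc$family, sum)[agg$family] *
      length(ensemble$models))
  list(by_descriptor = by_desc, by_family = agg[order(-agg$frequency), ])
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat("<sensitivity_model> seed ", x$seed, "; ",
      length(x$train_ids), " train / ", length(x$test_ids), " test lipids\n",
      "  Box-Cox lambda: ", if (x$use_boxcox) signif(x$lambda, 4) else "off",
      "; RFE: ", if (x$use_rfe) paste0(length(x$selected_descriptors),
                                       " descriptors") else "off", "\n",
      "  kernel ", x$hyperparameters$kernel, ", cost ", x$hyperparameters$cost,
      "; held-out MdAPE ", signif(x$test_mdape, 4), "%\n", sep = "")
  invisible(x)
}

#' @export
print.sensitivity_ensemble <- function(x, ...) {
  cat("<sensitivity_ensemble> ", length(x$models), " iterations (",
      x$n_failed, " failed), metric ", x$metric, "\n",
      "  selected iteration seed ", x$selected_model$seed,
      " with error ", signif(x$errors[x$selected_index], 4), "\n", sep = "")
  invisible(x)
}
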