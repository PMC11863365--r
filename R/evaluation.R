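# Validation battery: percent-error and precision summaries, a stated
# outlier rule, leave-class-out and extreme-size hold-outs, and spike
# recovery.

#' Summarize quantitation errors and precision
#'
#' Per-lipid mean absolute percent error across samples, the global mean of
#' those per-lipid errors (with and without rule-flagged outliers), the
#' median absolute percent error over all rows, and precision defined as
#' the mean over lipids of the coefficient of variation (stdev/mean x 100)
#' of predicted concentrations across replicate samples.
#'
#' @param quant A `quant_result` (rows lacking `true_conc` are dropped with
#'   a warning).
#' @param replicate_groups Optional named vector mapping `sample_id` to a
#'   replicate group (e.g. the calibration level): the CV is then computed
#'   within each group of replicate samples and averaged over groups with at
#'   least two samples. By default all of a lipid's samples form one group,
#'   which is only meaningful when they are true replicates.
#' @return A `validation_report` list: `per_lipid`, `global_mean_error`,
#'   `global_mean_error_outliers_removed`, `outlier_ids`, `mdape`,
#'   `precision`.
#' @export
percent_error_summary <- function(quant, replicate_groups = NULL) {
  miss <- is.na(quant$true_conc) | is.na(quant$percent_error)
  if (any(miss)) {
    warning(sum(miss), " rows without known truth dropped", call. = FALSE)
    quant <- quant[!miss, , drop = FALSE]
  }
  abort_if(nrow(quant) == 0, "no rows with known truth")
  per_lipid <- aggregate(percent_error ~ lipid_id, quant, mean)
  names(per_lipid)[2] <- "mean_ape"
  one_cv <- function(v) {
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    100 * sd(v) / mean(v)
  }
  grp <- if (is.null(replicate_groups)) rep("all", nrow(quant))
         else as.character(replicate_groups[quant$sample_id])
  cv <- vapply(split(seq_len(nrow(quant)), quant$lipid_id), function(idx) {
    g_cvs <- vapply(split(quant$predicted_conc[idx], grp[idx]), one_cv,
                    numeric(1))
    if (all(is.na(g_cvs))) NA_real_ else mean(g_cvs, na.rm = TRUE)
  }, numeric(1))
  per_lipid$cv <- cv[per_lipid$lipid_id]
  errs <- setNames(per_lipid$mean_ape, per_lipid$lipid_id)
  out_ids <- outlier_rule(errs)
  keep <- !(per_lipid$lipid_id %in% out_ids)
  structure(list(
    per_lipid = per_lipid,
    global_mean_error = mean(per_lipid$mean_ape),
    global_mean_error_outliers_removed = mean(per_lipid$mean_ape[keep]),
    outlier_ids = out_ids,
    mdape = median(quant$percent_error),
    precision = mean(per_lipid$cv, na.rm = TRUE)
  ), class = "validation_report")
}

#' Flag high-error lipids
#'
#' The stated rule (applied identically everywhere): a lipid is an outlier
#' when its mean absolute percent error exceeds the median plus three times
#' the median absolute deviation (scaled, `stats::mad`) of the per-lipid
#' errors. With fewer than 5 lipids no outliers are flagged.
#'
#' @param per_lipid_errors Named vector of per-lipid mean APEs.
#' @return Character vector of flagged lipid ids (possibly empty).
#' @export
outlier_rule <- function(per_lipid_errors) {
  if (length(per_lipid_errors) < 5) return(character(0))
  thr <- median(per_lipid_errors) + 3 * mad(per_lipid_errors)
  names(per_lipid_errors)[per_lipid_errors > thr]
}

# Out-of-sample R^2 of predicted vs true values in original space
# (can be strongly negative).
oos_r2 <- function(truth, pred) {
  if (length(truth) < 2 || var(truth) == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' Leave-class-out validation
#'
#' Trains on every lipid outside `held_class` (no internal split) and
#' reports the out-of-sample R-squared of predicted vs true `m_R` for the
#' held-out class, in original (back-transformed) space; extrapolation to a
#' class whose sensitivity law was never seen typically yields a strongly
#' negative R-squared.
#'
#' @param X,y Descriptors and relative sensitivities for all lipids.
#' @param class_labels Lipid-class label per row of `X`.
#' @param held_class Class to hold out.
#' @param seed Seed for CV folds during tuning.
#' @param ... Passed to [train_sensitivity_model()].
#' @return List with `held_class`, `r2`, `per_lipid` (id, true, predicted,
#'   APE), `n_train`.
#' @export
holdout_by_class <- function(X, y, class_labels, held_class, seed = 1, ...) {
  held <- class_labels == held_class
  abort_if(!any(held), "held class ", held_class, " has no members")
  abort_if(sum(!held) < 10, "fewer than 10 training lipids remain")
  model <- train_sensitivity_model(X[!held, , drop = FALSE], y[!held],
                                   seed = seed, split_fraction = 1, ...)
  pred <- predict_mR(model, X[held, , drop = FALSE])
  truth <- y[held]
  list(held_class = held_class,
       r2 = oos_r2(truth, pred),
       per_lipid = data.frame(lipid_id = rownames(X)[held], true_mR = truth,
                              predicted_mR = as.numeric(pred),
                              ape = 100 * abs(pred - truth) / truth,
                              stringsAsFactors = FALSE),
       n_train = sum(!held))
}

#' Extreme-size hold-out validation
#'
#' Holds out the `k_per_class` largest (or smallest) lipids by mass from
#' each class, trains on the remainder, and reports out-of-sample R-squared
#' of predicted vs true `m_R` — a test of extrapolation to chain lengths
#' beyond the training range. Ties in mass are broken by the
#' lexicographically smallest lipid id. Classes with too few members are
#' skipped with a warning.
#'
#' @inheritParams holdout_by_class
#' @param masses Monoisotopic mass per row of `X`.
#' @param which `"largest"` or `"smallest"`.
#' @param k_per_class Lipids held out per class (default 1).
#' @return List with `which`, `r2`, `per_lipid`, `held_ids`, `n_train`.
#' @export
holdout_by_size <- function(X, y, masses, class_labels,
                            which = c("largest", "smallest"),
                            k_per_class = 1, seed = 1, ...) {
  which <- match.arg(which)
  ids <- rownames(X)
  held_ids <- character(0)
  for (cl in unique(class_labels)) {
    members <- base::which(class_labels == cl)
    if (length(members) <= k_per_class) {
      warning("class ", cl, " too small; skipped", call. = FALSE)
      next
    }
    m <- masses[members]
    key <- if (which == "largest") -m else m
    ord <- members[order(key, ids[members])]
    held_ids <- c(held_ids, ids[ord[seq_len(k_per_class)]])
  }
  abort_if(length(held_ids) == 0, "no lipids held out")
  held <- ids %in% held_ids
  abort_if(sum(!held) < 10, "fewer than 10 training lipids remain")
  model <- train_sensitivity_model(X[!held, , drop = FALSE], y[!held],
                                   seed = seed, split_fraction = 1, ...)
  pred <- predict_mR(model, X[held, , drop = FALSE])
  truth <- y[held]
  list(which = which, r2 = oos_r2(truth, pred),
       per_lipid = data.frame(lipid_id = ids[held], true_mR = truth,
                              predicted_mR = as.numeric(pred),
                              ape = 100 * abs(pred - truth) / truth,
                              stringsAsFactors = FALSE),
       held_ids = held_ids, n_train = sum(!held))
}

#' Spike recovery from matrix vs neat samples
#'
#' Percent recovery of each lipid spiked at equal concentration into the
#' biological matrix and into neat solvent:
#' `recovery = 100 * area_matrix / area_neat`. Values above 100 indicate
#' ionization enhancement and are flagged.
#'
#' @param matrix_areas,neat_areas Named area vectors; lipids are paired by
#'   name.
#' @return data.frame with `lipid_id`, `recovery`, `flag` (`"enhancement"`,
#'   `"undefined"` for zero neat area, or `""`).
#' @export
recovery <- function(matrix_areas, neat_areas) {
  ids <- intersect(names(matrix_areas), names(neat_areas))
  abort_if(length(ids) == 0, "no paired lipids")
  rec <- ifelse(neat_areas[ids] > 0,
                100 * matrix_areas[ids] / neat_areas[ids], NA_real_)
  data.frame(lipid_id = ids, recovery = as.numeric(rec),
             flag = ifelse(is.na(rec), "undefined",
                           ifelse(rec > 100, "enhancement", "")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$per_lipid), " lipids\n",
      "  global mean error: ", signif(x$global_mean_error, 4), "% (",
      signif(x$global_mean_error_outliers_removed, 4),
      "% with outliers removed: ",
      if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ") else "none",
      ")\n  MdAPE: ", signif(x$mdape, 4), "%; precision (mean CV): ",
      signif(x$precision, 4), "%\n", sep = "")
  invisible(x)
}
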