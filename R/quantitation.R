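# Concentration estimation: invert the relative-sensitivity relationship
# (sample and blank responses relativized to the same-mode reference internal
# standard, divided by m_R), plus the two surrogate-calibration baselines
# used for comparison (one-point response factor, pooled class curve).

#' Predict concentration from peak area and relative sensitivity
#'
#' Relativizes the sample response and the blank response by the reference
#' internal standard's area in the respective sample, subtracts, divides by
#' the lipid's relative sensitivity, and scales by the reference standard's
#' spiked concentration:
#' `conc = (y / A_ref - b / A_ref_blank) / m_R * reference_conc`.
#' Because only area ratios enter, the estimate is invariant to any common
#' rescaling of the areas (instrument gain). Negative estimates (blank above
#' signal) are floored at 0 and flagged.
#'
#' @param y Peak area of the analyte in the sample (>= 0). Vectorized.
#' @param b Peak area of the analyte in the blank (>= 0).
#' @param mR Predicted or known relative sensitivity (> 0).
#' @param reference_area Reference internal standard's area in the sample
#'   (> 0).
#' @param blank_reference_area Reference standard's area in the blank;
#'   defaults to `reference_area`.
#' @param reference_conc Spiked concentration of the reference standard in
#'   the sample (same unit as the returned concentration). Default 1, i.e.
#'   concentrations are expressed in units of the reference spike.
#' @return Numeric concentrations, with attribute `floored` marking entries
#'   clipped at 0.
#' @export
predict_concentration <- function(y, b, mR, reference_area,
                                  blank_reference_area = reference_area,
                                  reference_conc = 1) {
  abort_if(any(mR <= 0), "m_R must be > 0")
  abort_if(any(reference_area <= 0) || any(blank_reference_area <= 0),
           "reference areas must be > 0")
  abort_if(any(y < 0) || any(b < 0), "peak areas must be >= 0")
  conc <- (y / reference_area - b / blank_reference_area) / mR * reference_conc
  floored <- conc < 0
  conc[floored] <- 0
  attr(conc, "floored") <- floored
  conc
}

#' Quantify lipids in samples with predicted relative sensitivities
#'
#' Applies [predict_concentration()] to every (sample, lipid) pair:
#' the blank term is the mean area of that lipid across blank samples, the
#' reference areas are taken from the same sample (and the blank mean for
#' the blank term), and the reference spike concentration is looked up from
#' the panel's calibration level of each sample.
#'
#' @param responses A `response_table`.
#' @param panel The `lipid_panel` (provides reference designation and spiked
#'   concentrations).
#' @param mR Named vector of relative sensitivities for the lipids to
#'   quantify.
#' @param mode Ion mode.
#' @param sample_ids Samples to quantify; default all calibrant and study
#'   samples.
#' @param method Label recorded in the output (default `"svr_model"`).
#' @return data.frame of class `quant_result`: `sample_id`, `lipid_id`,
#'   `method`, `predicted_mR`, `y`, `b`, `predicted_conc`, `true_conc`
#'   (`NA` when unknown), `percent_error`.
#' @export
quantify_samples <- function(responses, panel, mR, mode,
                             sample_ids = NULL, method = "svr_model") {
  abort_if(is.null(names(mR)), "mR must be a named vector")
  s <- responses$samples
  if (is.null(sample_ids))
    sample_ids <- s$sample_id[s$role %in% c("calibrant", "study_sample")]
  ref_id <- panel$lipid_id[panel$is_reference_standard & panel$ion_mode == mode]
  abort_if(length(ref_id) != 1, "panel must designate one reference in ", mode)
  a <- responses$areas
  rows <- list()
  for (sid in sample_ids) {
    lev <- s$calibration_level[match(sid, s$sample_id)]
    ref_area <- a$area[a$sample_id == sid & a$lipid_id == ref_id]
    if (length(ref_area) != 1 || ref_area <= 0) {
      warning("no reference area in sample ", sid, "; skipped", call. = FALSE)
      next
    }
    ref_conc <- if (!is.na(lev))
      panel[match(ref_id, panel$lipid_id), paste0("level_", lev)] else 1
    for (lid in names(mR)) {
      yv <- a$area[a$sample_id == sid & a$lipid_id == lid]
      if (length(yv) != 1) next
      bv <- mean_blank_area(responses, lid)
      cc <- predict_concentration(yv, bv, mR[[lid]], ref_area,
                                  reference_conc = ref_conc)
      truth <- if (!is.na(lev)) {
        panel[match(lid, panel$lipid_id), paste0("level_", lev)]
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, lipid_id = lid, method = method,
        predicted_mR = mR[[lid]], y = yv, b = bv,
        predicted_conc = as.numeric(cc), true_conc = as.numeric(truth),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  abort_if(is.null(out), "nothing quantified")
  out$percent_error <- ifelse(!is.na(out$true_conc) & out$true_conc > 0,
                              100 * abs(out$predicted_conc - out$true_conc) /
                                out$true_conc, NA_real_)
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Match the structurally most similar surrogate standard
#'
#' Same class/headgroup is mandatory; then minimal absolute difference in
#' total acyl carbons; then minimal difference in double-bond count; any
#' residual tie is broken by the lexicographically smallest `lipid_id`.
#'
#' @param analyte One-row data.frame (or list) with `lipid_class`,
#'   `carbons`, `double_bonds`.
#' @param standards data.frame of candidates with columns `lipid_id`,
#'   `lipid_class`, `carbons`, `double_bonds`.
#' @return The matched row of `standards`.
#' @export
match_surrogate <- function(analyte, standards) {
  cand <- standards[standards$lipid_class == analyte$lipid_class, , drop = FALSE]
  abort_if(nrow(cand) == 0, "no surrogate available for class ",
           analyte$lipid_class)
  dC <- abs(cand$carbons - analyte$carbons)
  dDB <- abs(cand$double_bonds - analyte$double_bonds)
  cand[order(dC, dDB, cand$lipid_id)[1], , drop = FALSE]
}

#' One-point surrogate calibration
#'
#' Estimates the analyte concentration from the response factor of the
#' single most structurally similar standard of the same class:
#' `RF = area_std / conc_std`, `conc = area_analyte / RF`.
#'
#' @param analyte List/row with `lipid_class`, `carbons`, `double_bonds`,
#'   `area` (blank-corrected peak area).
#' @param standards data.frame with `lipid_id`, `lipid_class`, `carbons`,
#'   `double_bonds`, `conc`, `area` (same sample/batch as the analyte).
#' @return List with `conc` and `matched_standard` (its `lipid_id`).
#' @export
one_point_calibration <- function(analyte, standards) {
  m <- match_surrogate(analyte, standards)
  abort_if(m$area <= 0 || m$conc <= 0, "matched standard ", m$lipid_id,
           " has non-positive area or concentration")
  rf <- m$area / m$conc
  list(conc = analyte$area / rf, matched_standard = m$lipid_id)
}

#' Lipid-class calibration-curve quantitation
#'
#' Pools the (spiked concentration, area) points of all same-class standards
#' into one least-squares line and uses its slope as the class response
#' factor: `conc = area_analyte / slope`. With a single class member it
#' falls back to [one_point_calibration()] with a warning.
#'
#' @inheritParams one_point_calibration
#' @return List with `conc`, `slope`, `n_standards` (and
#'   `matched_standard` when the fallback was used).
#' @export
class_curve_calibration <- function(analyte, standards) {
  cand <- standards[standards$lipid_class == analyte$lipid_class, , drop = FALSE]
  abort_if(nrow(cand) == 0, "no surrogate available for class ",
           analyte$lipid_class)
  if (nrow(cand) < 2) {
    warning("only one class standard; falling back to one-point calibration",
            call. = FALSE)
    op <- one_point_calibration(analyte, standards)
    return(list(conc = op$conc, slope = NA_real_, n_standards = 1L,
                matched_standard = op$matched_standard))
  }
  ord <- order(cand$conc)
  fit <- lm(cand$area[ord] ~ cand$conc[ord])
  slope <- unname(coef(fit)[2])
  abort_if(slope <= 0, "class curve slope is non-positive for class ",
           analyte$lipid_class)
  list(conc = analyte$area / slope, slope = slope, n_standards = nrow(cand))
}
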