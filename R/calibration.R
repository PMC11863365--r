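# Experimental ESI sensitivity: per-lipid ordinary least-squares calibration
# slope over the spiked concentration ladder, a linearity filter, and
# relativization of slopes to the mode-specific reference internal standard.

#' Construct a response table
#'
#' Bundles long-format peak areas with per-sample metadata.
#'
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `"calibrant"`, `"study_sample"`, `"blank"`, `"neat_spike"`), optional
#'   `calibration_level` (integer; required for calibrants), optional
#'   `donor`, `ion_mode`.
#' @param areas data.frame with columns `sample_id`, `lipid_id`, `area`
#'   (non-negative peak areas; absent combinations count as not detected).
#' @return A `response_table` object.
#' @export
response_table <- function(samples, areas) {
  abort_if(!all(c("sample_id", "role") %in% names(samples)),
           "samples needs sample_id and role columns")
  abort_if(!all(c("sample_id", "lipid_id", "area") %in% names(areas)),
           "areas needs sample_id, lipid_id, area columns")
  abort_if(!all(samples$role %in% c("calibrant", "study_sample", "blank", "neat_spike")),
           "unknown sample role")
  abort_if(!all(areas$sample_id %in% samples$sample_id),
           "areas reference unknown sample_id")
  abort_if(any(areas$area < 0, na.rm = TRUE), "peak areas must be >= 0")
  if (is.null(samples$calibration_level)) samples$calibration_level <- NA_integer_
  abort_if(any(samples$role == "calibrant" & is.na(samples$calibration_level)),
           "every calibrant sample needs a calibration_level")
  structure(list(samples = samples, areas = areas), class = "response_table")
}

#' Read a response table from delimited text files
#'
#' @param areas_path Long-format CSV (`sample_id, lipid_id, area`).
#' @param samples_path Sample-metadata CSV (`sample_id, role, ...`).
#' @param sep Field separator.
#' @return A `response_table`.
#' @export
read_responses <- function(areas_path, samples_path, sep = ",") {
  for (p in c(areas_path, samples_path))
    abort_if(!file.exists(p), "file not found: ", p)
  response_table(read.csv(samples_path, sep = sep, stringsAsFactors = FALSE),
                 read.csv(areas_path, sep = sep, stringsAsFactors = FALSE))
}

# Mean area per (lipid, calibration level) over calibrant samples.
calibrant_level_means <- function(responses, lipid_id) {
  s <- responses$samples
  cal <- s[s$role == "calibrant", ]
  a <- responses$areas
  a <- a[a$lipid_id == lipid_id & a$sample_id %in% cal$sample_id, ]
  if (nrow(a) == 0) return(numeric(0))
  lev <- cal$calibration_level[match(a$sample_id, cal$sample_id)]
  tapply(a$area, lev, mean)
}

mean_blank_area <- function(responses, lipid_id) {
  s <- responses$samples
  bl <- s$sample_id[s$role == "blank"]
  a <- responses$areas
  a <- a[a$lipid_id == lipid_id & a$sample_id %in% bl, ]
  if (nrow(a) == 0) 0 else mean(a$area)
}

#' Fit one external calibration curve
#'
#' Ordinary least-squares fit of `area = m * conc + intercept` with the
#' coefficient of determination of that fit. Degenerate input (constant
#' areas) yields slope 0 and R-squared 0.
#'
#' @param concs Strictly increasing spiked concentrations (>= 3 values).
#' @param areas Peak areas, same length.
#' @return List with `slope_m`, `intercept`, `r_squared`.
#' @export
fit_calibration_curve <- function(concs, areas) {
  abort_if(length(concs) != length(areas), "length mismatch")
  abort_if(length(concs) < 3, "need at least 3 calibration points")
  abort_if(any(diff(concs) <= 0), "concentrations must be strictly increasing")
  sst <- sum((areas - mean(areas))^2)
  if (sst == 0) return(list(slope_m = 0, intercept = mean(areas), r_squared = 0))
  sxx <- sum((concs - mean(concs))^2)
  slope <- sum((concs - mean(concs)) * (areas - mean(areas))) / sxx
  intercept <- mean(areas) - slope * mean(concs)
  ssres <- sum((areas - intercept - slope * concs)^2)
  list(slope_m = slope, intercept = intercept, r_squared = 1 - ssres / sst)
}

#' Choose the calibration levels used for slope fitting
#'
#' By default the top calibration level is dropped for every lipid, since the
#' highest calibrator commonly sits outside the linear response range.
#'
#' @param n_levels Total number of levels L defined by the panel.
#' @param policy `"drop_top"` (default), `"none"`, or `"drop_top_k"`.
#' @param k Number of top levels to drop for `"drop_top_k"`.
#' @return Integer vector of levels to use.
#' @export
apply_level_policy <- function(n_levels, policy = c("drop_top", "none", "drop_top_k"),
                               k = 1) {
  policy <- match.arg(policy)
  drop <- switch(policy, drop_top = 1L, none = 0L, drop_top_k = as.integer(k))
  levels_used <- seq_len(n_levels - drop)
  abort_if(length(levels_used) < 3,
           "level policy leaves fewer than 3 calibration levels")
  levels_used
}

#' Calibrate a lipid panel against measured responses
#'
#' For every lipid of the requested ion mode, fits the calibration line of
#' mean peak area against spiked concentration over the retained levels,
#' applies the linearity filter (lipids with R-squared below `r2_min` are
#' excluded), excludes non-positive slopes, and relativizes the surviving
#' slopes to the mode's reference internal standard.
#'
#' @param panel A `lipid_panel`.
#' @param responses A `response_table` containing the calibrant samples.
#' @param mode `"positive"` or `"negative"`.
#' @param levels_used Levels retained for fitting; default
#'   `apply_level_policy(L)` (top level dropped).
#' @param r2_min Linearity criterion; lipids with R-squared < `r2_min` get
#'   status `excluded_linearity`. Default 0.8.
#' @param blank_subtract If `TRUE`, the mean blank area of each lipid is
#'   subtracted from its calibrant areas before fitting. Default `FALSE`.
#' @param relativize If `TRUE` (default) compute `m_R` via
#'   [relativize_slopes()].
#' @return A `calibration_result` data.frame with one row per lipid:
#'   `lipid_id`, `lipid_class`, `slope_m`, `intercept`, `r_squared`, `m_R`,
#'   `status`, plus a `levels_used` attribute.
#' @export
calibrate_panel <- function(panel, responses, mode,
                            levels_used = NULL, r2_min = 0.8,
                            blank_subtract = FALSE, relativize = TRUE) {
  abort_if(!inherits(panel, "lipid_panel"), "`panel` must be a lipid_panel")
  abort_if(!inherits(responses, "response_table"),
           "`responses` must be a response_table")
  L <- attr(panel, "n_levels")
  if (is.null(levels_used)) levels_used <- apply_level_policy(L)
  sub <- panel[panel$ion_mode == mode, ]
  abort_if(nrow(sub) == 0, "no lipids in ", mode, " mode")

  res <- lapply(seq_len(nrow(sub)), function(r) {
    lid <- sub$lipid_id[r]
    lv_means <- calibrant_level_means(responses, lid)
    have <- intersect(levels_used, as.integer(names(lv_means)))
    row <- data.frame(lipid_id = lid, lipid_class = sub$lipid_class[r],
                      slope_m = NA_real_, intercept = NA_real_,
                      r_squared = NA_real_, m_R = NA_real_,
                      status = "excluded_missing", stringsAsFactors = FALSE)
    if (length(have) < 3) return(row)
    concs <- as.numeric(sub[r, paste0("level_", have)])
    areas <- as.numeric(lv_means[as.character(have)])
    if (blank_subtract) areas <- areas - mean_blank_area(responses, lid)
    fit <- fit_calibration_curve(concs, areas)
    row$slope_m <- fit$slope_m
    row$intercept <- fit$intercept
    row$r_squared <- fit$r_squared
    row$status <- if (fit$slope_m <= 0) "excluded_nonpositive_slope"
                  else if (fit$r_squared < r2_min) "excluded_linearity"
                  else "included"
    row
  })
  out <- do.call(rbind, res)
  attr(out, "levels_used") <- levels_used
  attr(out, "ion_mode") <- mode
  class(out) <- c("calibration_result", "data.frame")
  if (relativize) {
    ref_id <- sub$lipid_id[sub$is_reference_standard]
    out <- relativize_slopes(out, ref_id)
  }
  out
}

#' Relativize calibration slopes to a reference internal standard
#'
#' Divides every included lipid's slope by the reference standard's slope,
#' yielding the unitless relative sensitivity `m_R`; the reference itself
#' gets `m_R = 1` exactly. `m_R` is invariant to any common rescaling of the
#' peak areas (instrument gain) because the reference slope cancels.
#'
#' @param cal A `calibration_result`.
#' @param reference_lipid_id Identifier of the reference standard.
#' @return The `calibration_result` with `m_R` filled in.
#' @export
relativize_slopes <- function(cal, reference_lipid_id) {
  i <- match(reference_lipid_id, cal$lipid_id)
  abort_if(is.na(i), "reference standard ", reference_lipid_id,
           " not present in calibration results")
  abort_if(cal$status[i] != "included" || cal$slope_m[i] <= 0,
           "reference standard ", reference_lipid_id,
           " is excluded or has non-positive slope; cannot relativize")
  inc <- cal$status == "included"
  cal$m_R[inc] <- cal$slope_m[inc] / cal$slope_m[i]
  cal$m_R[i] <- 1
  attr(cal, "reference_lipid_id") <- reference_lipid_id
  cal
}

#' Assemble the model training table for one ion mode
#'
#' Aligns cleaned descriptors with relative sensitivities of the lipids that
#' passed the calibration filters. Lipids present in only one of the two
#' inputs are dropped (with a message).
#'
#' @param cal A `calibration_result` with `m_R` values.
#' @param descriptors A cleaned `descriptor_matrix` with lipid ids as rows.
#' @return List with `X` (descriptor matrix) and `y` (named `m_R` vector),
#'   rows aligned.
#' @export
build_training_table <- function(cal, descriptors) {
  inc <- cal[cal$status == "included", ]
  ids <- intersect(inc$lipid_id, rownames(descriptors))
  dropped <- setdiff(inc$lipid_id, ids)
  if (length(dropped) > 0)
    message("dropped (no descriptors): ", paste(dropped, collapse = ", "))
  abort_if(length(ids) < 5, "fewer than 5 included lipids with descriptors")
  if (length(ids) < 10)
    warning("fewer than 10 training lipids; model will be unstable", call. = FALSE)
  list(X = descriptors[ids, , drop = FALSE],
       y = setNames(inc$m_R[match(ids, inc$lipid_id)], ids))
}
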