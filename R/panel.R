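# Lipid panel: one row per lipid standard or analyte, with class, SMILES,
# ion mode, reference-standard flag and spiked concentration per calibration
# level (columns level_1..level_L).

#' Parse and validate a lipid panel table
#'
#' Validates a panel of lipid standards/analytes: every SMILES must parse,
#' `lipid_id` must be unique within an ion mode, calibration levels
#' `level_1..level_L` must be contiguous with strictly increasing
#' concentrations (the reference internal standard is exempt — it is spiked
#' at a constant level as an internal-standard channel), and each ion mode
#' must designate exactly one reference standard. Monoisotopic mass is
#' derived from the structure.
#'
#' @param df A data.frame with columns `lipid_id`, `lipid_class`, `smiles`,
#'   `ion_mode` (`"positive"`/`"negative"`), at least three `level_*`
#'   columns, and optionally `name` and `is_reference_standard` (logical).
#' @return A `lipid_panel` data.frame with a `monoisotopic_mass` column
#'   added and an attribute `n_levels`.
#' @export
parse_panel <- function(df) {
  req <- c("lipid_id", "lipid_class", "smiles", "ion_mode")
  miss <- setdiff(req, names(df))
  abort_if(length(miss) > 0, "panel is missing columns: ",
           paste(miss, collapse = ", "))
  lev_cols <- grep("^level_\\d+$", names(df), value = TRUE)
  lev_idx <- sort(as.integer(sub("level_", "", lev_cols)))
  abort_if(length(lev_idx) == 0, "panel has no level_* columns")
  abort_if(!identical(lev_idx, seq_along(lev_idx)),
           "calibration levels must be contiguous level_1..level_L")
  L <- length(lev_idx)

  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$name)) df$name <- df$lipid_id
  if (is.null(df$is_reference_standard)) df$is_reference_standard <- FALSE
  df$is_reference_standard <- as.logical(df$is_reference_standard)
  abort_if(!all(df$ion_mode %in% c("positive", "negative")),
           "ion_mode must be 'positive' or 'negative'")

  ok <- validate_smiles(df$smiles)
  abort_if(any(!ok), "unparsable SMILES in panel row(s): ",
           paste(which(!ok), collapse = ", "),
           " (lipid_id: ", paste(df$lipid_id[!ok], collapse = ", "), ")")

  for (mode in unique(df$ion_mode)) {
    sub <- df[df$ion_mode == mode, ]
    dup <- sub$lipid_id[duplicated(sub$lipid_id)]
    abort_if(length(dup) > 0, "duplicate lipid_id in ", mode, " mode: ",
             paste(unique(dup), collapse = ", "))
    nref <- sum(sub$is_reference_standard)
    abort_if(nref != 1, mode, " mode must have exactly one reference standard (found ",
             nref, ")")
  }

  conc <- as.matrix(df[, paste0("level_", seq_len(L))])
  storage.mode(conc) <- "double"
  for (r in seq_len(nrow(df))) {
    if (df$is_reference_standard[r]) next
    abort_if(any(!is.finite(conc[r, ])) || any(diff(conc[r, ]) <= 0) ||
               any(conc[r, ] <= 0),
             "spiked concentrations must be positive and strictly increasing ",
             "across levels for lipid ", df$lipid_id[r])
  }

  df$monoisotopic_mass <- exact_mass(df$smiles)
  structure(df, n_levels = L, class = c("lipid_panel", "data.frame"))
}

#' Read a lipid panel from a delimited text file
#'
#' @param path CSV (or TSV, `sep = "\t"`) file with the columns documented
#'   in [parse_panel()].
#' @param sep Field separator.
#' @return A validated `lipid_panel`.
#' @export
read_panel <- function(path, sep = ",") {
  abort_if(!file.exists(path), "panel file not found: ", path)
  parse_panel(read.csv(path, sep = sep, stringsAsFactors = FALSE))
}

#' Parse lipid shorthand nomenclature
#'
#' Extracts the class (headgroup) token, total acyl carbon count and total
#' double-bond count from shorthand names such as `"PC 15:0-18:1"`,
#' `"PC(15:0/18:1)"` or `"TG 16:0-18:1-18:2"`. Chain composition is summed
#' over all chains. Deuterium annotations such as `"(d7)"` are ignored.
#'
#' @param name Character vector of shorthand lipid names.
#' @return A data.frame with columns `name`, `lipid_class`, `carbons`,
#'   `double_bonds` (`NA` where no chain composition is present).
#' @export
parse_lipid_name <- function(name) {
  cls <- sub("^\\s*([A-Za-z0-9-]+).*$", "\\1", name)
  strip <- gsub("\\(d\\d+\\)", "", name)
  chains <- regmatches(strip, gregexpr("\\d+:\\d+", strip))
  carbons <- vapply(chains, function(ch) {
    if (length(ch) == 0) return(NA_real_)
    sum(as.numeric(sub(":.*", "", ch)))
  }, numeric(1))
  dbs <- vapply(chains, function(ch) {
    if (length(ch) == 0) return(NA_real_)
    sum(as.numeric(sub(".*:", "", ch)))
  }, numeric(1))
  data.frame(name = name, lipid_class = cls, carbons = carbons,
             double_bonds = dbs, stringsAsFactors = FALSE)
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat("<lipid_panel> ", nrow(x), " lipids, ", attr(x, "n_levels"),
      " calibration levels\n", sep = "")
  for (mode in unique(x$ion_mode)) {
    sub <- x[x$ion_mode == mode, ]
    cat("  ", mode, ": ", nrow(sub), " lipids (",
        paste(sort(unique(sub$lipid_class)), collapse = ", "),
        "); reference: ", sub$lipid_id[sub$is_reference_standard], "\n",
        sep = "")
  }
  invisible(x)
}
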