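# 2D molecular descriptors from the hydrogen-suppressed molecular graph:
# constitutional counts, classical topological indices, and the
# Moreau-Broto (ATS/AATS), centered (ATSC), Moran (MATS) and Geary (GATS)
# autocorrelation families over topological lags 1..8, weighted by tabulated
# atomic properties. Descriptor names follow the field's convention
# (e.g. GATS6se = Geary autocorrelation, lag 6, Sanderson electronegativity).

# Atomic property tables (standard tabulations): average mass, van der Waals
# radius (Angstrom), Sanderson / Pauling / Allred-Rochow electronegativity,
# polarizability (Angstrom^3), first ionization energy (eV), valence-electron
# count, principal quantum number.
.atom_props <- local({
  el <- c("H", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "Na", "K")
  data.frame(
    row.names = el,
    Z    = c(1, 6, 7, 8, 15, 16, 9, 17, 35, 53, 11, 19),
    mass = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06, 18.998, 35.45,
             79.904, 126.904, 22.990, 39.098),
    rvdw = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
             2.27, 2.75),
    se   = c(2.592, 2.746, 3.194, 3.654, 2.515, 2.957, 4.000, 3.475, 3.219,
             2.778, 0.835, 0.445),
    pe   = c(2.20, 2.55, 3.04, 3.44, 2.19, 2.58, 3.98, 3.16, 2.96, 2.66,
             0.93, 0.82),
    are  = c(2.20, 2.50, 3.07, 3.50, 2.06, 2.44, 4.10, 2.83, 2.74, 2.21,
             1.01, 0.91),
    pol  = c(0.667, 1.760, 1.100, 0.802, 3.630, 2.900, 0.557, 2.180, 3.050,
             5.350, 24.11, 43.40),
    ion  = c(13.598, 11.260, 14.534, 13.618, 10.487, 10.360, 17.423, 12.968,
             11.814, 10.451, 5.139, 4.341),
    zval = c(1, 4, 5, 6, 5, 6, 7, 7, 7, 7, 1, 1),
    pqn  = c(1, 2, 2, 2, 3, 3, 2, 3, 4, 5, 3, 4)
  )
})

.autocorr_props <- c("Z", "m", "v", "se", "pe", "are", "p", "i", "dv", "d", "s")
.autocorr_max_lag <- 8L

# Per-atom weight vectors for one parsed molecule.
atom_weights <- function(gr) {
  p <- .atom_props[gr$elements, ]
  abort_if(anyNA(p$Z), "unsupported element in molecule: ", gr$smiles)
  dv <- p$zval - gr$nH - gr$charges      # Kier-Hall valence delta
  s <- ifelse(gr$degree > 0,
              ((2 / p$pqn)^2 * dv + 1) / gr$degree,   # intrinsic state
              NA_real_)
  list(
    Z = p$Z, m = p$mass, v = (4 / 3) * pi * p$rvdw^3,
    se = p$se, pe = p$pe, are = p$are, p = p$pol, i = p$ion,
    dv = dv, d = as.numeric(gr$degree), s = s
  )
}

# All autocorrelation descriptors for one molecule.
autocorr_descriptors <- function(gr) {
  W <- atom_weights(gr)
  A <- gr$n_atoms
  D <- gr$dist
  ut <- upper.tri(D)
  dvec <- D[ut]
  out <- c()
  for (pn in .autocorr_props) {
    w <- W[[pn]]
    wc <- w - mean(w)
    ssc <- sum(wc^2)
    wi <- matrix(w, A, A)[ut]; wj <- matrix(w, A, A, byrow = TRUE)[ut]
    wci <- matrix(wc, A, A)[ut]; wcj <- matrix(wc, A, A, byrow = TRUE)[ut]
    vals <- c(ATS0 = sum(w^2), ATSC0 = ssc)
    names(vals) <- paste0(c("ATS0", "ATSC0"), pn)
    for (k in seq_len(.autocorr_max_lag)) {
      at <- which(dvec == k)
      dk <- length(at)                    # unordered pair count at lag k
      ats <- if (dk > 0) sum(wi[at] * wj[at]) else NA_real_
      atsc <- if (dk > 0) sum(wci[at] * wcj[at]) else NA_real_
      aats <- if (dk > 0) ats / dk else NA_real_
      mats <- if (dk > 0 && ssc > 0) (atsc / dk) / (ssc / A) else NA_real_
      gats <- if (dk > 0 && ssc > 0 && A > 1) {
        (sum((wi[at] - wj[at])^2) / (2 * dk)) / (ssc / (A - 1))
      } else NA_real_
      kv <- c(ats, aats, atsc, mats, gats)
      names(kv) <- paste0(c("ATS", "AATS", "ATSC", "MATS", "GATS"), k, pn)
      vals <- c(vals, kv)
    }
    if (anyNA(w)) vals[] <- NA_real_      # e.g. intrinsic state on a lone atom
    out <- c(out, vals)
  }
  out
}

constitutional_descriptors <- function(gr) {
  el <- gr$elements
  p <- .atom_props[el, ]
  deg <- gr$degree
  D <- gr$dist
  finD <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  comps <- length(unique(apply(D, 1, function(r) paste(which(is.finite(r)), collapse = ","))))
  nb <- nrow(gr$bonds)
  c(
    MW = sum(p$mass) + 1.008 * sum(gr$nH),
    nHeavy = gr$n_atoms,
    nHyd = sum(gr$nH),
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nP = sum(el == "P"), nS = sum(el == "S"),
    nX = sum(el %in% c("F", "Cl", "Br", "I")),
    nBonds = nb,
    nDouble = sum(gr$bonds[, "order"] == 2),
    nTriple = sum(gr$bonds[, "order"] == 3),
    nRings = nb - gr$n_atoms + comps,
    Zagreb1 = sum(deg^2),
    Zagreb2 = if (nb > 0) sum(deg[gr$bonds[, 1]] * deg[gr$bonds[, 2]]) else 0,
    Wiener = sum(finD),
    TopoDiameter = if (length(finD)) max(finD) else 0,
    MeanDist = if (length(finD)) mean(finD) else 0
  )
}

#' Compute 2D molecular descriptors from SMILES
#'
#' Builds the hydrogen-suppressed molecular graph of each structure (via
#' OpenBabel) and computes constitutional counts, classical topological
#' indices, and the Moreau-Broto (`ATS`, `AATS`), centered (`ATSC`), Moran
#' (`MATS`) and Geary (`GATS`) autocorrelation descriptor families over
#' topological lags 1 to 8, weighted by atomic mass, van der Waals volume,
#' three electronegativity scales, polarizability, ionization energy, valence
#' electrons, degree and intrinsic state. Descriptors are purely 2D — no
#' conformers are generated — so repeated calls on the same SMILES are
#' bitwise identical.
#'
#' Lags longer than a molecule's topological diameter have no atom pairs and
#' yield `NA`; such columns are removed later by [clean_descriptors()].
#' Molecules whose structure cannot be parsed are dropped with a warning
#' rather than aborting the whole matrix.
#'
#' @param x A `lipid_panel` (see [parse_panel()]) or a character vector of
#'   SMILES strings (optionally named; names become row names).
#' @return A numeric matrix of class `descriptor_matrix` (lipids x
#'   descriptors) with attributes `provenance` (descriptor family per column)
#'   and `failed` (identifiers of molecules that could not be processed).
#' @seealso [clean_descriptors()]
#' @export
compute_descriptors <- function(x) {
  if (inherits(x, "lipid_panel")) {
    smiles <- x$smiles
    ids <- x$lipid_id
  } else {
    smiles <- as.character(x)
    ids <- names(x) %||% paste0("mol_", seq_along(smiles))
  }
  rows <- vector("list", length(smiles))
  failed <- character(0)
  for (m in seq_along(smiles)) {
    row <- tryCatch({
      gr <- smiles_to_molgraph(smiles[m])
      c(constitutional_descriptors(gr), autocorr_descriptors(gr))
    }, error = function(e) NULL)
    if (is.null(row)) {
      warning("descriptor computation failed for ", ids[m], "; excluded",
              call. = FALSE)
      failed <- c(failed, ids[m])
    }
    rows[m] <- list(row)
  }
  keep <- !vapply(rows, is.null, logical(1))
  abort_if(!any(keep), "no molecule could be processed")
  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- ids[keep]
  fam <- ifelse(grepl("^(ATS|AATS|ATSC|MATS|GATS)\\d", colnames(mat)),
                sub("^(ATS|AATS|ATSC|MATS|GATS).*$", "\\1", colnames(mat)),
                "constitutional")
  structure(mat, provenance = setNames(fam, colnames(mat)), failed = failed,
            class = c("descriptor_matrix", class(mat)))
}

#' Clean a descriptor matrix for regression
#'
#' Drops columns containing any missing or non-finite value and columns with
#' zero variance, leaving a finite, informative matrix as required by support
#' vector regression and recursive feature elimination. The operation is
#' deterministic and idempotent.
#'
#' @param mat A `descriptor_matrix` from [compute_descriptors()], or any
#'   numeric matrix.
#' @return The cleaned matrix, with a `cleaning_report` attribute listing
#'   `dropped_missing` and `dropped_constant` column names. Provenance tags
#'   are subset accordingly.
#' @export
clean_descriptors <- function(mat) {
  abort_if(!is.matrix(mat) || !is.numeric(mat), "`mat` must be a numeric matrix")
  bad_missing <- colnames(mat)[apply(mat, 2, function(v) any(!is.finite(v)))]
  keep1 <- setdiff(colnames(mat), bad_missing)
  m1 <- mat[, keep1, drop = FALSE]
  bad_const <- colnames(m1)[apply(m1, 2, function(v) var(v) == 0)]
  keep <- setdiff(keep1, bad_const)
  abort_if(length(keep) == 0, "cleaning removed every descriptor column")
  out <- mat[, keep, drop = FALSE]
  prov <- attr(mat, "provenance")
  structure(out,
            provenance = if (!is.null(prov)) prov[keep],
            failed = attr(mat, "failed"),
            cleaning_report = list(dropped_missing = bad_missing,
                                   dropped_constant = bad_const),
            class = c("descriptor_matrix", "matrix", "array"))
}
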