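# SMILES -> molecular graph, via OpenBabel (ChemmineOB) for parsing and
# ChemmineR for the SDF container. Everything downstream (descriptors) works on
# the hydrogen-suppressed graph with per-atom implicit-hydrogen counts.

ob_quiet <- function(expr) {
  # OpenBabel writes parse warnings to stderr; keep them out of test output
  # while preserving R-level errors.
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  zz <- file(tf, open = "wt")
  sink(zz, type = "message")
  on.exit({ sink(type = "message"); close(zz) }, add = TRUE, after = FALSE)
  expr
}

#' Validate SMILES strings
#'
#' A SMILES string is considered valid when OpenBabel parses it to a molecule
#' with at least one atom.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, one element per input.
#' @export
validate_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    out <- tryCatch(
      ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES to OpenBabel's canonical form, so that alternative
#' encodings of the same structure collide (used for de-duplication).
#'
#' @param smiles Character vector of valid SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")))
    out <- trimws(strsplit(out, "\t")[[1]][1])
    abort_if(!nzchar(out), "SMILES could not be canonicalized: ", s)
    out
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into a molecular graph:
# elements, formal charges, implicit-H count per heavy atom, bond matrix
# (i, j, order), degree, and the heavy-atom topological distance matrix.
smiles_to_molgraph <- function(smiles) {
  sdf_txt <- ob_quiet(ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(smiles, "\n"),
    options = data.frame(names = "h", args = "")
  ))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  abort_if(length(lines) < 4, "SMILES could not be parsed: ", smiles)
  sdf <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n_all <- length(elements)

  charges <- integer(n_all)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    idx <- f[seq(1, length(f), by = 2)]
    charges[idx] <- f[seq(2, length(f), by = 2)]
  }

  bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
  heavy <- which(elements != "H")
  nH <- integer(n_all)
  for (b in seq_along(bi)) {
    if (elements[bi[b]] == "H") nH[bj[b]] <- nH[bj[b]] + 1L
    if (elements[bj[b]] == "H") nH[bi[b]] <- nH[bi[b]] + 1L
  }

  keep <- !(elements[bi] == "H" | elements[bj] == "H")
  remap <- match(seq_len(n_all), heavy)
  bonds <- cbind(i = remap[bi[keep]], j = remap[bj[keep]], order = bo[keep])

  n <- length(heavy)
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  D <- igraph::distances(g)

  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  bond_order_sum <- numeric(n)
  for (b in seq_len(nrow(bonds))) {
    bond_order_sum[bonds[b, 1]] <- bond_order_sum[bonds[b, 1]] + bonds[b, 3]
    bond_order_sum[bonds[b, 2]] <- bond_order_sum[bonds[b, 2]] + bonds[b, 3]
  }

  list(
    smiles = smiles,
    elements = elements[heavy],
    charges = charges[heavy],
    nH = nH[heavy],
    bonds = bonds,
    degree = degree,
    bond_order_sum = bond_order_sum,
    dist = D,
    n_atoms = n
  )
}

# Monoisotopic mass from structure (lightest-isotope masses).
.monoisotopic <- c(
  H = 1.0078250319, C = 12, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, F = 18.99840320, Cl = 34.96885271,
  Br = 78.9183376, I = 126.904468, Na = 22.98976928, K = 38.9637069
)

exact_mass <- function(smiles) {
  vapply(smiles, function(s) {
    gr <- smiles_to_molgraph(s)
    m <- .monoisotopic[gr$elements]
    abort_if(anyNA(m), "unsupported element for mass computation in: ", s)
    sum(m) + .monoisotopic[["H"]] * sum(gr$nH)
  }, numeric(1), USE.NAMES = FALSE)
}
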