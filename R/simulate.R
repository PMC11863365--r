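# Synthetic study generator: programmatic lipid panels (homologous series of
# glycerophospholipids, glycerolipids and ceramides with valid SMILES), a
# smooth descriptor -> sensitivity law with class structure and within-class
# spread, and noisy multi-level spiked response tables, so the whole pipeline
# is testable end to end without any external data.

# Linear acyl chain after the carbonyl: n_total carbons including the
# carbonyl carbon, with methylene-interrupted cis-style double bonds
# (written without stereo).
acyl_chain <- function(n_total, n_db) {
  n <- n_total - 1L
  abort_if(n < 1, "chain too short")
  abort_if(n_db > 0 && (3 + 3 * n_db) > n,
           "too many double bonds for chain length ", n_total)
  bond <- rep("", n)
  for (k in seq_len(n_db)) bond[3 + 3 * (k - 1) + 1] <- "="
  paste0(vapply(seq_len(n), function(i) paste0(bond[i], "C"), character(1)),
         collapse = "")
}

split_chains <- function(total, db, n_chains) {
  base <- rep(total %/% n_chains, n_chains)
  extra <- total %% n_chains
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  dbs <- rep(db %/% n_chains, n_chains)
  dextra <- db %% n_chains
  if (dextra > 0) dbs[seq_len(dextra)] <- dbs[seq_len(dextra)] + 1L
  list(carbons = base, db = dbs)
}

# SMILES scaffold per lipid class; `total`/`db` are summed over acyl chains
# (the ceramide sphingoid backbone contributes a fixed d18:1).
lipid_smiles <- function(class, total, db) {
  two <- function() {
    sp <- split_chains(total, db, 2L)
    list(a = acyl_chain(sp$carbons[1], sp$db[1]),
         b = acyl_chain(sp$carbons[2], sp$db[2]))
  }
  switch(class,
    PC = { c2 <- two(); paste0("C[N+](C)(C)CCOP(=O)([O-])OCC(OC(=O)", c2$b,
                               ")COC(=O)", c2$a) },
    PG = { c2 <- two(); paste0("OCC(O)COP(=O)(O)OCC(OC(=O)", c2$b,
                               ")COC(=O)", c2$a) },
    PI = { c2 <- two(); paste0("OC1C(O)C(O)C(OP(=O)(O)OCC(OC(=O)", c2$b,
                               ")COC(=O)", c2$a, ")C(O)C1O") },
    DG = { c2 <- two(); paste0("OCC(OC(=O)", c2$b, ")COC(=O)", c2$a) },
    TG = { sp <- split_chains(total, db, 3L)
           paste0("C(OC(=O)", acyl_chain(sp$carbons[2], sp$db[2]),
                  ")(COC(=O)", acyl_chain(sp$carbons[1], sp$db[1]),
                  ")COC(=O)", acyl_chain(sp$carbons[3], sp$db[3])) },
    LPC = paste0("C[N+](C)(C)CCOP(=O)([O-])OCC(O)COC(=O)", acyl_chain(total, db)),
    MG = paste0("OCC(O)COC(=O)", acyl_chain(total, db)),
    Cer = paste0("CCCCCCCCCCCCCC=CC(O)C(CO)NC(=O)", acyl_chain(total, db)),
    stop("unknown lipid class: ", class, call. = FALSE)
  )
}

.default_chain_ranges <- list(
  PC = c(28, 44), LPC = c(14, 22), PG = c(28, 44), PI = c(30, 44),
  TG = c(42, 60), DG = c(28, 44), Cer = c(14, 26)
)

.reference_smiles <- list(
  positive = "CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C",  # cholesterol backbone
  negative = "OCC(O)COC(=O)CCCCCCCCCCCCCCCC"                    # monoacylglycerol 17:0
)

#' Configure a synthetic lipidomics study
#'
#' Defaults emulate the structure of a multi-level spiked calibration
#' experiment: a six-level calibrant ladder with the dilution ratios
#' 1:500, 1:200, 1:67, 1:33, 1:17, 1:10 (top:bottom concentration ratio 50),
#' per-lipid sensitivities that follow a smooth function of molecular
#' descriptors plus a lipid-class offset and within-class lognormal spread,
#' 5% multiplicative lognormal area noise, and a small concentration-
#' independent blank background.
#'
#' @param classes Lipid classes per ion mode (named list). Defaults:
#'   positive PC/LPC/TG/DG, negative PG/PI/Cer.
#' @param lipids_per_class Lipids generated per class (default 8).
#' @param chain_ranges Named list of total-acyl-carbon ranges per class.
#' @param n_levels Calibration levels (default 6).
#' @param dilution_factors Dilution of the stock at each level (level 1
#'   first).
#' @param base_conc Stock concentration scale (arbitrary units, default
#'   100; level concentrations are `base_conc / dilution_factors` times a
#'   per-lipid lognormal stock factor).
#' @param stock_sd Lognormal sd of the per-lipid stock factor (default 0.3).
#' @param descriptor_weights Named weights of the sensitivity law on
#'   z-scored descriptors (default on size, unsaturation and a Geary
#'   electronegativity autocorrelation term).
#' @param class_offset_sd Sd of per-class log-sensitivity offsets (default
#'   0.5).
#' @param within_class_sd Within-class log-sensitivity spread (default 0.1).
#' @param noise_sd Lognormal sd of multiplicative area noise (default 0.05).
#' @param blank_frac Blank background as a fraction of each lipid's level-1
#'   signal (default 0.05).
#' @param matrix_effect_sd Lognormal sd of per-lipid matrix
#'   enhancement/suppression factors (default 0: all factors 1; the
#'   reference standard's factor is always 1).
#' @param n_replicates Calibrant replicates per level (default 1).
#' @param n_blanks Blank samples (default 3).
#' @param n_neat Neat (non-matrix) spike samples for recovery (default 0).
#' @param neat_level Calibration level at which neat samples are spiked.
#' @param saturating_ids Lipids whose top-level response saturates.
#' @param saturation_factor Top-level response of a saturating lipid,
#'   relative to its level-`L-1` response (default 0.6, emulating
#'   ionization suppression past the linear range).
#' @param m_ref_abs Absolute sensitivity of the reference standard (area
#'   units per concentration unit, default 1e5).
#' @param seed Master seed for all generator randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(classes = list(positive = c("PC", "LPC", "TG", "DG"),
                                      negative = c("PG", "PI", "Cer")),
                       lipids_per_class = 8,
                       chain_ranges = .default_chain_ranges,
                       n_levels = 6,
                       dilution_factors = c(500, 200, 67, 33, 17, 10),
                       base_conc = 100, stock_sd = 0.3,
                       descriptor_weights = c(MW = -0.7, nDouble = 0.25,
                                              GATS4se = 0.4),
                       class_offset_sd = 0.5, within_class_sd = 0.1,
                       noise_sd = 0.05, blank_frac = 0.05,
                       matrix_effect_sd = 0,
                       n_replicates = 1, n_blanks = 3,
                       n_neat = 0, neat_level = 4,
                       saturating_ids = character(0),
                       saturation_factor = 0.6,
                       m_ref_abs = 1e5, seed = 1) {
  abort_if(length(dilution_factors) != n_levels,
           "need one dilution factor per level")
  abort_if(any(diff(dilution_factors) >= 0),
           "dilution factors must decrease (concentrations increase)")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic lipid panel
#'
#' Builds homologous series of programmatic SMILES for each configured
#' class (total acyl carbons spread evenly over the class's range,
#' double-bond counts cycling 0..3), assigns each lipid a spiked
#' concentration ladder `stock / dilution_factors`, and appends the
#' mode-specific reference internal standard. All SMILES are validated by
#' [parse_panel()].
#'
#' @param cfg A `sim_config`.
#' @param mode Ion mode to generate (default `"positive"`).
#' @return A `lipid_panel`.
#' @export
generate_panel <- function(cfg, mode = "positive") {
  classes <- cfg$classes[[mode]]
  abort_if(is.null(classes), "no classes configured for mode ", mode)
  rows <- list()
  for (cl in classes) {
    rng <- cfg$chain_ranges[[cl]]
    abort_if(is.null(rng), "no chain range for class ", cl)
    totals <- unique(round(seq(rng[1], rng[2], length.out = cfg$lipids_per_class)))
    for (i in seq_along(totals)) {
      db <- (i - 1) %% 4
      nm <- paste0(cl, " ", totals[i], ":", db)
      rows[[length(rows) + 1]] <- data.frame(
        lipid_id = paste0(cl, "_", totals[i], "_", db), name = nm,
        lipid_class = cl, smiles = lipid_smiles(cl, totals[i], db),
        ion_mode = mode, is_reference_standard = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ref_cl <- if (mode == "positive") "CHOL" else "MG"
  rows[[length(rows) + 1]] <- data.frame(
    lipid_id = paste0(ref_cl, "_ref"), name = paste0(ref_cl, " reference"),
    lipid_class = ref_cl, smiles = .reference_smiles[[mode]],
    ion_mode = mode, is_reference_standard = TRUE, stringsAsFactors = FALSE)
  df <- do.call(rbind, rows)
  stocks <- with_seed(cfg$seed, cfg$base_conc * exp(rnorm(nrow(df), 0, cfg$stock_sd)))
  conc <- outer(stocks, cfg$dilution_factors, "/")
  colnames(conc) <- paste0("level_", seq_len(cfg$n_levels))
  parse_panel(cbind(df, as.data.frame(conc)))
}

#' Generate ground-truth relative sensitivities
#'
#' The log relative sensitivity of each lipid is a weighted sum of z-scored
#' molecular descriptors plus a per-class offset and a within-class normal
#' spread; the vector is renormalized so that the reference standard's
#' `m_R` is exactly 1.
#'
#' @param panel A `lipid_panel`.
#' @param descriptors Cleaned `descriptor_matrix` covering the panel.
#' @param cfg A `sim_config`.
#' @return Named vector of true `m_R` values (> 0).
#' @export
generate_ground_truth_mR <- function(panel, descriptors, cfg) {
  ids <- panel$lipid_id
  abort_if(!all(ids %in% rownames(descriptors)),
           "descriptors missing for some panel lipids")
  w <- cfg$descriptor_weights[names(cfg$descriptor_weights) %in%
                                colnames(descriptors)]
  abort_if(length(w) == 0, "none of the weighted descriptors survive cleaning")
  Xz <- scale(descriptors[ids, names(w), drop = FALSE])
  Xz[is.nan(Xz)] <- 0
  classes <- unique(panel$lipid_class)
  log_mR <- with_seed(cfg$seed + 1L, {
    offsets <- setNames(rnorm(length(classes), 0, cfg$class_offset_sd), classes)
    as.numeric(Xz %*% w) + offsets[panel$lipid_class] +
      rnorm(length(ids), 0, cfg$within_class_sd)
  })
  mR <- exp(log_mR)
  ref <- ids[panel$is_reference_standard]
  mR <- mR / mR[match(ref, ids)]
  setNames(mR, ids)
}

#' Generate a noisy response table
#'
#' Peak areas follow the linear concentration-response regime:
#' `area = m_R * m_ref_abs * conc + blank`, times multiplicative lognormal
#' noise and a per-lipid matrix factor. Blank samples carry the
#' concentration-independent background only. Lipids listed in
#' `cfg$saturating_ids` respond linearly up to level `L-1` and sag to
#' `saturation_factor` of the level-`L-1` response at the top level. Neat
#' spike samples (for recovery) omit the matrix factor.
#'
#' @param panel A `lipid_panel`.
#' @param true_mR Named vector from [generate_ground_truth_mR()].
#' @param cfg A `sim_config`.
#' @param mode Ion mode.
#' @return A `response_table`.
#' @export
generate_responses <- function(panel, true_mR, cfg, mode = "positive") {
  sub <- panel[panel$ion_mode == mode, ]
  L <- cfg$n_levels
  conc <- as.matrix(sub[, paste0("level_", seq_len(L))])
  ids <- sub$lipid_id
  m_abs <- true_mR[ids] * cfg$m_ref_abs
  # exogenous deuterated reference standard: no endogenous blank background
  blank_base <- cfg$blank_frac * m_abs * conc[, 1]
  blank_base[sub$is_reference_standard] <- 0

  samples <- data.frame(
    sample_id = c(paste0("cal_L", rep(seq_len(L), each = cfg$n_replicates),
                         "_r", rep(seq_len(cfg$n_replicates), L)),
                  if (cfg$n_blanks > 0) paste0("blank_", seq_len(cfg$n_blanks)),
                  if (cfg$n_neat > 0) paste0("neat_", seq_len(cfg$n_neat))),
    role = c(rep("calibrant", L * cfg$n_replicates),
             rep("blank", cfg$n_blanks), rep("neat_spike", cfg$n_neat)),
    calibration_level = c(rep(seq_len(L), each = cfg$n_replicates),
                          rep(NA_integer_, cfg$n_blanks),
                          rep(cfg$neat_level, cfg$n_neat)),
    stringsAsFactors = FALSE)
  samples$ion_mode <- mode

  areas <- with_seed(cfg$seed + 2L, {
    mf <- exp(rnorm(length(ids), 0, cfg$matrix_effect_sd))
    mf[sub$is_reference_standard] <- 1
    names(mf) <- ids
    rows <- vector("list", nrow(samples) * length(ids))
    k <- 0L
    for (si in seq_len(nrow(samples))) {
      role <- samples$role[si]
      lev <- samples$calibration_level[si]
      for (li in seq_along(ids)) {
        signal <- if (role == "blank") 0 else {
          cl <- conc[li, lev]
          if (ids[li] %in% cfg$saturating_ids && lev == L) {
            cfg$saturation_factor * m_abs[li] * conc[li, L - 1L]
          } else m_abs[li] * cl
        }
        mu <- signal + blank_base[li]
        noise <- exp(rnorm(1, 0, cfg$noise_sd))
        fac <- if (role == "neat_spike") 1 else mf[li]
        k <- k + 1L
        rows[[k]] <- data.frame(sample_id = samples$sample_id[si],
                                lipid_id = ids[li],
                                area = mu * noise * fac,
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  response_table(samples, areas)
}

#' Run the full synthetic study generator
#'
#' Panel, descriptors (computed and cleaned), ground-truth sensitivities
#' and responses in one call.
#'
#' @inheritParams generate_responses
#' @return List with `panel`, `descriptors`, `true_mR`, `responses`, `cfg`.
#' @export
simulate_study <- function(cfg = sim_config(), mode = "positive") {
  panel <- generate_panel(cfg, mode)
  desc <- clean_descriptors(compute_descriptors(panel))
  true_mR <- generate_ground_truth_mR(panel, desc, cfg)
  responses <- generate_responses(panel, true_mR, cfg, mode)
  list(panel = panel, descriptors = desc, true_mR = true_mR,
       responses = responses, cfg = cfg)
}

#' Simulate a descriptor-only regression study
#'
#' A lightweight generator for model-level validation: `n` lipids with `p`
#' standard-normal descriptors of which `k_informative` determine the log
#' relative sensitivity (monotone law with geometrically decaying weights),
#' observed with multiplicative lognormal noise.
#'
#' @param n Lipids (default 60).
#' @param p Descriptors (default 200).
#' @param k_informative Informative descriptors (default 5).
#' @param noise_sd Lognormal sd of the observation noise (default 0.05,
#'   i.e. about 5% multiplicative noise).
#' @param seed Seed.
#' @return List with `X`, `y` (noisy), `y_true` (noise-free), and
#'   `informative` descriptor names.
#' @export
simulate_descriptor_study <- function(n = 60, p = 200, k_informative = 5,
                                      noise_sd = 0.05, seed = 1) {
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("lipid_", seq_len(n)),
                                paste0("d", seq_len(p))))
    w <- 0.5 * 0.75^(seq_len(k_informative) - 1)
    y_true <- exp(as.numeric(X[, seq_len(k_informative), drop = FALSE] %*% w))
    y <- y_true * exp(rnorm(n, 0, noise_sd))
    list(X = X, y = setNames(y, rownames(X)),
         y_true = setNames(y_true, rownames(X)),
         informative = colnames(X)[seq_len(k_informative)])
  })
}
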