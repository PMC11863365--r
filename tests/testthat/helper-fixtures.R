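# Shared fixtures. Expensive objects (descriptor matrices from SMILES) are
# built lazily and cached for the session, since descriptors are a pure
# function of the structures.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small positive-mode synthetic study (33 lipids incl. reference) used by
# many tests; descriptors computed once.
small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(seed = seed, ...)
  key <- "desc_positive_default"
  panel <- generate_panel(cfg, "positive")
  desc <- cached(key, clean_descriptors(compute_descriptors(panel)))
  true_mR <- generate_ground_truth_mR(panel, desc, cfg)
  responses <- generate_responses(panel, true_mR, cfg, "positive")
  list(panel = panel, descriptors = desc, true_mR = true_mR,
       responses = responses, cfg = cfg)
}

# A tiny manual panel data.frame (valid but minimal molecules).
toy_panel_df <- function() {
  data.frame(
    lipid_id = c("A", "B", "R"),
    lipid_class = c("PC", "PC", "CHOL"),
    smiles = c("CCO", "CCCO", "CC(C)O"),
    ion_mode = "positive",
    is_reference_standard = c(FALSE, FALSE, TRUE),
    level_1 = c(1, 2, 1), level_2 = c(2, 4, 2), level_3 = c(4, 8, 4),
    level_4 = c(8, 16, 8), level_5 = c(16, 32, 16), level_6 = c(32, 64, 32),
    stringsAsFactors = FALSE
  )
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

r2_of <- function(truth, pred) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}
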