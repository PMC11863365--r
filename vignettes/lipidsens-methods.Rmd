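---
title: "Predicting electrospray ionization sensitivity for semiquantitative lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electrospray ionization sensitivity for semiquantitative lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Electrospray ionization response differs by orders of magnitude between
lipids and drifts between instrument batches, so nontargeted LC-MS peak
areas are not concentrations. `lipidsens` models a lipid's *relative
sensitivity*

$$ m_R = \frac{m}{m_\mathrm{ref}}, $$

the ratio of its external calibration slope $m$ (area per concentration
unit, ordinary least squares over the spiked calibrant ladder) to the slope
of a mode-specific deuterated reference internal standard. Ratioing removes
instrument gain and injection-to-injection response drift: `m_R` is
dimensionless and, as the package asserts to $10^{-12}$, invariant to any
common rescaling of the areas.

`m_R` is then regressed on 2D molecular descriptors of the structure, on
the premise that ionization efficiency is controlled by the head-group
chemistry and acyl-chain geometry, both of which are encoded in how atomic
properties (electronegativity, polarizability, mass, ...) are distributed
over the molecular graph. Once a model is trained, any lipid with a known
structure can be quantified from its peak area via

$$ \hat c \;=\; \frac{y/A_\mathrm{ref} - b/A_\mathrm{ref}}{\hat m_R}\; c_\mathrm{ref}, $$

where $y$ is the analyte area in the sample, $b$ its area in the blank,
$A_\mathrm{ref}$ the reference standard's area in the same sample and
$c_\mathrm{ref}$ its spiked concentration. Only area *ratios* enter. The
display form of this inversion is one of several algebraically equivalent
readings of "relativize, blank-subtract, divide by sensitivity"; the one
implemented is the one that makes the noise-free roundtrip exact, which the
test suite verifies to $10^{-9}$ relative error. Negative estimates (blank
above signal) are floored at zero and flagged rather than propagated.

### Assumptions

* response is linear in concentration over the retained calibration levels;
* the blank background is concentration-independent;
* the reference standard is detected in every sample with positive area,
  and has no endogenous background (it is an exogenous labeled compound);
* `m_R` is strictly positive — enforced upstream by the calibration filters,
  and required by the Box-Cox transform.

## Calibration

Per lipid, areas are averaged per calibration level and fitted by OLS
*with* intercept (the intercept absorbs residual background; the blank term
of the inversion formula is handled separately). Filters:

* fewer than 3 usable levels → `excluded_missing`;
* slope ≤ 0 → `excluded_nonpositive_slope` (a non-positive sensitivity is
  physically meaningless and would break the Box-Cox step);
* R² < 0.8 → `excluded_linearity`.

The **top calibration level is dropped by default** (`apply_level_policy`,
policy `drop_top`): the highest calibrant of a 50-fold dilution ladder
commonly saturates the ESI response, and a lipid that is perfectly linear
below the top level should not be discarded for it. The policy is
configurable (`none`, `drop_top_k`); the test suite constructs a saturating
lipid that is excluded exactly when the top level is kept.

Relativization is performed on *slopes* (`m_R = m_i / m_ref`) rather than on
per-sample response ratios. The two coincide when the reference area is
proportional to its spiked concentration; the slope ratio is more robust to
a noisy reference in any single sample. Blank subtraction before fitting is
available (`blank_subtract`) but off by default, since the intercept already
absorbs constant background. Curves are unweighted; a 1/x weighting was
considered and rejected as an extra tunable without a driving use case
here.

## Molecular descriptors

Descriptors are computed in-package from the hydrogen-suppressed molecular
graph (SMILES parsed by OpenBabel through `ChemmineR`/`ChemmineOB`):

* constitutional counts (atoms by element, bonds, rings, hydrogens,
  molecular weight),
* classical topological indices (Wiener, Zagreb, diameter, mean distance),
* autocorrelation families at topological lags 1–8: Moreau–Broto (`ATS`,
  `AATS`), centered (`ATSC`, `AATSC`), Moran (`MATS`) and Geary (`GATS`),
  each weighted by eleven atomic properties — atomic number, mass, van der
  Waals volume, Sanderson/Pauling/Allred–Rochow electronegativity,
  polarizability, first ionization energy, valence-electron count
  (Kier–Hall $\delta^v = Z^v - n_H - q$), degree, and intrinsic state
  $((2/L)^2\delta^v + 1)/\delta$.

Names follow the field's convention (`GATS6se` = Geary autocorrelation,
lag 6, Sanderson electronegativity). The Geary family is validated in the
test suite against a direct implementation of the textbook formula on path
graphs. Only 2D descriptors are computed — no conformer generation — so
descriptor computation is bitwise deterministic and a pure function of the
SMILES. Deuterium labels in standards may be written as the unlabeled
backbone: label positions negligibly affect 2D descriptors.

A lag longer than a molecule's topological diameter has no atom pairs and
yields `NA`; `clean_descriptors()` drops any column containing a missing or
non-finite value and any zero-variance column, records what it dropped, and
is idempotent. Cleaning is this package's own rule: SVR and RFE require a
finite, informative matrix, and column-wise removal keeps the cleaned
matrix a function of the panel alone.

## The regression workflow

Each training iteration (`train_sensitivity_model`):

1. random split, 80% training / 20% held-out (the operating ratio; the
   `learning_curve()` helper reproduces the split-fraction diagnostic that
   motivates it);
2. Box-Cox transform of the training `m_R` (λ by maximizing the profile
   log-likelihood with golden-section search on [−2, 2]; cross-checked
   against the `MASS::boxcox` grid in the tests). `m_R` spans decades and is
   right-skewed; the transform prevents the few most ionizable lipids from
   dominating the loss;
3. descriptor standardization using means/SDs of the *training rows only*
   (the tests mutate a held-out row and assert the scaler is unchanged);
4. SVM-RFE: a linear-kernel SVR ranks features by $|w|$, the worst 25% are
   dropped per step down to a floor of 4, and the candidate subset with the
   lowest 5-fold CV MAE is kept. The RBF kernel exposes no feature weights,
   so ranking uses the linear surrogate while the final model is refit with
   the tuned kernel — standard SVM-RFE practice. An RFE that selects
   nothing falls back to all features with a warning;
5. SVR hyperparameters by 5-fold CV over a small log grid (RBF: cost ∈
   {1, 10, 100} × γ ∈ {0.3, 1, 3}/p × ε ∈ {0.1, 0.01}; linear: cost ∈
   {1, 10} × ε ∈ {0.1, 0.01}). ε = 0.01 matters: an insensitivity tube
   wider than the target noise forces underfitting;
6. held-out metrics on back-transformed predictions (mean absolute error of
   `m_R`, MdAPE, mean APE).

`run_ensemble()` repeats this over `n_iterations` random splits (default
1101, matching the intended production setting; iteration *i* uses seed
`base_seed + i` so any iteration is reproducible in isolation) and selects
the **median-error model** — the model whose held-out mean absolute `m_R`
error is the median of the iteration errors. With a small panel, a single
lucky or unlucky split materially changes the model; the median of many
splits is a stable, honest representative. Conventions fixed here because
no external convention exists: even iteration counts take the *lower*
median; error ties resolve to the lower seed; the selection metric defaults
to mean absolute error in `m_R` and can be switched to MdAPE.

Full determinism under a fixed base seed — identical selected model and
bit-identical predictions across runs — is asserted by the test suite with
51-iteration ensembles.

Out-of-domain inverse Box-Cox inputs ($\lambda z + 1 \le 0$, possible when
the regressor extrapolates) are clamped to $10^{-12}$ so predicted
sensitivities stay finite and positive.

## Baselines

* **One-point calibration**: the analyte inherits the raw-area response
  factor of the single most structurally similar same-class standard —
  same head group (mandatory), then closest total acyl carbons, then
  closest double-bond count, residual ties to the lexicographically
  smallest identifier (logged, deterministic).
* **Class curve**: one OLS line pooled over all same-class standards and
  all calibrant levels (blank-corrected); the analyte's concentration is
  its blank-corrected area divided by the class slope. A class with a
  single member falls back to one-point with a warning.

## Validation battery

`percent_error_summary()` reports per-lipid mean absolute percent error,
the global mean of those, the MdAPE over rows, and precision — the mean
over lipids of the CV of predicted concentrations across replicate samples
(pass `replicate_groups` when the samples span different spike levels).
The outlier rule is explicit and fixed: a lipid is flagged when its mean
APE exceeds the median + 3·MAD of the per-lipid errors (no flagging below
5 lipids); both with- and without-outlier summaries are always reported so
no conclusion depends on the rule. `holdout_by_class()` and
`holdout_by_size()` report the out-of-sample R² of predicted vs true `m_R`
in original (back-transformed) space — out-of-sample R² can be strongly
negative, which is precisely the diagnostic signal for a class the model
has never seen. `recovery()` is the matrix/neat area ratio, with values
above 100% flagged as ionization enhancement.

## The synthetic-data generator

`sim_config()`/`simulate_study()` emulate a spiked multi-level calibration
experiment:

* programmatic, valence-correct SMILES for homologous series of PC, LPC,
  TG, DG (positive mode) and PG, PI, Cer (negative mode), ester-linked
  saturated/unsaturated acyl chains (no plasmalogens or ether lipids), plus
  a cholesterol-backbone reference in positive and a monoacylglycerol
  reference in negative mode;
* a six-level ladder with dilution factors 500, 200, 67, 33, 17, 10 —
  a 50-fold span with geometric-like spacing, matching common commercial
  calibrant schemes — and per-lipid lognormal stock factors (sd 0.3);
* ground truth $\log m_R = X_z w + \text{class offset} +
  \mathcal N(0, \sigma_{wc})$: a smooth descriptor law (defaults weight
  molecular weight, double-bond count and a lag-4 Geary electronegativity
  term), class-level structure (offset sd 0.5), and within-class spread
  ($\sigma_{wc}$ = 0.1 by default), renormalized so the reference's
  `m_R` is exactly 1;
* areas $= m_R\, m_\mathrm{ref}\, c + \text{blank}$, times multiplicative
  lognormal noise (sd 0.05 — a typical LC-MS area CV) and a per-lipid
  matrix factor (off by default; the reference's factor is always 1).
  Blanks carry the background only; the reference has zero background.
  Areas are positive and CV-stable under this noise model, which is why
  it is multiplicative lognormal rather than additive;
* optional saturating lipids: linear through level L−1, sagging to 60% of
  the level-(L−1) response at the top level — emulating ionization
  suppression past the linear range, strong enough to fail the R² ≥ 0.8
  filter only when the top level is kept;
* optional neat (non-matrix) spike samples for recovery.

`simulate_descriptor_study()` is the model-level generator: *n* = 60
lipids, *p* = 200 standard-normal descriptors of which 5 drive
$\log m_R$ with geometrically decaying weights, observed with 5%
multiplicative noise — the sparse-recovery setting under which the
workflow is expected to reach low held-out error and high R² against the
noise-free truth.

**The high within-class-spread comparison condition**
(`method_ordering_study()`): 10 lipids per class, a strong chain-length
dependence (weight −0.8 on molecular weight), within-class random spread
0.35, matrix-effect sd 0.2, stock sd 0.15, both ion modes pooled, and the
middle four members of each class held out as analytes so the nearest
surrogate is several chain carbons away. This mirrors the regime that
motivates model-based quantitation: the single-surrogate transfer pays for
*two* random draws (its own and the analyte's deviation) plus the
structural gap; the pooled class curve averages random spread but carries
the class-mean bias; the model carries neither systematic term. Mean
percent errors over 20 replicate studies are compared in the acceptance
suite.

What the generator does *not* emulate: retention-time behavior and
coelution, in-source fragmentation, adduct distributions, integration
errors, inter-batch drift, and real descriptor–efficiency laws (the true
law here is by construction within the descriptor span). Passing tests
therefore demonstrate correctness and internal consistency of the
workflow, not field accuracy on real extracts.

## Problem sizes and budgets

Test and acceptance runs use panel sizes of 30–70 lipids, 200–550
descriptors after cleaning, ensembles of 25–51 iterations, and 5–20
replicate studies per stochastic assertion — large enough for the
qualitative orderings to be stable under the fixed seeds, small enough to
keep a full check of the package in the minutes range on a single core.
The production-scale default of 1101 iterations is a configuration value,
not exercised by the tests.

## Known limitations

* Descriptor coverage is the classical 2D set; charge-state-aware or 3D
  descriptors are out of scope.
* RBF-kernel SVR extrapolates toward a constant far outside the training
  descriptor range; extreme-size hold-outs remain accurate near the range
  boundary but degrade further out (the linear kernel, which is in the
  tuning grid, extrapolates better and is often selected in such runs).
* The one-point/class-curve/model error ordering is a property of the
  simulated high-spread regime, asserted over replicate means; individual
  studies can deviate.
* A model transfers only within the instrument/method that produced its
  calibration slopes; cross-instrument transfer is a non-goal.
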