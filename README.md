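# lipidsens

Semiquantitative lipidomics by machine-learning prediction of electrospray
ionization (ESI) sensitivity.

## The problem

Nontargeted LC-MS lipidomics measures peak areas, not concentrations: each
lipid ionizes with its own efficiency, so areas are not comparable across
lipids or across instrument batches. Targeted quantitation fixes this with
matched stable-isotope standards, which exist for only a handful of lipids.
`lipidsens` takes the middle road: it *learns* the relative ESI sensitivity
of a lipid from its structure, so that any lipid with a known structure can
be quantified — approximately — without its own standard.

The core quantity is the **relative sensitivity**

```
m_R(i) = m(i) / m(ref)
```

where `m(i)` is the slope of lipid *i*'s external calibration line
(peak area vs spiked concentration, ordinary least squares, linearity
filter R² ≥ 0.8, top calibration level dropped by default) and `m(ref)` is
the slope of a mode-specific reference internal standard (a cholesterol-type
standard in positive mode, a monoacylglycerol in negative mode). `m_R` is
unitless and invariant to instrument gain.

`m_R` is predicted from 2D molecular descriptors computed from the lipid's
SMILES: constitutional counts, topological indices, and Moreau-Broto /
Moran / Geary autocorrelation families (`ATS*`, `MATS*`, `GATS*`) over
topological lags 1–8, weighted by atomic mass, van der Waals volume,
electronegativities, polarizability, ionization energy, valence electrons
and intrinsic state. The regression workflow is:

1. **Box-Cox** transform of the `m_R` target (maximum-likelihood λ),
2. descriptor standardization (training rows only),
3. **recursive feature elimination** with a linear-SVR ranker,
4. **support vector regression** tuned by 5-fold cross-validation,
5. repeated over many random 80:20 train/test splits (default 1101
   iterations), keeping the **median-error model**.

Concentrations then follow from the inverted response model

```
conc = ( y/A_ref − b/A_ref ) / m_R × c_ref
```

with `y` the analyte peak area in the sample, `b` its area in the blank,
`A_ref` the reference standard's area in that sample and `c_ref` the
reference's spiked concentration. Two classical surrogate-standard
baselines (one-point response factor; pooled lipid-class calibration
curve) are implemented for comparison, together with a validation battery
(percent-error and precision summaries, an explicit outlier rule,
leave-class-out and extreme-size hold-outs, spike recovery) and a
synthetic-study generator that emulates spiked multi-level calibration
experiments end to end.

## Worked example

```r
library(lipidsens)

# a synthetic spiked-calibration study: 33 positive-mode lipids
# (PC/LPC/TG/DG + reference), 6 calibrant levels, 5% area noise
sim <- simulate_study(sim_config(seed = 1), mode = "positive")

cal <- calibrate_panel(sim$panel, sim$responses, "positive")
table(cal$status)
#> included
#>       33

tt  <- build_training_table(cal, sim$descriptors)
ens <- run_ensemble(tt$X, tt$y, n_iterations = 51, base_seed = 0)
ens$selected_model
#> <sensitivity_model> seed 2; 26 train / 7 test lipids
#>   Box-Cox lambda: -0.02759; RFE: 269 descriptors
#>   kernel linear, cost 1; held-out MdAPE 18.93%

mR_hat <- predict_mR(ens$selected_model,
                     sim$descriptors[ens$selected_model$test_ids, ])
q <- quantify_samples(sim$responses, sim$panel, mR_hat, "positive")
percent_error_summary(q)
#> <validation_report> 7 lipids
#>   global mean error: 14.99% (14.99% with outliers removed: none)
#>   MdAPE: 14.67%; precision (mean CV): 109.3%
```

The seven held-out lipids are quantified from their predicted
sensitivities with a ~15% mean error (noise-free inversion is exact;
error grows with area noise, within-class sensitivity spread and matrix
effects). The large "precision" here is expected: these samples are the
calibrant ladder itself, whose spiked concentrations span a 50-fold
range — pass `replicate_groups` to `percent_error_summary()` to compute
the CV within replicate groups instead (see the methods vignette).

A thin command-line wrapper over the same functions is provided in
`inst/cli/lipidsens.R` with `simulate`, `calibrate`, `train` and
`quantify` subcommands.

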