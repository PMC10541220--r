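# perfrad

Temporal radiomics for detecting per-territory myocardial perfusion
defects in stress/rest first-pass cardiac MR perfusion sequences.

## The problem

First-pass perfusion CMR images the left ventricle once per cardiac
cycle while a gadolinium bolus transits the heart, under
pharmacological stress and at rest. A flow-limiting coronary stenosis
produces a myocardial region that enhances less — and later — than its
neighbours, but only under stress (inducible ischaemia). Visual reads
of such sequences are specific but insensitive; `perfrad` implements a
quantitative pipeline for researchers working on perfusion analysis:

1. each short-axis slice's myocardium is split into the three coronary
   territories (LAD, LCX, RCA) by the AHA angular convention;
2. 35 radiomic features — 19 first-order and 16 gray-level size zone
   matrix (GLSZM) texture features — are computed per territory on
   every frame of the AIF-cropped first-pass window, giving temporal
   *feature sequences* (interpolated to 10 timesteps);
3. stress and rest sequences are subtracted (the delta isolates the
   inducible component), min–max scaled across training subjects, and
   converted to 8-bin histograms, which discard the temporal ordering
   and with it inter-subject bolus misalignment;
4. the resulting per-territory vectors of
   35 features × 8 bins × 3 slices = **840** entries are classified by
   a balanced random forest (each tree trains on a class-balanced
   bootstrap) under nested, subject-grouped, stratified
   cross-validation, with the decision threshold calibrated on inner
   validation folds to match a target specificity (default 0.84);
   a patient is called positive if any territory is.

Because clinical perfusion data are rarely shareable, the package
includes a synthetic phantom generator (`phantom_config()`,
`generate_cohort()`): gamma-variate first-pass kinetics, annular
myocardium with central blood pool, stress-only territory defects, and
a configurable cohort (default 92 subjects at 42% patient prevalence).
Every pipeline stage is tested against it, and GLSZM/first-order
features are verified against independent naive-formula oracles.

See `vignettes/temporal-perfusion-radiomics.Rmd` for the full method
description, parameter semantics, and design rationale.

## Worked example

```r
library(perfrad)

cfg <- phantom_config(n_subjects = 30, seed = 3)   # small phantom cohort
deltas <- extract_cohort_deltas(config = cfg)       # 90 x 1050 delta table
cc <- cv_config(n_outer_folds = 3, n_inner_folds = 5,
                max_selected_features = 4, screen_size = 20,
                sfs_num_trees = 30, seed = 5,
                grid = data.frame(num_trees = 100L, max_depth = 0L,
                                  mtry = NA_integer_))
cv <- nested_cv(deltas, cc)
cat("patient sensitivity:", round(cv$sensitivity, 3), "\n")
cat("patient specificity:", round(cv$specificity, 3), "\n")
head(feature_ranking(cv), 3)
```

prints

```
patient sensitivity: 1
patient specificity: 1
                 feature frequency
1              fo_energy         3
2             fo_entropy         0
3 fo_interquartile_range         0
```

At the default defect strength (stress amplitude reduced to 0.4 of
normal) and noise level the phantom is cleanly separable, so the
nested cross-validation recovers every patient: sensitivity and
specificity are the fraction of out-of-fold positive/negative patients
called correctly at the calibrated threshold. The ranking shows which
base feature types were selected in how many outer folds (here
first-order energy, whose delta histogram shifts when a territory
hypo-enhances under stress). Harder settings — weaker defects, more
noise — degrade these numbers smoothly, which is what the package's
permutation-null and recovery checks quantify.

A command-line front end wrapping the same functions is installed at
`inst/cli/perfrad.R` with subcommands `simulate`, `extract`,
`evaluate`, `run-all` and `report` (NIfTI cohort layout, feature CSVs,
JSON/markdown reports).

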