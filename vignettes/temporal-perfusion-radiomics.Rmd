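---
title: "Temporal radiomics for stress/rest perfusion CMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal radiomics for stress/rest perfusion CMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfrad)
```

## The problem

First-pass perfusion cardiac MR acquires a short-axis image of the left
ventricle once per cardiac cycle while a gadolinium bolus transits the
heart, under pharmacological stress and again at rest. A
flow-limiting coronary stenosis shows up as a myocardial region that
enhances less, and later, under stress than its neighbours — but only
under stress (inducible ischaemia). Visual reads of these sequences are
specific but insensitive. `perfrad` implements a quantitative
alternative: temporal radiomics. Instead of comparing single frames, it
tracks a catalogue of texture and intensity statistics *through time*,
contrasts stress against rest, and classifies each coronary territory
(LAD, LCX, RCA) with a machine-learning model evaluated under
leakage-free nested cross-validation.

Clinical perfusion data are rarely shareable, so the package also ships
a synthetic phantom generator that emulates the statistical structure
the pipeline relies on. Every stage of the pipeline is exercised and
tested against that phantom.

## The feature pipeline

For one subject the pipeline runs eight steps per condition
(stress, rest) and slice (basal, mid, apical):

1. The myocardium of each slice is delineated into the three coronary
   territories (see *Territory mapping* below).
2. Each image sequence is min–max normalized *along all timesteps*
   (within the myocardium + blood-pool region), so the contrast-passage
   dynamic is preserved while acquisition scaling is removed.
3. The blood-pool arterial input function (AIF) locates the first-pass
   window; on every frame of that window all 35 catalogue features are
   computed per territory, giving one feature *sequence* per
   (condition, slice, territory, feature).
4. Each sequence is linearly interpolated to 10 timesteps, so that
   per territory there are $35 \times 10 \times 6 = 2{,}100$ values
   (6 = two conditions × three slices).
5. Stress and rest sequences are subtracted elementwise, halving the
   count to $1{,}050$ and yielding 9 delta-sequence groups per subject
   (3 slices × 3 territories).
6. Each (feature, slice, territory, timestep) channel is min–max
   normalized **across training subjects** to $[0,1]$, removing the
   negative values the subtraction introduces.
7. Every scaled 10-step sequence is converted to an 8-bin histogram.
   The histogram discards temporal ordering deliberately: small
   inter-subject misalignments of the bolus no longer matter.
8. Histograms are regrouped per territory and concatenated, giving one
   vector of $35 \times 8 \times 3 = 840$ named features per
   (subject, territory).

The 2,100 → 1,050 → 840 ladder is asserted in the test suite for every
generated subject.

### Fold-aware scaling

Step 6 learns its min/max constants from data. Fitting them on the full
cohort would leak the test subjects' feature ranges into training — a
subtle but real form of contamination. `fit_delta_scaler()` therefore
takes an explicit training-subject list, and `nested_cv()` refits it
inside every outer training fold; test-subject values falling outside
the training range are clipped to $[0,1]$. Cohort-wide fitting remains
available (`assemble_territory_vectors()` with no scaler) for producing
a single feature table outside cross-validation, and is what the
command-line `extract` step uses.

## The feature catalogue

The fixed catalogue holds 19 first-order features (energy, total
energy, entropy, minimum, 10th/90th percentile, maximum, mean, median,
interquartile range, range, mean absolute deviation, robust MAD, RMS,
standard deviation, skewness, kurtosis, variance, uniformity) and 16
gray-level size zone matrix (GLSZM) features (small/large-area
emphasis, gray-level and size-zone non-uniformity and their normalized
variants, zone percentage, gray-level/zone variance, zone entropy, and
the low/high gray-level emphasis family). The GLSZM counts maximal
connected components ("zones") of equal discretized gray level; its
features are the standard double sums over gray level $g$ and zone size
$s$, e.g. small-area emphasis $= \sum_{g,s} P(g,s)/s^2 \,/\, N_z$.

Numerical conventions, chosen once and asserted by oracle tests:

* **Discretization**: 32 equal-width bins over the masked per-frame
  range. The upstream per-sequence normalization makes a fixed bin
  *count* stable across frames; a constant region maps to level 1.
* **Zones**: 8-connectivity (4-connectivity available).
* **Moments**: population variance/SD (divide by $N$); kurtosis is the
  Pearson (non-excess) fourth moment; a zero-variance region returns 0
  for skewness and kurtosis.
* **Total energy** assumes unit pixel area, so it equals energy; this
  keeps features resolution-independent on the phantom grid.
* `prune_correlated()` (greedy removal above an absolute-correlation
  cutoff, catalogue order, constant columns treated as uncorrelated) is
  provided for completeness, but the shipped pipeline uses the fixed
  35-feature catalogue directly: it *is* the post-pruning set, and the
  pre-pruning universe it was derived from is not part of the package.

A zone-matrix implementation detail: the connected-component labelling
is compiled (C++ flood fill) for speed; the test suite re-derives every
zone matrix with an independent pure-R flood fill and every feature
with naive-formula oracles, to $10^{-6}$.

## Territory mapping

The myocardial annulus is split by pixel angle measured
counterclockwise from the right-ventricular insertion ray, following
the AHA segment model collapsed to territories: on basal and mid slices
six 60° sectors with sectors 1–2 → LAD, 3–4 → RCA, 5–6 → LCX; on the
apical slice four 90° sectors with anterior + septal → LAD, inferior →
RCA, lateral → LCX (the apical cap is excluded). Pixels exactly on a
sector edge go to the lower-indexed sector, making the partition exact:
the three masks are disjoint and their union is the input mask, for any
mask shape. The RV insertion angle is an explicit input — the phantom
knows it by construction; real data would need a manual annotation.
Coronary-dominance variants are out of scope.

## AIF cropping

The first-pass window is found on the blood-pool curve: baseline = mean
of the first 3 frames; the peak is the first local maximum exceeding
baseline + 50% of the global enhancement; the window foot is the last
pre-peak frame at or below baseline + 10% of the peak enhancement; the
window end is the first post-peak local minimum *or* the first frame
falling back below the foot threshold, whichever comes first (a pure
gamma-variate decays monotonically and has no interior minimum — the
threshold rule handles that case, while the local-minimum rule cuts
before a recirculation bump). Both ends are widened by a configurable
guard (default 1 frame, i.e. the cycles immediately either side of the
peak support) and clipped to the sequence. A curve with no qualifying
peak raises an error asking for inspection rather than guessing.

## Classification

Territory vectors are classified by a **balanced random forest**: each
tree draws a bootstrap of equal size from both classes (the majority
class is downsampled per tree), and the predicted probability is the
fraction of trees voting positive. This counters the class imbalance a
~42%-prevalence cohort produces at territory level without reweighting.

Evaluation is a **double (nested) grouped cross-validation**:

* Outer: stratified group K-fold over subjects (default K = 5; the
  outer fold count is an evaluation choice, not part of the model).
  All three territories of a subject stay on one side of every split;
  this is asserted programmatically and a violation is a hard error.
* Inner (10-fold, same grouped stratification): greedy sequential
  forward feature selection by mean ROC-AUC of the balanced forest
  (ties to the lowest feature index; selection stops when no candidate
  improves the criterion), then an exhaustive hyperparameter grid
  search (ties to the smaller model).
* Threshold: the inner out-of-fold probabilities are aggregated to
  patients (a patient's score is the max over its three territories)
  and the smallest threshold achieving the target specificity
  (default 0.84, a conventional-reader operating point) is taken.
* The final forest is refit on the outer training fold and applied to
  the held-out territories; a patient is called positive if any
  territory is. Sensitivity and specificity are pooled over outer
  folds at patient level.

AUC was chosen as the selection criterion because it is
threshold-free — the operating threshold is set later, by the
specificity-matching step, and should not influence which features are
picked. Full forward selection over 840 features is quadratic in cost;
`sequential_select()` therefore offers an optional univariate-AUC
screen (`screen_size`) that bounds the candidate pool. The screen sees
only the training data of its fold, so fold isolation is preserved; by
default it is off.

`mcnemar_test()` compares two paired sets of diagnostic calls: the
asymptotic statistic $(b-c)^2/(b+c)$ without continuity correction
against $\chi^2_1$, switching to the exact two-sided binomial when the
discordant count is below 25 (both variants are available explicitly).

All randomness — fold assignment, tree bootstraps, phantom noise —
derives from a single seed through a documented Lehmer-step derivation
(`derive_seed()`), so every stage is independently reproducible.

## The phantom

The generator emulates what the pipeline assumes about real data:

* First-pass kinetics as gamma-variate curves
  $\mathrm{SI}(t) = b + A\,(t-t_0)^\alpha e^{-(t-t_0)/\beta}$, the
  standard single-bolus enhancement model, with the blood pool peaking
  earlier and higher than the myocardium (defaults: AIF $t_0=5$,
  $\alpha=3$, $\beta=1.5$ frames; myocardium $t_0=8$, $\alpha=3$,
  $\beta=2.5$). One frame is one cardiac cycle.
* Stress/rest amplitude difference: the rest myocardial amplitude is
  0.7× the stress one (hyperaemia raises stress inflow).
* Defects are stress-only, full-thickness angular wedges spanning the
  territory sector: amplitude × 0.4 and onset + 2 frames by default.
  Rest carries no defect — this is the inducible-ischaemia signature
  the stress/rest delta is designed to detect.
* Cohort shape: 92 subjects, 42% patient prevalence, positive subjects
  get 1–3 defect territories uniformly. Territory-level prevalence is
  left free (it follows from the patient prevalence and the uniform
  1–3 draw) rather than being pinned separately.
* i.i.d. Gaussian pixel noise, sd 4 SI units by default — roughly 2.4%
  of the blood-pool peak enhancement and 24% of the normal myocardial
  peak enhancement, i.e. a clean but not noiseless acquisition.

What it does **not** emulate — and therefore what passing tests do not
establish about clinical data: cardiac/respiratory motion and breathing
artefact (excluded cases in practice), dark-rim artefact, surface-coil
intensity gradients, coronary anatomy variants, late gadolinium
enhancement, recirculation (available in tests as a constructed
two-bolus curve but off by default), and any realistic coupling between
territory label noise and image appearance. Phantom accuracy figures
are a *recovery* check of the pipeline's machinery, not a forecast of
clinical performance.

## Problem sizes used by the tests and the acceptance script

Unit tests run on reduced phantoms (48-pixel images, 28 frames, 16
subjects) chosen so the whole suite stays interactive. The end-to-end
experiment uses the full default cohort (92 subjects, 64-pixel images,
40 frames) with forward selection capped at 8 features over a
40-candidate screen and a 2×2 hyperparameter grid — sizes at which the
strong-defect phantom is comfortably separable, which is what the
recovery check needs. The label-permutation null uses 20 replicates
with a lighter selection cap (4 features, 25 candidates); chance
behaviour does not depend on model capacity.

## Known limitations

* The per-patient pipeline variant (features pooled without territory
  division) is not implemented; the package is territory-first.
* No DICOM ingestion; NIfTI only, chosen for lossless simplicity.
* `read_features()` accepts any numeric feature block, so externally
  produced tables can be evaluated, but then `nested_cv()` cannot
  refit the delta scaler per fold (the delta stage is unavailable); it
  uses the vectors as-is and the scaling-leakage protection is the
  caller's responsibility.
* The specificity-matched threshold is exact on its calibration set by
  construction but only approximate on new data; with small validation
  sets the realized test specificity can sit noticeably below the
  target.
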