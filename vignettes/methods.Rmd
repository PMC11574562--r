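---
title: "Methods: serum-metabolome multi-cancer detection with metabodetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum-metabolome multi-cancer detection with metabodetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Untargeted serum metabolomics measures thousands of small-molecule
features per sample by LC-MS. A multi-cancer early-detection (MCED)
classifier built on such data must survive the technical structure of the
measurement: per-run mass-calibration drift on the ppm scale, batch-level
intensity shifts, and abundance-dependent dropout, all entangled with the
biological signal of interest — a modest shift in a subset of metabolites
that correlates with the presence of cancer. `metabodetect` implements
the complete workflow from per-run peak lists to a validated RBF-kernel
SVM classifier, together with a ground-truthed cohort simulator so every
stage is testable without instrument data.

The package follows the classic R modelling idiom: `mcd_fit()` is the
single fitting entry point, returning an `mcd_model` with `print()`,
`summary()`, `plot()` and `predict()` methods, while each pipeline stage
is also exposed as a documented function. `run_train()` and
`run_validate()` orchestrate the full workflow with an auditable
manifest; together with `scripts/acceptance.R` they are the package's
operational surface (no shell CLI is shipped — the functions and this
vignette are the interface).

## The synthetic cohort generator

`simulate_library()` builds a mock annotation library: monoisotopic
masses drawn log-uniformly in 70–1200 Da with a minimum pairwise spacing
of 100 ppm, so annotation within a ≤ 40 ppm window is unambiguous by
construction; a configurable fraction of records is flagged as drug-,
plant-derived or of ambiguous origin for the curation filter.

`simulate_cohort()` draws, for each sample and feature,

    log10 intensity = base + batch offset + class effect + N(0, resid_sd)

with the following defaults, chosen as what a practitioner would call a
realistic serum LC-MS cohort where no published value exists (none of the
generator's distributional facts are published — they are stand-ins):

* **Case mix.** 400 cancer samples allocated across the bundled 30-type
  case-mix table (largest-remainder rounding) and 400 controls; stages,
  sexes and age groups are sampled from the bundled study marginals.
* **Signature.** 60 human-origin metabolites carry a class effect of
  0.3 log10 units (alternating sign across the signature) in cancer
  samples, flat across stages by default (`stage_attenuation` all 1,
  reflecting reported near-constant detection across stages; exposed for
  power studies).
* **Technical structure.** 8 acquisition batches with per-batch scalar
  log10 offsets (sd 0.3); per-run mass drift uniform in ±30 ppm;
  residual sd 0.2 (log10); retention-time jitter sd 2 s.
* **Missingness.** A peak is absent — never zero — when its intensity
  falls below its feature's 5% quantile (MNAR) or, independently, with
  probability 0.02 (MCAR). The truth table records the cause per cell.
* **Run-order randomization** is on by default so batches are not
  confounded with class.

What the generator does **not** emulate: chromatographic peak shapes,
isotopologues, multi-adduct chemistry (a single protonation offset is
used), retention-time warping, and instrument-specific noise floors.
Passing tests therefore demonstrate correctness of the pipeline's
contracts under a plausible noise model, not clinical performance on
real serum data.

### Drift designs

Per-run drift is i.i.d. uniform by default. For alignment-recovery
experiments the generator also offers `drift_design = "stratified"`: an
evenly spaced, mean-zero drift grid assigned to runs in random order.
This matters because anchor-based correction can only estimate drift
*relative to the cross-run consensus*; a common offset (the cohort-mean
drift, about 2 ppm sd at 60 runs under the uniform design) is a gauge
freedom no lock-mass scheme can identify without an external calibrant.
The stratified design makes the injected truth identifiable so recovered
and injected drift can be compared directly.

## Virtual-lock-mass alignment

`detect_vlm_anchors()` pools all runs' peaks, clusters them by relative
m/z gaps, and accepts a cluster as an anchor when every matched run
contributes exactly one peak within `ppm_window` of the consensus
(ambiguous windows are discarded) and at least `min_presence` of runs
match. `correct_masses()` divides each peak's m/z by `1 + e(mz)/1e6`,
with `e` piecewise-linear between flanking anchors and constant beyond
the first/last — the simplest scheme that removes run-wise mass shifts.
This is a re-specification of the lock-mass idea, not a reproduction of
any particular published implementation.

Defaults (`ppm_window = 10`, `min_presence = 0.95`, `annotation_ppm =
10`, `rt_tolerance = 30` s) are conventional for high-resolution
instruments. Note that the anchor window must span the drift range in
play: under ±30 ppm drift a ~40 ppm window is required for one
metabolite's peaks to share a window across runs (the 100 ppm library
spacing keeps this unambiguous).

`build_feature_matrix()` annotates each corrected peak to the library
record minimizing absolute ppm difference, subject to the ppm and RT
tolerances; within a run, duplicate annotations resolve to the
higher-intensity peak, and the matrix holds one column per annotated
metabolite (the alternative — one column per (RT, m/z) feature before
name-level deduplication — would give larger matrices; this package
enforces one column per metabolite).

## Preprocessing

The order of operations is fixed: curation filter → prevalence filter →
log10 → quantile normalization → imputation, with normalization before
imputation. Two feature-reduction modes exist because the underlying
procedure is described ambiguously in the literature this design targets
(a "lowest 20% by abundance" rule and a "present in < 20% of samples"
rule with the same claimed output size): the pipeline default is the
prevalence rule (boundary-inclusive at exactly 20% presence), with the
abundance-percentile rule (`floor(k/100 · p)` lowest mean-log10 features
dropped, ties by metabolite id) retained as an option. Neither published
matrix size is treated as reproducible.

### Train-referenced quantile normalization

`fit_quantile_reference()` interpolates each training sample's sorted
observed values onto the common grid `(r − 0.5)/p` and averages across
samples; on complete data this is textbook quantile normalization.
`normalize_quantiles()` maps each sample *independently* onto that
reference — the defining property that lets a single test sample be
normalized without its cohort, and why row-by-row equals whole-matrix
normalization exactly.

Tie handling: tied observed values receive the **mean of the reference
values their ranks span** (the convention used by `limma`-style quantile
normalization). For distinct values this coincides with mapping the
average rank through the reference; for an all-tied sample it yields the
mean of the reference quantiles, which is the behaviour the package
contracts and tests.

## Chained-equations imputation

`fit_mice()` initializes missing cells at feature means, then visits
features in ascending missingness (ties by metabolite id), fitting a
gradient-boosted tree regressor (xgboost; depth 3, 40 rounds, learning
rate 0.3, single-threaded for determinism) of each feature on the
current working values of the others, and overwriting the feature's
missing cells with predictions. Iteration stops at `max_iterations`
(default 5) or earlier when the sum of squared differences between
successive imputations grows — in which case the grown iteration is
**rolled back**, so the recorded convergence trace is non-increasing by
construction. The boosted-tree backend sits behind a four-function
regressor interface (`fit`/`predict`/`save`/`load`), so any conformant
regression backend can be substituted.

Two tractability choices are package design decisions: each regressor
uses only the target's 20 most-correlated partner features as predictors
(in the spirit of `mice::quickpred`; with ~1000 features, all-predictor
fits would dominate runtime for negligible accuracy gain on this data),
and after convergence a frozen regressor is refit per feature on the
completed matrix. Test-time imputation (`impute()`) uses only those
frozen regressors — no refitting — initialized at the stored means and
run for the model's iteration count, which preserves the single-sample
contract: observed cells are untouched bit-for-bit and the output is
complete.

## The classifier

`svm_rbf()` solves the soft-margin dual for the Gaussian kernel
`k(x, x′) = exp(−‖x − x′‖²/2σ²)` with an SMO solver written for this
package (maximal-violating-pair working-set selection on a precomputed
kernel; stop when the KKT violation gap falls below `tol`, default 1e-4;
the intercept is the midpoint of the final violation bounds). The
decision function is the support-vector expansion
`F(x) = Σ αᵢ yᵢ k(x, xᵢ) + b` with cancer encoded +1, so larger y-scores
are more cancer-like. Classification applies a cutoff of zero; a score
*exactly* at the cutoff calls normal (the boundary case is otherwise
undefined in the procedure this follows). The solver's dual objective is
cross-checked in the tests against an independent interior-point QP
solution (`kernlab::ipop`) on a small problem.

`grid_search_svm()` evaluates mean CV accuracy over C ∈ {0.1, 1, 10,
100} × a log2 grid of σ centered on the median pairwise-distance
heuristic, with identical fold assignments for every pair; ties break
toward smaller C then larger σ. Accuracy is the selection metric (the
alternative — selecting on sensitivity or AUC — is a documented open
choice; accuracy was chosen and is reported alongside the full grid
table for audit). `kfold_cv()` reports per-fold sensitivity /
specificity / accuracy at cutoff zero with across-fold means and normal
95% CIs; the pipeline default is 20 folds.

`evaluate_scores()` computes the confusion counts, the three metrics in
percent, AUC by the tie-corrected rank (Mann–Whitney) construction, and
per-group sensitivities (cancer type, stage, age group) with Wilson
score intervals — chosen because they behave sensibly at proportions
near 1, where these sensitivities live.

`rfe_rank()` implements SVM-RFE with the drop-one kernel-weight
criterion: a feature's importance is the change in
`‖w‖² = Σ αᵢαⱼyᵢyⱼ K(xᵢ,xⱼ)` when that feature is removed from the
kernel (for the RBF kernel, removal multiplies each pairwise term by
`exp(+(xᵢf − xⱼf)²/2σ²)`). A constant feature changes no distance and
has exactly zero importance, so it is eliminated before any informative
feature. `step` may be a count or a fraction per round; eliminated
features within a round are ordered by importance, rank 1 is the last
survivor, and a held-out sensitivity trace is recorded per round.

## Pipeline orchestration and leakage control

`run_train()` executes simulate → split → anchor detection (training
runs only) → correction → annotation → `mcd_fit()`, archiving the frozen
artifacts (normalization reference, SVM bundle, CV report, metadata)
with MD5 hashes in a `run_manifest`. The train/validation split is
stratified by class and cancer type, defaulting to the bundled study
proportions (~51% of cancers, ~50% of controls in the training-testing
set); exact counts may be requested instead. `run_validate()` refuses
any sample-id overlap with the training set, then feeds each held-out
run one sample at a time through the frozen artifacts — anchor
correction, log10, single-sample normalization, frozen imputation, SVM
scoring — before subgroup evaluation. Batch and one-at-a-time processing
are exactly equivalent and tested as such.

## Numerical choices and degenerate inputs

* Missingness is always an absent peak (`NA`), never zero; `log10`
  refuses non-positive observed values and double application (a
  provenance check on the transform log).
* Quantile interpolation uses constant extrapolation beyond the grid
  ends; normalization deviation from the reference on complete samples
  is exact to 1e-9.
* The SMO iteration cap scales with n (300·n); degenerate pair updates
  are skipped rather than allowed to stall.
* Anchor detection discards ambiguous windows (two peaks of one run in a
  window) rather than guessing; an empty anchor set leaves the run
  uncorrected with a warning.
* A feature with zero observed training values, an all-missing test
  sample, single-class training labels, and feature-order mismatches are
  hard errors.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script exercise: a 60-run, 150-feature
drifted cohort for alignment recovery; a 150 × 40 correlated matrix with
10% MCAR masking for imputation; and the default 800-sample,
1000-feature cohort (strong-effect and null-effect variants) for
end-to-end recovery, with RFE run at a 10% elimination fraction per
round. These sizes were chosen so the complete experiment suite runs on
a single CPU in minutes while keeping every estimate comfortably away
from its acceptance boundary.

## Known limitations

* The generator's intensity model is log-normal with a shared per-batch
  offset; real batch effects are partly feature-specific and drift
  within batches.
* Single-adduct annotation only; chimeric and isobaric interferences are
  absent by construction (the 100 ppm library spacing).
* The imputation model freezes regressors at train time; a test sample
  whose missingness pattern is far from anything seen in training is
  extrapolation.
* Reported performance on synthetic cohorts says nothing about clinical
  sensitivity/specificity on real serum samples; the published headline
  numbers of the study design this emulates depend on a cohort that is
  not publicly available and are deliberately not treated as
  reproduction targets.
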