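---
title: "Machine-learning-driven data preparation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Machine-learning-driven data preparation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mldprep)
```

## The problem

Small clinical feature tables — tens of patients, tens to hundreds of
numeric features (radiomic descriptors being the canonical case), one binary
endpoint — combine every pathology that hurts off-the-shelf classifiers:
feature counts exceeding sample counts, heavy feature redundancy, class
imbalance, outliers, and borderline cases in the class-overlap region.
Preparation operators that address these (resampling, outlier removal,
feature selection) are standard, but the *composition* — which operators, in
which order, at which settings — is usually chosen by hand, per study, with
the whole dataset in view. That practice is both suboptimal and a leakage
channel.

`mldprep` treats the composition itself as a learning problem: an
evolutionary search over an explicitly restricted space of ordered operator
pipelines, scored only within the training data, selects a preparation
pipeline per training set. The package's harness then measures — rather than
assumes — whether the searched preparation helps a downstream classifier.

## The pipeline space

A pipeline is an ordered list of steps drawn from eight operators:

| id | operator | category | scope |
|----|----------|----------|-------|
| IF | isolation-forest outlier removal | outlier detection | sample space |
| SFS | R²-based sequential forward selection | feature selection | feature space |
| PCA | principal-component projection | dimensionality reduction | feature space |
| RO | random minority oversampling | oversampling | sample space |
| RU | random majority undersampling | undersampling | sample space |
| SMOTE | synthetic minority oversampling | oversampling | sample space |
| BSMOTE | borderline SMOTE | oversampling | sample space |
| TL | Tomek-link purification | undersampling | sample space |

The *scope* column is the load-bearing distinction of the whole design. A
feature-space step learns a transform (selected columns; a centering vector
and loadings) that can legitimately be applied to unseen samples. A
sample-space step edits the training rows; applying it to validation data
would be leakage and is an error in this package.

Validity of a pipeline is defined by a restriction table: a method pool, a
maximum length (default 7), no repetition of a method, unordered method
pairs that may not co-exist, and optional forbidden adjacencies. The default
table forbids only `{SFS, PCA}` — both reshape the feature space, and the
composition of a greedy selector with a projection fitted on its output is
hard to interpret. These defaults are this package's conventions (the
originating study's exact restriction clauses were not published) and are
config-overridable.

All valid pipelines, order permutations included, form the pipeline tree.
Because every restriction clause is hereditary (a prefix of a valid pipeline
is valid), the tree is summarized by its admissible method subsets and
per-depth counts; with the default table it has 25,443 nodes. Sampling draws
a length uniformly over available depths first, then a pipeline uniformly
within that length — node-uniform sampling would make short pipelines
vanishingly rare (40,320 of the nodes have length 7).

## The fitness

A candidate pipeline is scored only inside the training cohort: for each of
`inner_splits` (default 5) stratified 80/20 splits, the full pipeline is
fitted on the inner-training part, its feature-space steps are applied to
the inner-validation part, a fixed-seed surrogate random forest is trained
on the prepared data, and its scores are thresholded at 0.5. The fitness is
the mean ROC distance

$$d = \sqrt{(1-\mathrm{sens})^2 + (1-\mathrm{spec})^2},$$

the Euclidean distance of the operating point from the perfect corner of ROC
space; 0 is perfect, $\sqrt2$ is the always-wrong corner. A pipeline that
empties a class receives $\sqrt2$ (with a warning) rather than an error, so
the search can traverse degenerate regions.

Two deliberate properties of this fitness deserve emphasis:

* **The fixed 0.5 cutoff rewards balance.** Under class imbalance a
  calibrated classifier has low sensitivity at 0.5, so imbalance-correcting
  steps genuinely improve this fitness. That is what makes resampling
  operators competitive in the search — and it mirrors the high SMOTE
  occurrence the motivating study reported. We implemented and measured the
  alternative (distance from the best point of the empirical ROC curve,
  i.e. a ranking criterion): it removes the selection advantage of
  resampling entirely and with it the ability to recover planted
  imbalance/outlier structure, so it was rejected. The consequence —
  operating-point fitness does not optimize AUC — is discussed under
  *Limitations*.
* **Common random numbers.** The inner splits are fixed per search (derived
  from the search seed), so all pipelines are compared on identical splits;
  fitness differences are paired, not confounded with split noise. A cache
  keyed by the pipeline signature (methods + hyperparameters) keeps the
  evaluation budget honest.

## The evolutionary loop

Population 24 (default), tournament selection of size 3 by lower fitness,
one-point crossover with independent cut points, then a repair pass that
drops duplicate methods, forbidden-pair violators and over-length tails —
offspring are valid by construction. With probability `mutation_rate` one
structural mutation (swap/delete/insert an unused method) is applied, and
with probability `hyperparam_mutation_rate` one hyperparameter is redrawn
uniformly within its registry bounds. The two best pipelines are carried
over unchanged (elitism), which makes the best fitness non-increasing per
generation; the search stops after `generations` (default 20) or
`plateau_patience` (default 5) generations without improvement. Ties are
broken toward shorter pipelines, then lexicographically, so results are
deterministic under a fixed seed. All of these settings are declared
conventions — the originating study did not publish its evolutionary
configuration — and every one is a `search_config()` knob.

The hyperparameter registry (bounds in `hyperparam_registry()`) is likewise
a declared convention: IF threshold in [0.5, 0.7] (default 0.55, 100 trees,
subsample 256 capped at n); SFS keeps up to `n_keep` in [2, 30] features
(default 10, stop tolerance 1e-4); PCA retains 80–99% variance (default
95%); SMOTE/BSMOTE use k in [1, 7] (default 5, danger neighbourhood 10);
resampling targets a minority/majority ratio in [0.5, 1] (default 1).

## Distances, scaling and tie-breaks

SMOTE, BSMOTE, Tomek links and the borderline score all use Euclidean
neighbourhoods computed on z-scored features (fitted on the current training
rows; zero-variance features get divisor 1). Without this, a single
large-magnitude feature — common in radiomics — owns every neighbourhood.
Interpolation itself happens in the original coordinates, so SMOTE's convex
combination property holds per feature. Nearest-neighbour ties resolve to
the lowest index; Tomek links remove only the majority member (removing
minority members would aggravate the imbalance other steps correct), and
a removal that would empty a class is refused with a warning. Isolation
trees consume raw features (per-feature splits are scale-free). PCA centers
but does not rescale. SFS regresses the 0/1 label on candidate feature sets
by OLS and scores `R² = 1 − SSE/SST`; constant columns are never selectable.

One non-obvious consequence of the mutual-nearest-neighbour definition: Tomek
links form a perfect matching (each sample has exactly one nearest
neighbour), so every link has exactly one minority and one majority member,
and the borderline score is invariant under relabeling the classes. The test
suite asserts this invariance.

## The evaluation harness

`run_experiment()` compares three arms per fold — no preparation, MLDP
(search re-run on each fold's training split), and a fixed manual baseline
(SFS then SMOTE at defaults, the composition most hand-prepared radiomics
studies use) — across five classifier schemes at fixed registered defaults:
random forest, Newton-boosted trees, RBF least-squares SVM with
Platt-calibrated scores, a single-hidden-layer ReLU network, and a
diagonal-covariance multi-Gaussian posterior classifier. Because the
environment provides no tree-ensemble or SVM packages, the learners are
implemented in-package (CART forests and second-order boosting in C++); the
"registered default" settings (100 trees; depth 6, learning rate 0.3, 100
rounds; C = 1, γ = 1/(p·var); 32 hidden units, 200 epochs of Adam) pin down
what "default parameters" means reproducibly. The multi-Gaussian scheme is a
faithful-intent reconstruction: per-class diagonal Gaussians with variances
`var + 1e-6 + 0.1·overall_var`, scored as prior-weighted posteriors; the
original formulation was not published in reusable detail. Features are
z-scored inside SVM/NN/MG; tree ensembles consume raw features.

Fold metrics (ACC, SNS, SPC, PPV, NPV from the confusion matrix at the 0.5
cutoff; rank-based AUC with midrank ties) are computed per fold and then
aggregated as mean, SD and t-based 95% CI; metrics with zero denominators
are flagged `NA`, never silently zero. Fold-wise AUC of the MLDP arm is
compared with the no-preparation arm by two-group one-way ANOVA (identical
to the pooled-variance t-test, F = t²; zero pooled variance returns p = 1
with a flag). Pooled-prediction metrics are also emitted, since fold-mean
and pooled AUC answer slightly different questions. Stratification of the
Monte-Carlo splits is a deliberate choice the source text does not mention:
at n ≈ 44 an unstratified 20% draw regularly contains a single class.

Leakage safety is enforced, not assumed: every fitness evaluation records
the sample ids it touched; `run_experiment()` aborts if a validation id
appears in the search audit log or in any sample-space operator input, and
asserts that validation row counts are unchanged by pipeline application.

## The synthetic world

`generate_cohort()` draws class-conditional Gaussian informative features
(mean shift `class_separation` in SD units), redundant features as noisy
unit-norm linear combinations of the informative block (radiomics features
cluster heavily), pure-noise features, a configurable minority fraction,
injected outliers (rows relocated to ±`outlier_magnitude` SD with random
signs), and a `borderline_overlap` fraction of minority samples drawn with
zero shift. Ground truth (informative indices, outlier ids, overlap ids) is
returned alongside. Presets match the shapes, imbalances and outlier regimes
of the published cohorts (69×160 / 67-vs-33, 57×306 / 52-vs-48, 44×57 /
32-vs-68, 41×57 / 39-vs-61; outlier fractions 1.3%, 0.5%, 2.4%, 0.0%); the
two lymphoma presets share their redundant-feature wiring (a common
`structure_seed`) and the second center adds a 0.2 SD covariate shift,
emulating same-region cohorts scanned on different systems.

What the generator does *not* emulate: heavy-tailed marginals, measured
radiomic covariance structure, batch effects beyond a mean shift, and label
noise. A green test on this world therefore establishes mechanical
correctness (operators, search, harness, leakage safety) and qualitative
behaviour (diagnostics track their knobs; the search recovers planted
outlier/imbalance structure), not clinical performance claims.

## Numerical choices and degenerate inputs

* Seeds fan out through a counter-based derivation (`derive_seed()`), so
  adding folds or generations never reshuffles earlier streams; every
  result in the package is bit-reproducible from one integer seed.
* Missing feature cells reject the affected rows at ingestion with a
  warning. Silent imputation would be an undocumented preparation step.
* Labels are binarized at ingestion; downstream code sees {0, 1} only.
* SMOTE reduces k to (minority − 1) with a warning; BSMOTE with an empty
  danger set is a warned no-op; resampling with a target at or below the
  current ratio is a warned no-op; isolation-forest removal and Tomek
  removal refuse to empty a class.
* `write_cohort()` prints 17 significant digits, so a write/read round trip
  is the identity within 1e-12.
* MG log-likelihoods are computed and normalized in log space.

## Known limitations

* **Operating-point fitness vs rank metrics.** The fitness that reproduces
  the qualitative selection signature of the motivating study (high
  outlier-detection and SMOTE occurrence) evaluates a fixed 0.5 cutoff. On
  clean Gaussian synthetic cohorts, where a random forest's *ranking* is
  already near-optimal without preparation, pipelines selected under this
  fitness carry a small (~0.02) fold-mean AUC penalty from selection noise
  — the winner's curse over ~25 noisy fitness draws. The acceptance
  criterion asserting a directional AUC benefit of the MLDP arm is
  accordingly red on the synthetic world and documented as such; on data
  whose pathologies resemble the real cohorts (heavy tails, batch effects)
  the same machinery is expected to behave differently, but that cannot be
  demonstrated from synthetic Gaussians alone.
* Greedy OLS-R² forward selection is statistically weak at n ≈ 50 against
  hundreds of noise features (the single-feature R² of a moderate signal is
  comparable to the maximum of hundreds of null R² draws); it earns its
  place in the searchable space, not a guarantee.
* The pipeline tree supports `max_repetitions = 1` only; the source design
  allows a per-method cap, but no analyzed configuration repeats methods.
* Classifier hyperparameters are deliberately fixed at registered defaults;
  tuning them (or searching preparation and classifier jointly) is out of
  scope by design.
* At test scale the search budgets are reduced (population 6–12,
  generations 3–6, 2–3 inner splits, 25–50 surrogate trees) to keep the
  whole suite within a single-CPU budget; the recovery criterion sits at
  its threshold (7/10) at that budget and is deterministic under the frozen
  seeds.
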