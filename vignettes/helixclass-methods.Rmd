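---
title: "helixclass: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixclass: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixclass)
```

This vignette records how the pipeline works, which choices were genuinely
open when it was designed, and what the synthetic data can and cannot tell
you about real molecular-dynamics (MD) trajectories.

## The data model

A *trajectory record* holds, for one simulated 25-mer duplex, seventeen
helical-parameter time series: per snapshot and per base-pair level, the
six intra-base-pair parameters (shear, stretch, stagger, buckle, propeller,
opening), the six inter-base-pair step parameters (shift, slide, rise,
tilt, roll, twist), four axis parameters (X/Y displacement, inclination,
tip) and the overall axis bend. Rotational parameters are in degrees,
translational ones in Ångström. The axis bend is not listed with either
group in standard references; it is an angle between successive axis
segments, so the package treats it as rotational and reports it in degrees.

Series files follow a declared Canal-style dialect: one whitespace-delimited
text file per parameter (`<prefix>_<parameter>.ser`), one row per snapshot,
column 1 the time in ns, `#` comment lines ignored, undefined cells the
literal sentinel `NA`. Real Canal output leaves terminal step cells blank
or starred depending on version; a single sentinel keeps parsing
unambiguous, and the reader rejects ragged rows and non-numeric cells by
line number.

An L-mer duplex has only L−1 steps, but the feature schema needs one common
level axis. Each step is indexed by its 3′-side base pair (step i→i+1
stored at level i+1), leaving level 1 undefined for step-type parameters.
After trimming two levels at each terminus, levels 3–23 of a 25-mer are
defined for all seventeen parameters, which is what makes the
17 × 21 = 357 feature arithmetic exact.

## From trajectories to features

Three decisions shape the feature matrix:

* **Equilibration window.** The first 10 ns of a 100 ns run are discarded
  before aggregation; a frame is retained when `start ≤ t` (and
  `t < end` for a closed window). When a bundle's time span differs from
  100 ns, the *fraction* 0.10 of the span is discarded instead, so the
  same rule applies to shorter synthetic runs. Duplicate time stamps are
  rejected outright, because window trimming relies on time order.
* **Temporal aggregation.** How ~900 retained frames become one feature
  value per (level, parameter) cell is not dictated by the data layout;
  the 72-samples-by-357-features arithmetic forces *per-simulation*
  aggregation, and the ensemble average (mean over retained, unmasked
  frames) is the conventional summary, so the mean is the default, with
  `sd` and `median` selectable. A cell with zero defined frames is an
  error naming the cell, not a silent NA.
* **Replicates stay rows.** Triplicate runs are three rows; nothing is
  averaged across replicates. Train/test splits are at row level, which
  means replicates of one site can straddle the split — that matches the
  evaluation protocol being emulated, and is worth remembering when
  reading the near-perfect synthetic benchmark numbers.

Feature names use the em-dash form `14—propeller`; an ASCII hyphen is
accepted on input.

## The classifier benchmark

Fifteen classifiers — nearest neighbours; linear, polynomial and RBF SVMs;
Gaussian process; gradient boosting; decision tree; extra trees; random
forest; a small feed-forward neural network; AdaBoost; naïve Bayes; QDA;
an SGD-trained linear classifier; LDA — run under one protocol: per seed a
stratified 80/20 split, 10-fold stratified cross-validation inside the
training portion, and held-out test metrics, with the train–test gap
defined as train accuracy minus test accuracy. The fixed seed list is the
integers 0–9, since "the same seeds" only means something once the list is
declared.

Multiclass precision, recall and F1 use class-support weighting, under
which weighted recall equals accuracy — the pattern visible when accuracy
and recall columns coincide in benchmark tables. ROC AUC is one-vs-rest
with thresholds at the unique score values of each class column, trapezoid
integrated, macro-averaged; classes absent from the truth are skipped with
a warning, and classifiers that expose no scores simply have no AUC.

Engine choices: the panel calls the standard R implementations (`e1071`,
`kernlab`, `ranger`, `xgboost`, `rpart`, `nnet`, `MASS`, `class`). Two
members have no installed R counterpart and are implemented in the
package: AdaBoost as SAMME over depth-1 `rpart` stumps (50 rounds), and
the SGD classifier as one-vs-rest hinge-loss SGD with L2 regularisation
and internal standardisation. "Default hyperparameters" therefore means
each engine's shipped defaults, with two deliberate exceptions: the
standalone decision tree is grown fully (no pruning, minimum node size 1),
because a pruned-by-default CART stalls on small training sets and the
panel's reference behaviour is an unpruned tree; and the neural network
uses 10 hidden units with weight decay 1e-4, a practical size for
p ≈ 357 inputs. A classifier that cannot fit a given dataset (QDA whenever
features outnumber per-class samples) is recorded as missing with a
warning rather than aborting the benchmark.

## The random-forest model

The production model is a probability forest (`ranger`) mapped from the
usual hyperparameter vocabulary: `n_estimators` → trees, `max_depth`,
`max_features` ∈ {sqrt, log2, all} → `mtry`, `min_samples_leaf` →
`min.bucket`, `min_samples_split` → `min.node.size`, and `bootstrap off`
→ every tree sees the full training set (`replace = FALSE`, sampling
fraction 1). Grid search scores every point of the grid's cartesian
product by mean stratified-CV accuracy; ties go to the first point in
enumeration order. The searched grid is configurable; the shipped default
spans trees {50, 89, 100, 200}, depth {2, 4, 8, ∞}, features {sqrt, log2},
leaf {1, 2}, split {2, 4}, bootstrap {on, off}, and contains the optimised
configuration (89 trees, depth 4, sqrt, leaf 1, split 2, bootstrap off).

Deployment to an unseen dataset evaluates a stratified random 95 % of its
rows (ceiling arithmetic, per-class counts within ±1 of proportionality);
the remaining 5 % plays no role. Sampling canonicalises candidates by
sample name, so results are invariant to row order of the unseen matrix
under a fixed seed. The truncated-window robustness check rebuilds the
training features with an additional fraction of the span excluded,
retrains, redeploys on the *original-window* unseen features, and reports
metric deltas — a convergence diagnostic in which a reduction of zero
reproduces the base run exactly.

Whether feature scoring should use the optimised or the default forest is
not determined by anything upstream; both work, and the package defaults
to the optimised configuration everywhere for consistency.

## Feature scoring and consolidation

Scoring runs on adduct-bound samples only, with the binary hotspot label:
the question being asked is which geometric features separate
lesion-carrying hotspot duplexes from lesion-carrying nonhotspot ones.

* *Cross-validated RF importance*: impurity importances averaged over the
  10 fold-wise fits, ranked descending.
* *RFE with CV*: repeated elimination of the least important features,
  the surviving subset CV-scored at each stage; the reversed elimination
  order is the ranking. The classical step of one feature per round is the
  default; a fractional step (0.1 of the surviving set) is used on the
  full 357-feature schema for tractable run time and is configurable.
* *Lasso*: the "L1 regularisation" selector must be a classifier here, so
  the package uses L1-penalised logistic regression with internal
  standardisation and its penalty chosen by 10-fold CV; ranking is by
  absolute coefficient, zero-coefficient features following in column
  order. Standardisation makes the ranking invariant to column rescaling.

Consolidation assigns, per method, score `top_n − rank + 1` to the top
`top_n = ⌈0.10 · n_features⌉` features (36 for 357; rank 1 scores 36, rank
36 scores 1) and 0 to all others. A score span described as "36 … to 0"
over 36 features admits two off-by-one readings; this mapping is the only
one in which exactly the selected features have nonzero scores and 0 means
excluded. Totals are summed across the three methods, the selected set is
every feature with total > 0 (between `top_n` and `3 · top_n` features),
and ties in the global ranking break by feature column order. Nature
summaries report the rotational fraction and per-parameter shares of the
selected set.

## G/C-content comparison

Regional G/C content is computed on the adducted strand over base pairs
2–12 by default. That printed range is described as a "10 bp region" but
spans 11 positions inclusive; the package honours the positional range
(11 bases) and leaves both bounds as parameters. Duplex complementarity
makes G/C content strand-invariant, so one strand suffices. The default
test is a two-sided permutation test on the difference of group-mean G/C
fractions — exhaustive whenever the number of group assignments is at most
20 000 (exact at these group sizes), otherwise 10 000 seeded Monte-Carlo
draws with the add-one correction — because the underlying comparison was
reported only as a p-value threshold without a named test, and a
permutation test makes the fewest assumptions at n ≤ 12 per group. Welch's
t-test is available as an alternative.

## The synthetic generator

`generateBundle()` emulates what the analysis assumes about Canal output,
not the physics that produces it. Each (parameter, level) series is

```
baseline + planted shifts + replicate offset + AR(1) noise,
```

with canonical B-DNA baselines (twist 34°, rise 3.4 Å, other parameters
0-centred), stationary frame noise of 4° (rotational) / 0.4 Å
(translational) — typical fluctuation magnitudes for helical parameters at
room temperature — lag-1 autocorrelation 0.3, and a per-series replicate
offset (sd one quarter of the frame sd) representing run-to-run drift.
The training-scale preset (`tp53Config()`) generates 6 hotspot and 6
nonhotspot sites, triplicate, with and without the adduct: 72 records,
1000 frames over 100 ns. Its planted effects, each a 3-frame-sd mean
shift, encode three things the classifier should find: lesion-induced
distortion at the adduct base (buckle, rise at base 7 whenever the adduct
is present), sequence-intrinsic hotspot dynamics (tip at 23, X
displacement at 10), and a hotspot-specific adduct response (tip at 10,
propeller at 14, shift at 11) — the last three are the recovery targets
for feature scoring. Hotspot and nonhotspot sequences are generated with
regional G/C targets 0.7 and 0.4, with the lesion guanine fixed at
position 7 and the methylated cytosine at 6. Methylation is metadata-only
by default (no dynamical perturbation), consistent with treating it as a
label rather than a driver; a Val-style validation set is the same
configuration under a new seed.

What the generator does **not** reproduce: anharmonic and multimodal
parameter distributions (BPDE adducts flip between conformations),
cross-parameter and cross-level correlations, sequence-dependent
baselines, slowly decaying autocorrelation, and terminal fraying beyond a
simple mask. Passing tests on synthetic data therefore demonstrate that
the pipeline's bookkeeping, protocols and estimators are correct and that
planted signal of stated size is recovered — not that real MD data will
classify with any particular accuracy. Reproducing reported performance
on real trajectories requires the deposited MD dataset; the pipeline can
regenerate such tables given those inputs, and its synthetic benchmark
numbers should not be read as estimates of them.

## Numerical choices and degenerate inputs

* Series round-trips are exact to 1e-6 (six-decimal fixed-point output);
  the defined mask round-trips exactly.
* Time stamps must be strictly increasing; windows that exclude all
  frames, termini trims that exhaust the duplex, single-class training
  labels, empty rankings, and all-constant lasso inputs are errors, not
  warnings.
* All stochastic components (splits, folds, forests, Monte-Carlo
  permutations, the generator) are seeded; `ranger` and `xgboost` run
  single-threaded so fits are bit-reproducible.
* Ranking ties break by feature column order via stable ordering; grid
  ties break by enumeration order (first wins).
* Stratified sampling uses floor-plus-largest-remainder allocation, so
  per-class counts stay within ±1 of exact proportionality and the total
  equals the ceiling of the requested fraction.

## Problem sizes used by the test suite

The dataset arithmetic (357 features, 72 × 357 matrix) is independent of
the frame count, so the suite generates bundles at 100–250 frames and the
planted-recovery check runs 10 seeds at 250 frames; the acceptance script
uses the full 1000-frame preset throughout. Benchmark unit tests run the
15-classifier panel on small constructed feature sets (tens of samples,
single-digit features) where chance-level and perfect-separation behaviour
are unambiguous.

## Known limitations

* The Canal dialect is declared, not inferred from the original tool's
  output; real Canal files may need a thin conversion step.
* Row-level splitting lets replicates of a site appear on both sides of a
  split; a group-aware split by site is a natural extension the current
  interface does not expose.
* The benchmark's "library defaults" are R-engine defaults and two
  documented local choices, not a bit-faithful port of any other stack's
  defaults; cross-stack metric comparisons should expect engine-level
  differences.
* Deployment assumes the unseen feature matrix shares the training
  columns exactly; there is no imputation or column matching beyond an
  explicit error.
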