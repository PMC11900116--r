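---
title: "Methods: miRNA classification from sequence and annotation features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA classification from sequence and annotation features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirnadx` classifies miRNAs as disease-associated (`selected`) or
control (`random`) from three feature families: intrinsic sequence
descriptors, predicted gene targets, and enriched KEGG pathways. This
vignette documents the model and procedure, the conventions and
parameters the package fixes, why they are fixed that way, and what the
synthetic benchmark does and does not demonstrate.

## Feature construction

**Sequence descriptors.** For a mature miRNA sequence over A/C/G/U the
package computes: length in nt; the four base fractions (summing to 1);
GC fraction; a hydrogen-bond count; a mean residue mass; and one binary
presence flag per tetramer (all 256 k-mers of length 4, overlaps
allowed). Two conventions deserve spelling out because "hydrogen bonds"
and "mean mass" of a single strand are not self-defining:

* *Hydrogen-bond count* = `2(n_A + n_U) + 3(n_G + n_C)`: each base
  contributes its Watson–Crick pairing capacity (A:U pairs form 2
  hydrogen bonds, G:C pairs 3). This is the only sequence-intrinsic
  reading for a single strand — it is the bond count of the miRNA's
  perfect duplex, and it is a GC-content surrogate on a physically
  meaningful scale.
* *Mean mass* = the average internal-residue mass of the ribonucleotide
  monophosphates, with the constant table A = 329.21, C = 305.18,
  G = 345.21, U = 306.17 Da. The table is frozen so tests can assert
  exact arithmetic; terminal OH/phosphate corrections are deliberately
  ignored since only the per-residue average enters the model.

Motif features are binary presence rather than counts, consistent with
a one-hot design matrix; sequences shorter than 4 nt get an all-zero
motif block rather than an error. The full 256-tetramer vocabulary is
generated and left for feature selection to prune — a curated shortlist
would presuppose the answer.

**Annotation features.** Gene targets come with a prediction score in
[0, 100]; pathway assignments with an enrichment p-value. The filters
are *score ≥ 97* (boundary inclusive — the band "97–100%") and
*p < 0.05* (strict). Duplicate (miRNA, gene) rows keep the maximum
score and duplicate (miRNA, pathway) rows the minimum p-value; both
rules are fixed rather than configurable so a given input always yields
the same dataset. Surviving annotations become binary columns, one per
gene and per pathway in the vocabulary. In training mode the vocabulary
is the sorted union over the cohort (genes and pathways attached to
zero miRNAs after filtering are excluded — constant columns carry no
information and break some learners). In validation mode the training
vocabulary is frozen and unseen genes/pathways are dropped, so the
training and validation matrices always align column for column; this
is the package's defense against silent feature drift between model
building and holdout evaluation.

## Feature selection: CFS with best-first search

"Subset evaluation" is implemented as correlation-based feature
selection. Columns are discretized (10-bin equal-frequency binning for
numeric descriptors; binary columns pass through) and correlations are
measured by symmetric uncertainty
`SU(X, Y) = 2·I(X;Y)/(H(X)+H(Y)) ∈ [0, 1]`. A subset S of k features
scores

```
Merit_S = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)
```

with `r̄_cf` the mean feature–class SU and `r̄_ff` the mean pairwise SU
within S (vacuously 0 at k = 1). Best-first forward search expands the
highest-merit open subset by single-feature additions, breaking ties
toward the lower feature index, and stops after 5 consecutive
non-improving expansions. Equal-frequency binning was chosen over
MDL-based discretization to keep the procedure deterministic and
dependency-free; 10 bins is the conventional default and, at cohort
sizes near 88, finer binning mostly fragments the entropy estimates.

No hard cap is placed on the subset size: a report of "the 26 most
important features" on one dataset is an outcome of this procedure, not
one of its parameters (a `max_features` override exists for parity
experiments). One algebraic subtlety: the merit of a subset is *not*
monotonically harmed by every redundant addition. Duplicating a
subset's most relevant feature can raise the merit, because the doubled
relevance term can outgrow the redundancy penalty; duplicating a
singleton leaves merit exactly unchanged, and duplicating the least
relevant member never helps. The tests assert the latter two (true)
properties.

## The classifier bank

Seven learners share one interface (`fit_classifier()` /
`predict_prob()`, scores = P(selected), classification threshold 0.5,
ROC on the raw scores). Four are authored from scratch because their
update rules are the substance of the method; three delegate commodity
induction to mature implementations behind the same interface:

* **Naive Bayes** (from scratch): posterior ∝ prior × per-feature
  likelihoods; binary/one-hot columns use add-1-smoothed Bernoulli
  estimates `(count + 1)/(n_class + 2)`, numeric columns per-class
  Gaussians with a 1e-6 standard-deviation floor. Priors are the
  empirical class frequencies.
* **Hoeffding tree** (from scratch): a VFDT-style streaming tree over
  the discretized columns. Examples are processed once; every 10
  examples a leaf evaluates the information gain of each attribute and
  splits when the top-two gap exceeds the Hoeffding bound
  `ε = sqrt(R² ln(1/δ)/2n)` (R = 1 for two-class information gain,
  δ = 1e-7) or when ε falls below the tie threshold 0.05. Leaves
  predict with naive Bayes over their accumulated counts — on cohorts
  of under a hundred rows ε stays large, the tree rarely splits, and
  majority-vote leaves would collapse to chance; naive-Bayes leaves are
  the standard remedy and the reason the learner remains competitive at
  this scale. No mature VFDT implementation exists in the R ecosystem
  this package targets, so the induction loop is implemented here.
* **AdaBoost.M1** (update rule from scratch): `β_t = ε_t/(1−ε_t)`,
  correct-instance weights multiplied by β_t, renormalization to sum 1,
  abort at ε_t ≥ 0.5, perfect-learner stop at ε_t = 0; 10 rounds of
  depth-1 `rpart` stumps as the weak learner; committee votes weighted
  by `log(1/β_t)`.
* **Sequential neural network** (from scratch): the fixed architecture
  input → 100 → 70 → 50 → 30 → 1 with ReLU on the four dense layers and
  a sigmoid output. Training is plain backpropagation with Adam
  (learning rate 1e-3, β₁ = 0.9, β₂ = 0.999), binary cross-entropy,
  200 epochs, batch size 16, Glorot-uniform initialization — all
  conventional defaults, all recorded, since none are dictated by the
  architecture itself. Weights re-initialize per CV fold from the
  fold's derived seed.
* **Random tree / random forest** delegate to `randomForest` (1 tree
  resp. 100 trees, `mtry = sqrt(p)`), and the **MLP** to `nnet` (one
  hidden layer of `(p+2)/2` capped at 20 units, weight decay 1e-4) —
  commodity induction where the method contributes only configuration.

Numeric descriptor columns are z-scored with *training-fold* statistics
before MLP and sequential-network training (a mean-mass column near 320
next to 0/1 flags otherwise dominates the gradients); one-hot columns
pass through. Every learner re-seeds from its spec, so fits and
predictions are bit-reproducible.

## Evaluation

Cross-validation is stratified k-fold (default k = 10): within each
class, shuffled indices are dealt round-robin with a continuing offset
across classes, so per-class fold counts differ by at most 1 and fold
sizes by at most 1 (88 = 44/44 at k = 10 gives folds of 8–9 with 4–5
per class). Metrics are computed on the *pooled* out-of-fold
predictions — a single correct/total count over the whole cohort —
rather than averaged per fold; pooling is what makes "83/88 correctly
classified" a meaningful statement. Percent accuracy is
`100·correct/total` rounded half-up to 2 decimals. ROC curves sweep
every distinct score as a threshold and carry the threshold per point;
AUC is the trapezoidal area, which the tests verify equals the pairwise
Mann–Whitney count (ties half-weighted) to 1e-12.

The holdout protocol: build the validation table with the frozen
training vocabulary, drop any validation miRNA whose id occurred in
training, train the two classifiers with the highest pooled CV accuracy
(ties broken by AUC) on the full training table, and evaluate once.

## The synthetic cohort generator

`synthetic_config()` defaults define the benchmark conditions: 44
selected + 44 random training miRNAs and an 18-miRNA validation set
(matching the scale of a literature-curated two-arm cohort), sequence
lengths uniform on 18–25 nt (the mature-miRNA range), 5 marker genes
and 2 marker pathways carried with probability 0.9 by selected and 0.1
by random miRNAs, 40 background genes and 10 background pathways
carried class-independently at 0.3, and two biased tetramers (AACA at
0.9/0.1, GUGU at 0.85/0.15) implanted at random positions. Target
scores are uniform on [90, 100] and marker pathway p-values uniform on
[0.001, 0.06] (background on [0.02, 0.8]), deliberately chosen so both
filters remove real rows — a filter that never fires is untested code.
The validation set is drawn 9/9: the composition of an external
validation panel is a study-design choice, and a balanced draw keeps
holdout accuracy interpretable for both classes.

What the generator emulates: class-conditional enrichment, filter
attrition, annotation sparsity, id-disjoint validation draws. What it
does not: seed-match biology of target prediction, correlated gene
sets, pathway hierarchies, expression levels, or measurement noise in
any of these. A pipeline that recovers the implanted signal here is
demonstrated to be correct and leak-free, not demonstrated to reach any
particular accuracy on a real cohort.

## Numerical and procedural choices

* The permutation null used in the signal-recovery test cross-validates
  on the *full* table after label permutation, skipping the in-sample
  CFS step. Selecting features on permuted labels and then
  cross-validating on the selected columns reports the selection bias —
  observed at 70–85% pooled "accuracy" under the null — not chance. The
  real-signal arm keeps the select-then-cross-validate workflow, as the
  original analysis style (whole-dataset attribute selection before CV)
  does; the gap between the two arms is therefore a conservative
  statement of recovered signal.
* Problem sizes in the tests: cohorts of 88 (the study scale), CFS
  exhaustive-oracle tables of ≤ 12 features (2^12 subsets enumerable),
  AUC oracles at n ≤ 30, signal-recovery medians over 5 seeds. These
  sizes make every oracle exactly computable while keeping the default
  suite in the low minutes.
* Degenerate inputs: all-constant feature tables yield an empty
  selection with merit 0 and a warning; sub-4-nt sequences get zero
  motif blocks; single-class training data, one-class ROC inputs, and
  column-mismatched prediction tables raise errors naming the problem.
* Rounding uses explicit half-up (`floor(x·100 + 0.5)/100`), not R's
  banker's rounding, so count→percent arithmetic matches conventional
  reporting (64/88 → 72.73).

## Known limitations

Annotation tables are local TSV stand-ins for database exports; no
network access is attempted. The Hoeffding tree is single-pass and
depth-limited (6), adequate for the cohort sizes targeted here but not
a streaming-scale implementation. CFS is a filter method: features
whose relevance is purely interactive (XOR-like) score zero
individually; the best-first search can keep them only once a partner
is in the subset. The sequential network's hyperparameters are fixed
defaults, not tuned; no calibration of predicted probabilities is
performed anywhere.
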