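# mirnadx

Machine-learning classification of disease-associated microRNAs from
sequence and annotation features.

## The problem

Circulating miRNAs are attractive psychiatric biomarkers: a panel of
miRNAs consistently dysregulated in schizophrenia patients can be told
apart from randomly chosen miRNAs using nothing but the molecules'
intrinsic properties — their sequence and the genes and pathways they
regulate. `mirnadx` implements that discrimination pipeline end to end
for a cohort of labeled miRNAs (`selected` = disease-associated,
`random` = control):

1. **Sequence descriptors** per miRNA: length, base composition, GC
   fraction, hydrogen-bond count `2(n_A + n_U) + 3(n_G + n_C)`, mean
   residue mass, and a binary presence flag for each of the 256
   tetramers (e.g. `motif_AACA`).
2. **Annotation features**: gene targets with prediction scores
   (miRDB-style) kept at score ≥ 97, and KEGG pathway assignments
   (DAVID-style, ids `hsaNNNNN`) kept at p < 0.05, one-hot encoded.
3. **Feature selection**: correlation-based feature subset selection
   (CFS). Subsets are scored by
   `Merit_S = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` where `r̄_cf` is the mean
   symmetric uncertainty between subset features and the class and
   `r̄_ff` the mean pairwise symmetric uncertainty within the subset,
   searched by best-first forward search.
4. **Classifier bank** (7 learners): naive Bayes (add-1-smoothed
   Bernoulli + Gaussian likelihoods), a VFDT-style Hoeffding tree
   governed by the bound `ε = sqrt(R² ln(1/δ) / 2n)`, AdaBoost.M1 with
   the `β_t = ε_t/(1−ε_t)` reweighting, random tree, random forest, a
   multilayer perceptron, and a five-layer sequential neural network
   (dense ReLU layers of 100, 70, 50, 30 neurons, sigmoid output)
   trained by backpropagation with Adam on binary cross-entropy.
5. **Evaluation**: stratified 10-fold cross-validation with pooled
   out-of-fold accuracy (`100·correct/total`, half-up to 2 decimals),
   confusion matrices, threshold-swept ROC curves and trapezoidal AUC,
   plus an independent-holdout protocol with training-overlap exclusion
   and a frozen feature vocabulary.

Because real cohorts require database exports, the package ships a
synthetic cohort generator (`generate_cohort()`) that implants marker
genes, marker pathways, and sequence motifs class-conditionally at
configurable rates, so the whole pipeline is runnable, testable, and
benchmarkable offline.

## Worked example

```r
library(mirnadx)

cohort <- generate_cohort(synthetic_config(seed = 1))   # 44 selected + 44 random
ann    <- filter_annotations(cohort$annotations)        # score >= 97, p < 0.05
tab    <- build_table(cohort$records, ann)
tab
#> feature_table: 88 miRNAs x 319 features (264 descriptor, 45 gene, 10 pathway)
#> labels: random=44, selected=44

sel <- best_first_select(tab)
sel
#> selected_subset: 3 features, merit 0.6097
#> hsa05142, motif_GUGU, hsa05161

wt <- ft_cols(tab, sel$feature_indices)
cross_validate(classifier_spec("sequential_nn", seed = 1), wt, k = 10, seed = 1)
#> sequential_nn: 83/88 correct (94.32%), AUC 0.981
cross_validate(classifier_spec("naive_bayes", seed = 1), wt, k = 10, seed = 1)
#> naive_bayes: 84/88 correct (95.45%), AUC 0.982
```

The selection picked the two implanted marker pathways and one of the
two implanted biased motifs; on those three features the sequential
network classifies 83 of the 88 miRNAs correctly out-of-fold and the
naive Bayes 84, both with AUC ≈ 0.98 — the generator's class signal is
recovered almost completely, while label permutation drives the same
learners to chance (see the tests).

`run_pipeline(default_run_config(seed = 1, outdir = "out"))` runs all
seven classifiers, picks the two best by CV accuracy (ties by AUC),
trains them on the full table, evaluates them on an independent 18-miRNA
validation cohort with training overlap excluded, and writes the ARFF/CSV
tables, per-classifier JSON reports, and a manifest that reproduces the
run bit for bit.

A thin command-line front-end with `simulate`, `build-dataset`,
`select`, `evaluate` and `run-all` subcommands is installed at
`inst/scripts/mirnadx-cli`.

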