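---
title: "Mutation-based molecular subtyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-based molecular subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transcriptome-defined tumor subtypes (such as the PAM50 breast cancer
classes) guide therapy, but RNA-based classification requires invasive,
degradation-sensitive assays. Somatic point mutations are stable, detectable
from liquid biopsies, and cumulative — an attractive substrate for subtype
inference. They are also a statistically hostile one: a cohort's gene-level
mutation matrix is binary, extremely sparse (around 1% of entries non-zero),
spans ~10^4 genes with a long-tailed recurrence distribution, and the four
subtypes of interest are strongly imbalanced. `mutsubtype` implements a
complete pipeline for this setting: MAF ingestion, pathway-constrained
mutual-information feature selection, a hybrid wide/factorization-machine/
deep classifier, imbalance-aware training, and evaluation machinery with
bootstrap uncertainty.

# From mutation calls to features

`read_maf()` parses tab-separated MAF files and
`filter_nonsynonymous()` retains the protein-altering variant classes
(missense, nonsense, nonstop, frameshift and in-frame indels, splice-site,
translation-start-site — the convention of standard MAF tooling, and
configurable). `build_binary_matrix()` collapses records to a samples ×
genes indicator: entry 1 means at least one retained mutation. Samples with
zero retained mutations are kept as all-zero rows whenever an explicit
sample list is supplied, since dropping them would bias cohort-level
summaries. `summarize_cohort()` reports per-sample variant counts and
tumor mutational burden (count divided by the capture size; default 50 Mb,
a typical whole-exome footprint — the capture size is a parameter because
TMB is meaningless without it).

Feature selection then proceeds in three stages:

1. **Recurrence filter** (`recurrence_filter()`): genes mutated in fewer
   than a fraction `threshold` of training samples are removed; the
   boundary is inclusive (a gene exactly at the threshold is kept). The
   default threshold is 0.005; a sensitivity grid
   `{0.01, 0.005, 0.0025, 0.001}` is the conventional sweep, and
   `stability_analysis()` quantifies how the selected sets move across it
   (Jaccard, inclusion rate of the stricter set, Spearman correlation of
   the mutual-information rankings over the shared top genes — the shared
   subset is used, with the number of excluded genes reported, because a
   rank correlation over genes absent from one set is undefined).
2. **Pathway grouping**: genes are organized by a curated GMT collection
   (`read_gmt()`), not by data-driven clustering; genes in no pathway are
   unselectable by construction.
3. **Mutual-information representatives**
   (`select_pathway_representatives()`): within each pathway the surviving
   member gene with the highest mutual information against the subtype
   labels is chosen. The MI estimator is the maximum-likelihood plug-in
   over the empirical 2 × C contingency table, with zero-count cells
   contributing zero (the x log x limit) and no pseudocounts. MI is
   computed in nats internally; ranking and argmax are base-invariant, so
   the unit only matters for reporting (a bits toggle exists). Ties —
   possible because MI of a binary gene takes finitely many values — break
   to the higher mutation frequency (better-supported feature), then to the
   lexicographically smaller symbol, making selection fully deterministic.

Feature selection is a training-data operation. `run_pipeline()` splits the
cohort (stratified 70/30 by default) before selection ever sees a label,
and the command layer records the exact training-sample list in a JSON
audit file. The test suite includes a poisoning test: implanting a
perfectly label-correlated gene in the held-out rows must not change the
selected set.

# The classifier

The model maps a binary feature vector $x \in \{0,1\}^N$ to class logits as
the sum of three branches:

* **Wide**: $y_{\text{linear}} = W x + b$, the marginal effect of each
  gene — subtype-biasing driver mutations act here.
* **Factorization machine**: each gene carries a latent vector
  $v_i \in \mathbb{R}^K$ (default $K = 4$) and pairwise interactions are
  $\sum_i \sum_{j>i} \langle v_i, v_j\rangle x_i x_j$, computed in
  $O(NK)$ via the sum-of-squares identity
  $\tfrac12[(\sum_i x_i v_{ik})^2 - \sum_i x_i v_{ik}^2]$ per component
  (verified against the naive double loop in the tests). This branch
  targets co-occurrence and mutual-exclusivity structure.
* **Deep**: the active embeddings are sum-pooled,
  $e = \sum_i x_i v_i \in \mathbb{R}^K$, and passed through an MLP with
  hidden layers of 64 and 32 ReLU units, dropout after each hidden layer
  (rate 0.5 by default; the rate is a free parameter), and a final dense
  layer of C units with no activation.

A softmax turns the summed logits into class probabilities.

Two architectural points were genuinely open and are worth recording. The
literal factorization-machine output is a *scalar*; adding a scalar to
every class logit is annihilated by the softmax, so a literal reading makes
the FM branch a no-op. The default `fm_mode = "per_class"` therefore
projects the K-dimensional interaction vector to C logits through a learned
matrix, preserving the pairwise-interaction mechanism while letting it
discriminate classes; the inert scalar mode is retained as a configuration
option and its no-op behavior is itself a unit test. Second, the deep
branch consumes the *sum-pooled* embedding (input dimension K), not the
N × K concatenation used by some related architectures; the pooled form is
implemented as specified, and the output head is a dense C-unit layer.
Initialization is seeded: embeddings and the FM projection start from
N(0, 0.01²); dense layers use fan-in-scaled uniform weights; biases start
at zero.

# Training recipe

`fit_classifier()` optimizes unweighted multiclass cross-entropy with Adam
(β₁ = 0.9, β₂ = 0.999, learning rate 10⁻³). Gradients are derived
analytically for all branches and validated against finite differences in
the tests. The recipe's components:

* **Imbalance handling**: mini-batches (size 64, one epoch =
  ⌈n/64⌉ batches) are drawn *with replacement* with probability
  proportional to inverse class frequency, so each class is sampled at
  equal expected rate; the loss itself is untouched. A `sampler = "uniform"`
  mode exists solely for controlled comparisons.
* **Validation carve-out**: a stratified 10% of the training partition is
  held out internally; it drives both schedules below.
* **Learning-rate decay**: multiply by 0.5 when the validation loss has
  not improved for 10 epochs ("improved" means dropping by more than
  10⁻³).
* **Early stopping**: stop after 10 non-improving epochs (same
  improvement definition, independent counter; the scheduler is consulted
  first each epoch) and return the parameters from the best validation
  epoch. With equal patience values the first decay and the stop coincide —
  the recipe is effectively single-rate — but both mechanisms are
  implemented independently so other configurations behave as expected.
* **Selective L2**: weight decay 10⁻³ applies to the linear weights, the
  dense-layer weights and the FM projection, but not to the embeddings or
  any bias.
* **Reproducibility**: one seed fans out into named sub-streams (split,
  initialization, sampler, dropout, folds, bootstrap), so identical
  configurations give bit-identical histories, parameters and outputs, and
  stages can be re-run independently.

`cross_validate()` and the `cmd_crossval` command run stratified 5-fold
cross-validation (folds partition the samples with per-fold class counts
within one of proportionality). Whether feature selection should be redone
per fold or inherited from a global training split is ambiguous in
principle; the command layer re-selects inside each fold's training
partition — the strictest leakage control — and `cross_validate()` operates
on an already-selected matrix for callers who want the global variant.

# Evaluation and uncertainty

`evaluate_predictions()` reduces the confusion matrix one-vs-rest per
class: sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
TP/(TP+FP), F1, plus overall accuracy and unweighted macro averages.
Zero-denominator cases are defined as 0 and flagged rather than returned as
NaN, keeping macro averages defined on small folds while surfacing the
degeneracy; specificity is reported per class but excluded from the macro
set, matching the conventional reporting quartet
(precision/recall/accuracy/F1). ROC curves sweep descending unique scores
with ties grouped; the trapezoidal AUC equals the normalized
Mann–Whitney statistic and is tested for exact agreement with a pairwise
concordance count. Average precision is the step-wise sum
$\sum_n (R_n - R_{n-1}) P_n$ with the prevalence baseline reported. The
macro OvR AUC is the unweighted mean of the per-class OvR AUCs. One-vs-one
AUCs renormalize the probability pair by default (a raw-probability flag
exists); reversing the pair flips both score and positive class, so the
pairwise AUC is order-invariant.

`bootstrap_ci()` resamples the evaluated indices with replacement (B =
1000 by default), keeping the trained model fixed, and reads 95% intervals
from the 2.5th/97.5th percentiles using R's default linear-interpolation
empirical quantile. Replicates in which a metric is undefined (a class
absent from the resample) are recorded as missing, excluded, and counted.
The accuracy interval is validated against the closed-form binomial
percentile interval on a fixed correctness vector.

# The synthetic generator

`generate_cohort()` emulates the statistical structure the method assumes,
so that every pipeline property can be tested against a known truth:

* **Background**: per-gene rates drawn log-uniformly from
  (0.001, 0.02) produce the long-tailed recurrence profile of real
  cohorts (a fixed-rate mode exists for analytic expectation checks).
* **Classes**: sizes follow largest-remainder apportionment of the
  configured proportions; the `tcga_like_config()` preset uses
  0.47/0.21/0.21/0.11 for Luminal A/Luminal B/Basal/HER2-like imbalance
  (approximate by design — exact cohort counts are cohort-specific) at
  n = 900.
* **Signal**: informative genes follow a two-level Bernoulli code — rate
  `base + gap` in marked classes, `base` elsewhere, with `base` defaulting
  to the geometric mean (= median) of the background range so unmarked
  classes look like background. Marker genes are dedicated to single
  classes, allocated equally among the non-majority classes with
  remainders to the rarest; the most prevalent class receives none and is
  identified by marker *absence*. This mirrors the empirical observation
  that the rarer, more aggressive subtypes carry the more distinctive
  mutational patterns while the most common subtype is the default-like
  background class.
* **Pathways**: consecutive gene blocks form the pathway collection, and
  each informative gene is placed in exactly one pathway among noise
  genes, so pathway-representative selection has a well-defined target.

Fixture writers (`write_fixture_maf()`, `write_fixture_gmt()`) round-trip
exactly through the package's own readers, including optional sprinkled
synonymous rows that must be invisible after filtering.

## What the generator does and does not show

Two structural consequences of this design deserve emphasis, because they
bound what passing tests demonstrate about real data.

First, the generator's features are *conditionally independent given the
class*. For independent Bernoulli features the Bayes posterior log-odds
are exactly linear in the binary inputs, so the wide branch alone spans
the population-optimal classifier and the FM and deep branches can
contribute nothing but estimation variance on such cohorts. Branch
ablations on generated cohorts therefore show near-ties (or small
reversals) between the full model and the wide-only model — unlike real
mutation data, whose co-occurrence and pathway-level structure is exactly
what the richer branches exist to capture. A generator emitting
higher-order class-dependent dependence would be needed to exercise that
advantage synthetically.

Second, with ten marker genes of rate gap 0.4 under the preset imbalance,
the *population-optimal* classifier (computed from the true rates) reaches
a macro-F1 of roughly 0.89 — every trained model sits below this
information ceiling, however good the optimizer. Planted-signal tests at
this gap therefore check recovery of the informative genes and strong (not
near-perfect) generalization; the near-perfect regime requires a larger
gap, and the test suite uses 0.6 where it asserts tight recovery bounds.

Third, on label-independent (null) cohorts the inverse-frequency sampler
flattens the class prior: the loss-optimal model outputs near-uniform
probabilities, so null accuracy concentrates near 1/C rather than at the
majority-class rate a prior-preserving learner would show. This is a
property of the rebalancing recipe, not a defect: the sampler trades
majority-class accuracy for minority recall by design.

# Numerical choices

* MI: plug-in probabilities; 0 log 0 = 0; no pseudocounts; negative
  rounding error clamped at zero.
* Softmax: row-max subtraction for overflow safety; shift-invariance is a
  tested property.
* Binary inputs are validated; real-valued feature vectors are rejected
  rather than silently accepted.
* Checkpoints: a JSON header (configuration + shapes) followed by
  `%.17g`-formatted parameter lines — full double precision, so reloaded
  inference is bit-identical while the file stays plain text.
* Degenerate metrics return 0 with a flag (see above); single-class ROC
  input raises an undefined-metric error instead of fabricating a value.
* Fold assignment deals shuffled class members round-robin with a rotating
  starting fold, guaranteeing the ±1 balance invariant deterministically.

# Problem sizes used in the test suite

The packaged tests run the full pipeline at n = 1000 samples × 2100 genes
(200 pathways) for the study-condition checks, n = 400–500 for pipeline
mechanics, and n ≤ 100 for unit fixtures; the acceptance script uses the
n = 1000 configuration end to end with B = 1000 bootstrap replicates.
These sizes were chosen so the whole suite exercises every stage — data
generation through bootstrap — at cohort scales where the statistical
assertions (recovery rates, interval coverage, sampler balance) have
adequate power.

# Limitations

Beyond the generator caveats above: the pipeline models mutation presence
only (no copy number, no functional-impact weighting); gene symbols are
matched exactly with no alias resolution; the recurrence threshold is a
bias-variance dial whose best value is cohort-dependent; and models trained
on tissue-derived cohorts should not be expected to transfer to liquid
biopsy data without domain adaptation — the architecture is a starting
point for such transfer, not a solution to it.
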