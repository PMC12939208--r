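# mutsubtype

Molecular subtype classification of tumors from somatic point-mutation
profiles.

## The problem

Tumor subtypes (for breast cancer, the PAM50 classes Luminal A, Luminal B,
HER2-enriched and Basal-like) are usually assigned from gene expression,
which requires invasive, degradation-sensitive assays. Somatic mutations
are stable and detectable from circulating cell-free DNA — but gene-level
mutation data is binary, ~99% sparse, spans tens of thousands of genes with
a long-tailed recurrence distribution, and the classes are heavily
imbalanced. `mutsubtype` is a complete R toolkit for subtype inference in
this regime, aimed at computational oncologists working with MAF-format
mutation calls and curated gene-set collections.

## The method

1. **Matrix construction** — MAF records are filtered to non-synonymous
   variant classes and collapsed to a binary gene × sample matrix
   (1 = at least one protein-altering mutation).
2. **Pathway-constrained feature selection** — genes below a recurrence
   threshold (default 0.5% of training samples) are dropped; surviving
   genes are grouped by curated pathways (GMT), and within each pathway
   the gene with the highest mutual information

   I(X;Y) = Σ_y Σ_x p(x,y) log [ p(x,y) / (p(x) p(y)) ]

   against the subtype labels is kept as that pathway's representative.
   Selection only ever sees the training partition.
3. **Three-branch classifier** — class logits are the sum of
   * a *wide* branch `W x + b` (marginal gene effects),
   * a *factorization machine* branch Σ_{i<j} ⟨v_i, v_j⟩ x_i x_j over
     latent gene embeddings v_i ∈ R^K (K = 4), computed in O(NK) via the
     sum-of-squares identity (pairwise co-occurrence / exclusivity), and
   * a *deep* branch: the sum-pooled embedding Σ_i x_i v_i through a
     64–32 ReLU MLP with dropout (higher-order structure),

   normalized by a softmax over the four classes.
4. **Training** — Adam (lr 1e-3), mini-batches drawn with replacement
   proportional to inverse class frequency, plateau learning-rate decay
   (×0.5, patience 10), early stopping (min-delta 1e-3, patience 10),
   selective L2 (1e-3, dense and linear weights only), all randomness from
   one seed.
5. **Evaluation** — stratified cross-validation and 70/30 held-out
   testing; per-class sensitivity/specificity/precision/F1, one-vs-rest
   and one-vs-one ROC, precision-recall with prevalence baselines, and
   percentile-bootstrap confidence intervals (B = 1000) on the test set.
   Branch ablations (`run_ablation()`) compare wide / fm / deep subsets on
   identical splits.

A synthetic-cohort generator (`generate_cohort()`) emulates the sparsity,
long-tailed recurrence, class imbalance and planted informative genes of
real cohorts, and writes MAF/GMT fixtures that round-trip through the
package's own readers. See the methods vignette
(`vignettes/mutation-subtyping.Rmd`) for the model, its assumptions and
the design decisions.

## Worked example

```r
library(mutsubtype)

cohort <- generate_cohort(tcga_like_config(seed = 42))
cohort
#> Synthetic cohort: 900 samples x 2000 genes (density 0.0067), 4 classes, 10 informative genes

res <- run_pipeline(cohort$matrix, cohort$labels, cohort$pathways,
                    threshold = 0.005, train_fraction = 0.7, seed = 42)
res$fit
#> Three-branch classifier (wide+fm+deep): 199 features -> 4 classes
#> Trained 34 epochs (best epoch 24, early-stopped)

res$report
#> Evaluation on 271 samples: accuracy 0.790, macro-F1 0.798, macro OvR AUC 0.930
#> # A tibble: 4 x 8
#>   class sensitivity specificity precision    f1 degenerate auc_ovr
#>   <chr>       <dbl>       <dbl>     <dbl> <dbl> <lgl>        <dbl>
#> 1 LumA        0.780       0.819     0.792 0.786 FALSE        0.886
#> 2 LumB        0.754       0.939     0.768 0.761 FALSE        0.924
#> 3 Basal       0.789       0.944     0.789 0.789 FALSE        0.935
#> 4 Her2        0.9         0.975     0.818 0.857 FALSE        0.977
```

The report says: on the 271 held-out samples, 79% of subtype calls are
correct, the unweighted mean F1 across the four subtypes is 0.80, and each
subtype is separated from the rest with ROC AUC 0.89–0.98 — the rare
HER2-like class is recovered best because the generator gives rarer classes
more dedicated marker genes. Bootstrap uncertainty on those numbers:

```r
test_ids <- !res$split
probs <- predict(res$fit, cohort$matrix[test_ids, res$features$gene],
                 type = "prob")
bs <- bootstrap_ci(cohort$labels[test_ids], probs, B = 1000, seed = 42)
tidy(bs)
#> # A tibble: 5 x 5
#>   metric           mean ci_low ci_high n_missing
#>   <chr>           <dbl>  <dbl>   <dbl>     <int>
#> 1 accuracy        0.790  0.745   0.834         0
#> 2 macro_auc_ovr   0.930  0.905   0.953         0
#> 3 macro_f1        0.797  0.751   0.844         0
#> 4 macro_precision 0.792  0.741   0.844         0
#> 5 macro_recall    0.806  0.756   0.853         0
```

`autoplot(res$report)` draws the confusion matrix; `plot_roc()` /
`plot_pr()` draw the one-vs-rest curves; `tidy()` / `glance()` methods
expose every result as a tibble.

The same pipeline is available from the shell via `inst/cli/mutsubtype`
with subcommands `simulate`, `build-matrix`, `select`, `train`,
`crossval`, `evaluate`, `bootstrap` and `ablate`, each writing TSV/JSON
outputs plus a manifest recording inputs and seeds.

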