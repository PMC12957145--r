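# trainmark

Biomarker discovery for trained immunity in heart failure — an end-to-end,
reproducible reimplementation of a multi-cohort transcriptomic prioritization
pipeline, exercised entirely on synthetic cohorts that the package itself
generates.

## The problem

Trained immunity is the long-lasting functional reprogramming of innate
immune cells (here, macrophages) after a priming stimulus. Bulk RNA-seq
studies of failing myocardium suggest that genes carrying this macrophage
training signature overlap the heart-failure transcriptional response. The
analytical question is: **which genes sit at the intersection of (i) the
disease's differential expression, (ii) a trained-immunity signature, and
(iii) trait-associated co-expression modules — and which of those candidates
carries the most classification-relevant signal?**

`trainmark` implements each stage of that discovery flow as a tested,
reusable R function:

1. **Differential expression** on log2(X+1) matrices with an
   empirical-Bayes moderated *t* (posterior variance
   s̃²g = (d₀s₀² + d·s²g)/(d₀ + d)) or Welch's *t*; calls at *p* < 0.05 and
   |log2FC| > 0.585 (a 1.5-fold change).
2. **Co-expression modules**: unsigned adjacency a_ij = |cor(x_i, x_j)|^β
   with β chosen so the connectivity distribution approximates scale-free
   topology (signed R² ≥ 0.90); topological overlap
   TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij); average-linkage
   clustering with a dynamic tree cut (minimum module size 30, eigengene
   merge height 0.25); module eigengene–trait Pearson correlation.
3. **Immune deconvolution**: nonnegative least squares against a reference
   signature, fractions normalized to sum to 1; Spearman cell–cell
   correlations; the pseudocount ratio (f_A + ϵ)/(f_B + ϵ) with ϵ = 10⁻⁶;
   a subfunction synergy network with edges at Spearman ρ ≥ 0.6.
4. **Ensemble prioritization**: 70/30 stratified split; six classifiers
   (RF, radial SVM, GLM, LASSO, KNN, NNET) with 5-fold CV; probability
   residuals |y − p̂| and RMSE; permutation importance (mean 1 − AUC drop
   over 50 shuffles); within-model z-scoring, inverse-rank model weights,
   and 3-D PCA with selection of the gene farthest along each of PC1–PC3.
5. **Cross-cohort validation**: mean-of-z signature scores, Mann–Whitney
   ROC/AUC, Hedges' g per cohort, DerSimonian–Laird random-effects pooling
   with Q, τ², I².
6. **Pre-ranked GSEA**: weighted Kolmogorov–Smirnov enrichment score over a
   signal-to-noise or Spearman-to-target ranking, gene-label permutation
   *p*, NES, and GSEA-style FDR *q* (significance at *q* < 0.25).
7. **Single-cell stratification**: top/bottom 40% expression strata,
   pseudotime profiles, and Wilcoxon strata differential expression.

A synthetic-data module (`make_bulk_cohort`, `make_mixture_cohort`,
`make_trained_signature`, `make_cell_population`) generates cohorts with
planted fold changes, latent-factor co-expression modules, known cell-type
mixtures and monotone pseudotime trends, so every stage can be scored
against ground truth without downloading anything.

## Worked example

```r
library(trainmark)

res <- run_discovery(run_config(seed = 1, gsea_nperm = 500),
                     out_dir = "trainmark_run")

res$hubs
#> [1] "g0001" "g0002" "g0003" "g0004" "g0005" "g0006" "g0007"
res$prioritization$selected_genes
#> [1] "g0001" "g0004" "g0005"
round(res$validation$auc, 3)
#> [1] 0.897 0.953 0.833
res$validation$meta$pooled
#> pooled g 2.90 [2.27, 3.52], I2 31.2
res$gsea[, c("set", "es", "nes", "p_perm", "q")]
#>   set     es    nes p_perm      q
#> 1  up  0.711  1.480 0.0172 0.0151
#> 2 down -0.305 -0.849 0.6935 0.6885
res$sc$fold_change$fold_change
#> [1] 2.03
```

Reading the output: the three-way intersection recovers the seven planted
hub candidates; the importance-fusion PCA selects three genes, led by
`g0001` — the gene planted with the strongest case/control effect. The
three held-out validation cohorts give signature-score AUCs of 0.83–0.95
and a pooled standardized mean difference of 2.90 (95% CI 2.27–3.52) for
the top gene, the planted "up" trained-immunity gene set is significantly
enriched toward the case phenotype (*q* = 0.015), and the single-cell stage
recovers the planted 2-fold macrophage expression shift (estimate 2.03).

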