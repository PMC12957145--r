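---
title: "Methods: models, parameters and design choices in trainmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in trainmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainmark)
```

`trainmark` re-implements, as a single tested pipeline, a multi-cohort
strategy for prioritizing trained-immunity biomarkers in heart failure:
differential expression, co-expression module detection, immune
deconvolution, ensemble machine-learning prioritization, cross-cohort
meta-analytic validation, pre-ranked enrichment, and single-cell
stratification. This vignette documents the statistical models, the
tunable parameters and their defaults, the numerical decisions made where
the procedure was genuinely open, and what the synthetic-data generator
does and does not emulate.

## Differential expression

Expression is analyzed on the `log2(x + 1)` scale; `to_log2p1()` applies
the transform exactly once and refuses a second application, because a
double transform silently compresses every fold change. The per-gene log2
fold change is the difference of group means on that scale (transform
first, test second), not the log of the ratio of linear means.

The default test is a moderated *t*: per-gene pooled variances
$s^2_g$ (residual df $d = n_1 + n_2 - 2$) are shrunk toward a prior by the
posterior $\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g) / (d_0 + d)$, with
$(d_0, s_0^2)$ estimated by moment matching on $\log s^2_g$ (the excess of
the variance of log sample variances over the $\chi^2$ sampling
contribution identifies $d_0$ through the trigamma function). The
moderated *t* is referred to $d_0 + d$ degrees of freedom. Welch's
unequal-variance *t* is available as `method = "welch"`; a zero-variance
gene under Welch gets $p = 1$ with a warning rather than an error, so one
degenerate gene cannot abort a cohort. The test suite cross-checks the
moderated statistics against limma's empirical-Bayes fit on a shared
fixture.

Calls use the nominal *p*-value (up: $p < 0.05$ and $\mathrm{log2FC} >
0.585$; down: the mirror condition). 0.585 is $\log_2 1.5$ — the 1.5-fold
boundary. Benjamini–Hochberg adjusted *p*-values are reported but do not
drive the calls, which mirrors how such thresholds are typically applied
in the source literature; both thresholds are arguments.

## Co-expression modules

The network is unsigned: adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$.
Signed versus unsigned is not dictated by the procedure being emulated;
unsigned is the historical default of the method family and treats
anticorrelated genes within a module as connected.

**Soft-threshold selection.** For each power $\beta \in \{1, \dots, 20\}$
the connectivities $k_i = \sum_{j \ne i} a_{ij}$ are summarized by a
scale-free fit index: connectivities are split into 10 equal-count bins,
each bin's frequency density is estimated as
$\mathrm{count} / (N \cdot \mathrm{width})$, and $\log_{10}$ density is
regressed on $\log_{10}$ mean connectivity; the index is
$-\mathrm{sign}(\mathrm{slope}) \cdot R^2$, positive for power-law-like
decay. Two numerical choices matter here:

* *Equal-count bins* (quantile breaks) rather than equal-width bins keep
  every bin populated at the few-hundred-gene scale where equal-width
  binning leaves most bins empty.
* *The bin width used for the density is the range actually spanned by the
  bin's members*, not the distance between quantile breaks. With clumped
  connectivity distributions a quantile bin can straddle a long, sparsely
  populated stretch of the axis; dividing by the break width would dilute
  that bin's density by orders of magnitude and wreck the regression even
  when the underlying decay is clean. The member range is the defensible
  estimate of where the bin's mass actually sits. Zero-range bins fall
  back to the break width.

The selected $\beta$ is the smallest power with fit $\ge 0.90$; if none
reaches the target the maximum-fit power is used and a message says so.
Mean connectivity is strictly decreasing in $\beta$ (each $|r| < 1$), which
the tests assert.

**Topological overlap and tree cutting.** The TOM is
$(\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with
$\ell_{ij} = \sum_u a_{iu} a_{uj}$; genes cluster by average linkage on
$1 - \mathrm{TOM}$. The dynamic cut is the tree-shape-based variant, not
the full hybrid algorithm with a PAM stage (which is under-specified for
this setting): the dendrogram is first cut at 99% of the top merge height
— genes with no topological overlap merge essentially at the maximum
dissimilarity, so they remain late-merging singletons and stay unassigned
— and each branch is then recursively split wherever two sub-branches of
at least `min_module_size` (default 30) genes are separated from their
joining merge by a height gap of at least 0.1. Clusters below the minimum
size are labeled 0 (unassigned). Because the cut is validated against
planted-module recovery (adjusted Rand index) rather than label-exact
output of any particular implementation, the simplification is tested, not
assumed.

**Eigengenes and merging.** A module eigengene is the first principal
component of the module's gene-standardized expression, scaled to unit
variance and sign-oriented to correlate nonnegatively with the module's
mean profile (PC signs are otherwise arbitrary, which would make
module–trait correlations seed-dependent). Modules whose eigengenes are
closer than `merge_height = 0.25` in correlation dissimilarity merge
iteratively until stable. Eigengene–trait association is Pearson *r* with
the usual *t*-approximation *p*.

## Immune deconvolution and ratio statistics

Cell fractions are estimated per sample by nonnegative least squares
($\min_w \lVert S w - b \rVert^2$, $w \ge 0$) followed by normalization to
sum 1, with the per-sample residual norm recorded. This deliberately
replaces the ν-SVR solver of the reference tool: NNLS is deterministic,
dependency-free, exact on noiseless mixtures, and the solver sits behind a
single function so it can be swapped. No reference signature is
redistributed; tests use synthetic block-marker signatures and users
supply their own as a genes × cell-types TSV.

Zero-variance cell types are removed before association analyses (a
constant column correlates spuriously), cell–cell structure is Spearman
with average ranks and unit diagonal, and the pairwise abundance ratio is
$(f_A + \epsilon)/(f_B + \epsilon)$ with $\epsilon = 10^{-6}$, log2
transformed; the pseudocount guarantees finiteness when a fraction is
exactly zero, and $\mathrm{ratio}(A,B)\cdot\mathrm{ratio}(B,A) = 1$ always.
Group comparison of log ratios uses the Wilcoxon rank-sum test with BH
adjustment across pairs — the nonparametric choice matches how such
compositional contrasts are usually displayed, and no specific test was
prescribed.

Subfunction scores are the mean across member genes of each gene's
across-sample z-scored `log2(x+1)` expression; the exact scoring rule of
the emulated analysis lives in supplementary material that is not part of
the procedure's main text, so mean-of-z is this package's documented
stand-in. Constant genes are skipped; sets left with fewer than two
usable genes are skipped with a warning. The synergy network connects set
pairs with Spearman $\rho \ge 0.6$ — a signed threshold, so
anticorrelation never creates an edge, and raising the threshold can only
remove edges.

## Ensemble prioritization

Candidates are the three-way intersection of DEG calls, the
trained-immunity signature and the top trait-module genes. The sample
split is stratified 70/30 with round-half-up per group (so 21 + 9 samples
split 15 + 6 / 6 + 3); features are centered and scaled using training
statistics only. Six classifiers — random forest, radial SVM, logistic
GLM, LASSO, KNN, single-hidden-layer neural network — are tuned by
stratified 5-fold cross-validation over small fixed grids (mtry ∈ {1, √p,
p}; SVM cost ∈ {0.25, 1, 4}; k ∈ {3, 5, 7}; nnet size ∈ {1, 3}, decay 0.1;
LASSO λ by its own CV path). The grids are deliberately small: with a
handful of candidate genes the models are low-dimensional and deeper
searches would add runtime without changing the ranking behavior being
tested.

Permutation importance of gene *g* under a model is the mean, over 50
seeded shuffles of column *g* on the evaluation partition, of the increase
in $1 - \mathrm{AUC}$ relative to the unpermuted baseline. The loss is not
prescribed by the emulated analysis; $1-\mathrm{AUC}$ matches the ROC
framing of the downstream validation. A feature constant on the partition
has importance exactly 0 (the shuffle is a no-op, and the code
short-circuits it).

Fusion proceeds exactly as: z-score importances across genes within each
model; rank models by mean absolute test-set probability residual (the
quantity the evaluation stage reports) and weight them linearly by inverse
rank, $w_m = (M - r_m + 1)/\sum (M - r + 1)$ — the emulated analysis says
only "re-weighted based on relative ranking", so the linear scheme is this
package's documented choice; multiply each model column by its weight; run
PCA on the gene × model matrix (genes as observations, centered but not
re-scaled — re-scaling would undo the weights); and select, for each of
PC1–PC3, the gene with the largest absolute coordinate ("farthest along" a
PC must be sign-agnostic, because PC signs are arbitrary). A gene already
selected on an earlier component is replaced by the next largest. A
degenerate importance matrix (all genes identical) falls back to
gene-identifier order with a warning.

## Cross-cohort validation

The signature score is the mean of per-gene z-scores (single gene: that
gene's z-score); the aggregation rule was stated only as "aggregating the
expression values", so mean-of-z — scale-free across genes — is the
package's choice, and per-gene ROC curves are available by passing one
gene at a time. AUC is the Mann–Whitney estimate with half-credit for
ties; the direction is reported as stated (no silent flipping), with
`auto_direction = TRUE` replicating tools that force AUC ≥ 0.5.

Effect sizes are Hedges' *g* (small-sample-corrected standardized mean
difference, $J = 1 - 3/(4\,df - 1)$) with the standard variance
approximation; pooling is DerSimonian–Laird:
$\tau^2 = \max(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w))$, random-effect
weights $1/(v_i + \tau^2)$, normal-quantile 95% CI, and
$I^2 = \max(0, 100 (Q - (k-1))/Q)$. "Standardized mean difference" and
"random effects" were the only constraints; Hedges' *g* and DL are the
defaults of the standard meta-analysis tooling, and the tests cross-check
against metafor. With one study the pooled estimate is that study's *g*
and $\tau^2 = 0$.

## Pre-ranked enrichment

Two ranking modes feed one engine: a two-group signal-to-noise statistic
(group standard deviations floored at $\max(0.2\,|\bar x|, 0.2)$, the
usual stabilization for near-constant genes), and Spearman correlation to
a target gene computed on $\log_2(\max(x, 10^{-3}))$ — the truncation
level for "minimal expression values" was unstated, and $10^{-3}$ on the
linear scale is small enough to only affect exact zeros in practice. Ties
break by gene identifier so rankings are deterministic.

The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic with `weight_p = 1` (the classic weighted scheme;
`weight_p = 0` reduces to the unweighted KS statistic, which the tests
assert). The running sum ends at zero — both cumulative distributions
reach 1 — and the code asserts this on every call. Significance uses
gene-label permutation (resampling set-sized gene subsets from the ranked
universe) for both modes: on a pre-ranked list phenotype permutation is
unavailable, and using one scheme everywhere keeps *p*-values comparable.
$p$ is the one-sided same-sign tail frequency with add-one correction,
NES divides by the mean magnitude of same-sign null scores, and *q* is the
GSEA-style FDR from the pooled null NES, capped at 1. The enrichment
threshold follows the emulated analysis at $q < 0.25$.

## Single-cell stratification

Pseudotime is consumed as an input column — trajectory inference itself
(graph learning, root choice) is a run of external tooling, whereas the
stratification and differential logic downstream of it is the
implementable content. Strata are rank-based: the top `round(0.40 n)`
cells by target-gene expression are "high", the bottom `round(0.40 n)`
"low", the middle excluded; round-half-up makes group sizes exact and
reproducible (interpolated quantiles would not), boundary ties resolve by
stable cell-id order with a logged count, and the cut is invariant under
any strictly monotone transform of expression. Strata differential
expression is Wilcoxon (no specific single-cell test was prescribed) with
$\mathrm{log2FC} = \log_2((\bar x_{high} + \epsilon)/(\bar x_{low} +
\epsilon))$, $\epsilon = 10^{-6}$, computable separately per disease
group. The stratifying gene itself is flagged `self = TRUE` in the output:
its "up" call is guaranteed by construction and must not be read as a
finding. Cell-type fold changes use the same ε-regularized ratio of group
means on the linear scale; how the emulated analysis computed its
macrophage fold change (mean-of-normalized versus normalized-of-mean) is
unstated, and the ε-regularized mean ratio is this package's choice.

## The synthetic-data generator

`make_bulk_cohort()` draws per-gene baselines uniformly on the log2 scale
(3–8), adds one standard-normal latent factor per module scaled by its
loading (optionally shifted between groups), adds ±lfc shifts to planted
differential genes (split evenly up/down, matching the symmetric
fold-change threshold), adds Gaussian log-scale noise, and back-transforms
by $2^x - 1$ truncated at zero — so the downstream `log2(x+1)` transform
inverts the generator exactly wherever truncation does not bite. The
Gaussian-on-log-scale model is the package's choice; the emulated cohorts
state no distributional assumptions.

What the generator emulates: case/control mean shifts, block co-expression
with a known eigengene, known mixture fractions, a signature with a
controlled overlap with cohort truth, monotone pseudotime trends with
dropout. What it does not: library-size and TPM normalization artifacts,
batch effects, count noise (negative binomial), correlated background
genes, doublets or ambient RNA. Passing recovery tests therefore shows the
algorithms are correct on their stated model, not that the pipeline is
robust to every artifact of real data.

The default modular cohort (`modular_cohort_spec()`) is 2000 genes,
30 + 30 samples, five 60-gene modules at loading 0.9, noise 0.3 — the
reference configuration for the soft-threshold selection checks. The
pipeline simulation (`simulate_study()`) plants a trait-shifted 60-gene
module (shift 1.2, so module genes sit comfortably above the 0.585 call
boundary at |log2FC| ≈ 1.1), gives the first gene an additional planted
effect of 1.5 log2 units to make it the uniquely strongest candidate, and
overlaps the trained-immunity signature with the first seven module genes
— producing exactly seven hub candidates of which one is the planted
biomarker.

## Problem sizes and reproducibility

The test suite runs cohorts of 50–2000 genes and 8–60 samples, 20
end-to-end pipeline replicates, 200 enrichment-calibration replicates at
200 permutations, and 50 meta-analytic coverage replicates — sizes chosen
so the full suite completes in about a minute while leaving the stochastic
checks enough replicates for their stated tolerance bands. Every
stochastic stage takes an explicit seed; the pipeline derives per-stage
seeds deterministically from one global seed, and rerunning with an
identical configuration reproduces every artifact byte for byte (asserted
on checksummed manifests).

## Known limitations

* The dynamic tree cut is the simplified tree-shape variant; dendrograms
  with gradual, nested structure may split differently than the full
  hybrid algorithm would.
* NNLS deconvolution has no outlier robustness; heavy-tailed noise on
  signature genes propagates into fractions (the ν-SVR it replaces is less
  sensitive).
* KNN class probabilities are vote fractions and therefore coarse; its
  permutation importances are correspondingly noisy.
* The GSEA null resamples gene labels, which ignores inter-gene
  correlation; on strongly co-expressed universes its *p*-values are
  anti-conservative, a known property of gene-label permutation.
* The generator's background genes are independent; module recovery on
  real data with correlated background will be harder than the planted
  benchmarks suggest.
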