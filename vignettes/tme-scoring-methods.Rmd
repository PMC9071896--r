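---
title: "Methods: tumor microenvironment scoring and its downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor microenvironment scoring and its downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmekit)
```

# Overview

`tmekit` implements a complete tumor-microenvironment (TME) scoring
pipeline for bulk expression cohorts with survival data, together with
the mutation-spectrum and association analyses that are usually run
alongside it. The stages are:

1. **Deconvolution** — estimate per-sample immune-cell fractions from
   bulk expression against an LM22-style signature matrix
   (`estimate_fractions()`), plus marker-set abundance scores
   (`mcp_abundance()`).
2. **TME clusters** — choose the number of clusters with the
   within-cluster sum of squares elbow and the gap statistic
   (`select_k()`), assign stable labels by consensus k-means
   (`consensus_cluster()`), and test the cluster–survival association
   (`cluster_survival()`).
3. **TMEscore** — find cluster marker genes with a moderated one-vs-rest
   t-test (`cluster_marker_genes()`), prune redundant genes with a
   random forest (`prune_redundant()`), split the survivors by the sign
   of their univariate Cox coefficient (`cox_sign_split()`), and score
   every sample (`compute_tmescore()`):
   $$\mathrm{TMEscore} = \sum_{g \in X} \log_2(x_g + 1)
                       - \sum_{g \in Y} \log_2(x_g + 1),$$
   where $X$ holds the hazard-decreasing genes and $Y$ the
   hazard-increasing ones, so a **higher score predicts better
   survival**. Samples are dichotomised at the cohort median (strictly
   above the median is "high"). Frozen signatures validate on new
   cohorts with `validate_score()`.
4. **Mutation spectrum** — MAF summaries (`summarize_maf()`), tumor
   mutation burden (`compute_tmb()`), the 96-trinucleotide-context
   catalog (`build_context_catalog()`), de novo signature extraction by
   KL-NMF (`extract_signatures()`, `select_signature_rank()`), cosine
   matching to a reference (`match_signatures()`), and per-gene
   mutation-rate comparisons (`compare_gene_mutation_rates()`).
5. **Associations** — TMEscore–TMB Spearman correlation, differential
   miRNA/mRNA/methylation features, median-split survival screening,
   DeLong comparison of response predictors, Wilcoxon group tests,
   fixed-effect pooling of hazard ratios, and the integrated landscape
   table.

Every stage is exercised end-to-end on synthetic cohorts with planted
structure (`simulate_cohort()`, `simulate_maf()`, `simulate_omics()`),
so recovery of known ground truth — not agreement with any particular
web service — is the correctness standard throughout.

# Deconvolution

`estimate_fractions()` follows the support-vector formulation of
signature-based deconvolution: the mixture sample and the signature
matrix are restricted to shared genes (at least 50% of signature genes
must be present), both are standardised by matrix-wide z-scoring, and
one linear $\nu$-regression is fit per $\nu \in \{0.25, 0.5, 0.75\}$.
The fit with the smallest root-mean-square reconstruction error wins
(ties to the smallest $\nu$); negative coefficients are clipped at zero
and renormalised to fractions summing to 1.

The published method's exact preprocessing (its quantile-normalisation
choices) is not part of this package's contract: we standardise jointly
and verify recovery of planted fractions instead — on noiseless
mixtures the mean absolute fraction error is below 0.05 and the
solution lies within 0.02 of an independent non-negative least-squares
solution. Significance is an empirical permutation p-value (the
fraction of random mixtures, values resampled from the full mixture
matrix, whose reconstruction correlation reaches the observed one,
add-one smoothed); the null is shared across samples of one matrix, as
is conventional, and its p-values are checked to be uniform under
structureless input.

# Cluster number and consensus clustering

The gap statistic compares $\log \mathrm{WSS}$ of the data against
uniform draws from the bounding box of the observed features
($n_{\mathrm{ref}} = 50$ by default) and applies the one-standard-error
rule: the chosen $k$ is the smallest one with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - \mathrm{se}(k+1)$. The raw
elbow ($k$ maximising the second difference of the WSS curve) is
reported alongside. The one-SE rule is the standard conservative
reading of "the k with the maximum gap"; both values are exposed so a
user can apply either convention.

Consensus clustering repeats k-means on random 80% subsamples
(`p_item = 0.8`, the referenced consensus-clustering convention; the
repeat count, 1000 by default, is the only parameter the source
procedure states). Each subsample is clustered with 5 k-means restarts
— a deliberate deviation from single-start convention, because a single
random start occasionally lands in a local optimum even on clearly
separated data, which would make the consensus matrix non-binary where
the structure is unambiguous. Final labels come from Ward
agglomeration (`ward.D`) of `1 - consensus` cut at $k$; ties in
agglomeration fall back to the lowest sample index (the `hclust`
convention).

# TMEscore derivation choices

Several steps of the published derivation are stated loosely; the
package fixes them as follows, each behind an explicit argument where a
user might reasonably want the other convention:

* **Marker contrasts** are one-vs-rest per cluster (the source says
  only "DEG in different samples").
* **The DEG filter** uses the Benjamini–Hochberg adjusted p (< 0.05)
  together with the strict fold-change filter
  $|\log_2 FC| > \log_2 1.5$, since the derivation prescribes BH
  adjustment; `use_adjusted = FALSE` filters on raw p instead.
* **The moderated t-test** is implemented in the package (empirical-
  Bayes shrinkage of gene variances toward a fitted scaled
  inverse-chi-square prior, moment-matched on the log variances); it
  agrees with the reference empirical-Bayes implementation to 1e-9 in
  the test suite.
* **Random-forest pruning** keeps genes whose out-of-bag permutation
  importance exceeds the mean importance (falling back to the top 10 so
  the set is never empty). The source states no rule; published gene
  counts (552 candidate, 177 retained) are data-specific outcomes, not
  contracts.
* **Cox sign split**: each gene's $\log_2(x+1)$ is z-scored before the
  univariate Cox fit. Standardisation affects the coefficient scale,
  never its sign under monotone transforms — and only the sign is
  consumed. No p-value filter is applied (the partition is by sign
  alone).
* **Direction convention**: the score formula's prose description of
  $X$ and $Y$ is ambiguous in the source; this package defines $X$ as
  the hazard-*decreasing* set so that high TMEscore means good
  prognosis, matching the reported direction of the original result.
  This is the single most consequential reading and is stated on every
  relevant help page.
* **Median ties** go to "low" (strict `>` for "high"), making the split
  deterministic.

# Mutational signatures

The 96 categories are the six pyrimidine-strand substitutions crossed
with the 16 flanking-base combinations, in COSMIC v2 row order, so
user-supplied reference matrices align by row position. Records with a
purine reference are reverse-complemented (flanks included); ambiguous
bases are skipped and counted.

Extraction minimises the generalised Kullback–Leibler divergence by
multiplicative updates — the convention of the somatic-signatures
literature, appropriate for count catalogs — with the best of 20
random restarts kept, and signature columns normalised to probability
vectors. The divergence trace is retained and checked non-increasing.

The rank is chosen by restart stability: for each candidate rank the
restarts are greedily cosine-matched to the best restart, and the rank
selected is the largest one that is *stable* (mean matched cosine
$\ge 0.90$) and *still gains structure* (relative divergence
improvement over the previous rank $\ge 5\%$). Both halves matter:
past the true rank, restarts split signatures arbitrarily and the
divergence gain collapses to the Poisson noise floor (on planted
three-signature catalogs the true-rank step gains ~30%, the step past
it ~4%); below the true rank solutions can also be unstable (forced
merges are ambiguous), so intermediate ranks are deliberately not
required to qualify. TMB is the raw per-sample record count without
per-megabase normalisation, since it is only consumed through ranks
and median splits.

# Association analyses

* The TMB + TME combined ROC predictor defaults to the sum of
  min–max-standardised components — parameter-free and monotone in both
  inputs — and can be overridden with a user-supplied vector.
* DeLong's paired AUC comparison is implemented directly (placements
  variance), which lets the degenerate self-comparison return
  $z = 0, p = 1$ exactly; it agrees with the reference implementation
  on non-degenerate inputs in the test suite.
* Survival screening uses the raw p < 0.05 convention of the source
  (with `adjust = TRUE` available), and reports which side of the
  median split lives longer.
* Wilcoxon group tests are exact for combined $n \le 20$ without ties,
  and use the normal approximation with tie and continuity correction
  otherwise.
* Hazard-ratio pooling is inverse-variance fixed-effect on the log
  scale.

# The synthetic cohorts

`simulate_cohort()` generates what the analysis assumes and nothing
more: cluster labels drawn uniformly; per-cluster mean cell-fraction
vectors as Dirichlet draws pushed toward a distinct dominant cell type
by `cluster_separation`; per-sample fractions jittered and
renormalised; expression as signature-times-fractions scaled to a
common library size, with `markers_per_cluster` planted marker genes
per cluster shifted by `de_effect_log2fc` on the log2 scale, under
multiplicative log-normal noise. Survival is exponential with
$\log h = \log h_0 + \beta z$ where $z$ is the standardised
planted-gene score (protective markers = cluster 1's, risk markers =
cluster 2's), and censoring is independent uniform, tuned by root
finding to the requested rate. The exponential/uniform choice is the
simplest model with a controllable event rate; nothing downstream
assumes more.

`simulate_maf()` draws per-sample burdens from a negative binomial,
exposures from a Dirichlet, and mutation contexts from the
exposure-weighted planted signatures, emitting each record on either
strand with probability 1/2. A requested Spearman coupling between
burden and a supplied score is imposed by Iman–Conover-style rank
reordering (exactly for $|\rho| = 1$ on tie-free draws; with tied
burdens an exact $\pm 1$ is unattainable because a reordered multiset
cannot mirror its own tie structure). `simulate_omics()` plants group
shifts in log-normal miRNA matrices and Beta-distributed methylation
matrices.

What the generators do *not* emulate: platform effects and batch
structure, gene–gene correlation beyond the mixture structure,
non-proportional hazards, subclonal mutation processes, or linkage
between omics layers beyond the stated links. Passing tests therefore
demonstrate that the algorithms recover the structure they claim to
recover — not that any particular real cohort satisfies these
assumptions.

# Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 150–300
samples, 20 seeds per stochastic claim, catalogs of 100 samples at mean
burden 200, and 20 NMF restarts per rank — sizes at which every planted
structure is comfortably identifiable while the full suite stays fast
on a single CPU. Degenerate inputs are handled explicitly: all-zero
coefficient vectors fall back to uniform fractions with a warning,
constant genes are excluded from Cox fits and screening, all-identical
samples short-circuit `select_k()` to $k = 1$, zero-variance features
are dropped before moderated tests, and a catalog with no counts is a
hard error. NMF denominators are floored at $10^{-12}$; consensus
matrices are symmetrised against floating-point asymmetry.

# Known limitations

* Deconvolution accuracy degrades, as for any signature-based method,
  when the mixture violates the signature's cell-type basis; absolute
  agreement with any web implementation is a non-goal.
* The TMEscore gene sets inherit instability from the marker and
  pruning stages on small cohorts; validation should always use the
  frozen sets (`validate_score()`), never a refit.
* The rank-selection rule assumes signatures distinct enough to
  separate (pairwise cosine well below the stability threshold);
  heavily overlapping processes can legitimately merge.
* Copy-number analysis, purity/ploidy estimation, and the computation
  of TIDE/MSI scores are out of scope; the latter are consumed as
  optional input columns.
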