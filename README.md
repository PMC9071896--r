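# tmekit

Tumor microenvironment (TME) scoring and mutational-signature analysis
for bulk expression cohorts with survival data.

Bulk tumor transcriptomes mix malignant cells with infiltrating immune
and stromal populations, and the composition of that infiltrate carries
prognostic and immunotherapy-response information that no single gene
does. `tmekit` is for researchers who want to go from an expression
matrix, clinical follow-up, and somatic mutation calls to a validated
per-sample TME score and its downstream genomic correlates, with every
stage testable against planted ground truth.

## What it computes

1. **Immune-cell fractions** by ν-support-vector regression of each
   sample on an LM22-style signature matrix (ν grid {0.25, 0.5, 0.75},
   best fit by reconstruction RMSE, coefficients clipped and
   renormalised; empirical permutation p-values), plus MCP-style
   marker-set abundances.
2. **TME clusters** from the fraction profiles: the cluster number by
   WSS elbow and gap statistic (Tibshirani one-SE rule), labels by
   consensus k-means (1000 subsamples at 80%, Ward agglomeration of
   1 − consensus), and the cluster–survival log-rank test.
3. **The TMEscore.** Cluster marker genes (moderated one-vs-rest t-test,
   BH-adjusted p < 0.05 and |log₂FC| > log₂1.5), random-forest
   redundancy pruning, then a univariate Cox fit per gene; genes with
   negative coefficients form set *X*, positive form set *Y*, and

       TMEscore = Σ_{g∈X} log2(expr_g + 1) − Σ_{g∈Y} log2(expr_g + 1)

   with a strict median split into high/low groups. Higher scores
   predict better survival by construction; frozen sets validate on new
   cohorts (log-rank p, Cox HR with 95% CI).
4. **Mutation spectrum**: MAF summaries, tumor mutation burden with
   median split, the 96-trinucleotide-context catalog (COSMIC v2
   ordering, pyrimidine-strand collapse), de novo signature extraction
   by KL-NMF with stability-based rank selection, cosine matching to a
   reference matrix, and per-gene Fisher tests between score groups.
5. **Associations**: TMEscore–TMB Spearman correlation (overall and per
   subtype), differential miRNA/mRNA/methylation features, median-split
   survival screening, ROC/DeLong comparison of TMB vs TME group vs
   their combination, Wilcoxon tests of TIDE/MSI-like scores between
   score groups, fixed-effect pooling of hazard ratios, and an
   integrated per-sample landscape table.

Synthetic generators (`simulate_cohort`, `simulate_maf`,
`simulate_omics`) produce cohorts with planted fractions, clusters,
survival axes, signatures and differential features, so the whole
pipeline runs and is benchmarked without any external data.

## Worked example

```r
library(tmekit)

sig <- synthetic_signature_matrix()                  # LM22-style reference
coh <- simulate_cohort(300, k_true = 3, signature = sig,
                       hazard_beta = -1, seed = 7)   # protective TME axis

cf <- estimate_fractions(coh$expression, sig)        # nu-SVR deconvolution
select_k(cf, k_range = 1:8, n_ref = 30, seed = 1)
#> k_selection: k_chosen = 3 (gap one-SE rule); k_elbow = 3

cm  <- consensus_cluster(cf, k = 3, n_reps = 200, seed = 1)
mk  <- cluster_marker_genes(coh$expression, cm$labels)
keep <- prune_redundant(coh$expression, cm$labels,
                        unique(mk$feature_id[mk$passes_filter]), seed = 2)
sets <- cox_sign_split(coh$expression, coh$clinical, keep)
sets
#> gene_signature_sets: |X| = 69 (hazard-decreasing), |Y| = 49 (hazard-increasing)

scores <- compute_tmescore(coh$expression, sets)
surv <- cluster_survival(setNames(scores$group, scores$sample_id), coh$clinical)
surv$p_value
#> [1] 9.968236e-24
```

The selected k = 3 recovers the planted cluster number; the log-rank
p-value says the high-TMEscore half of the cohort (which the Cox sign
convention aligns with the planted protective axis) survives
dramatically longer than the low half — the score works on a cohort
where the truth is known. On the mutation side:

```r
S <- synthetic_mutation_signatures(3, seed = 1)      # planted processes
maf <- simulate_maf(100, S, tmb_mean = 200, seed = 3)
ct  <- build_context_catalog(maf$maf)                # 96 x 100 counts
sel <- select_signature_rank(ct, ranks = 1:6, seed = 4)
sel$rank
#> [1] 3
match_signatures(sel$decompositions[[3]], S)$best_match
#>     signature   reference    cosine
#> 1 signature_1   planted_1 0.9984236
#> 2 signature_2   planted_2 0.9989937
#> 3 signature_3   planted_3 0.9983704
```

Rank scanning picks the planted number of mutational processes, and
each extracted signature matches its planted counterpart at cosine
≈ 0.998.

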