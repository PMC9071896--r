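# Synthetic cohort generators. These emulate the statistical structure the
# downstream analyses assume -- expression as mixtures of cell-type profiles
# with cluster structure, survival driven by a latent TME axis, mutation
# catalogs drawn from planted 96-context signatures -- so every pipeline
# stage can be exercised and benchmarked against known ground truth.

#' Synthetic LM22-style cell-type signature matrix
#'
#' Builds a reference expression matrix in which each cell type carries a
#' dedicated block of strongly over-expressed marker genes on top of a
#' shared log-normal baseline, the structure that makes LM22-style
#' deconvolution identifiable.
#'
#' @param n_genes total number of signature genes.
#' @param cell_types character vector of >= 2 cell-type labels.
#' @param marker_strength mean log-expression boost of a cell type's own
#'   marker block (natural-log scale).
#' @param seed integer seed.
#' @return numeric matrix, genes x cell types.
#' @export
synthetic_signature_matrix <- function(n_genes = 240,
                                       cell_types = paste0("celltype_", 1:8),
                                       marker_strength = 4,
                                       seed = 1) {
  if (length(cell_types) < 2L) stopf("need >= 2 cell types")
  withr::with_seed(seed, {
    k <- length(cell_types)
    base <- matrix(stats::rlnorm(n_genes * k, meanlog = 2, sdlog = 0.5),
                   nrow = n_genes, ncol = k)
    block <- rep_len(seq_len(k), n_genes)  # marker block assignment per gene
    boost <- stats::rlnorm(n_genes, meanlog = 2 + marker_strength, sdlog = 0.3)
    base[cbind(seq_len(n_genes), block)] <- base[cbind(seq_len(n_genes), block)] + boost
    rownames(base) <- sprintf("sig_gene_%03d", seq_len(n_genes))
    colnames(base) <- cell_types
    base
  })
}

#' Simulate an expression + survival cohort with planted TME structure
#'
#' Samples are assigned uniformly to `k_true` clusters. Each cluster has a
#' mean cell-fraction vector (a Dirichlet draw pushed towards a distinct
#' dominant cell type by `cluster_separation`); per-sample fractions are
#' the jittered cluster mean renormalised to sum 1. Expression is
#' `signature %*% t(fractions)` with each sample scaled to a common library
#' size, plus `markers_per_cluster` planted marker genes per cluster
#' (shifted by `de_effect_log2fc` on the log2 scale in their own cluster),
#' all under multiplicative log-normal noise of sd `noise_sd` (log scale).
#' Survival is exponential with
#' `log hazard = log(baseline_hazard) + hazard_beta * z`, where `z` is the
#' standardised planted-gene score (sum of `log2(x+1)` over the protective
#' markers minus the risk markers), with independent uniform censoring
#' tuned to approximately `censor_rate`.
#'
#' @param n_samples number of samples.
#' @param k_true number of planted clusters (>= 1, <= n_samples).
#' @param signature signature matrix (genes x cell types); defaults to
#'   [synthetic_signature_matrix()].
#' @param cluster_separation non-negative; how far cluster mean fraction
#'   vectors are pushed apart (0 = no structure).
#' @param de_effect_log2fc log2 shift of planted marker genes in their own
#'   cluster; 0 omits marker genes entirely (degenerate limit).
#' @param hazard_beta effect of the latent TME axis on the log hazard
#'   (negative = protective axis).
#' @param censor_rate target fraction of censored samples in `[0, 1)`.
#' @param noise_sd sd of the log-normal multiplicative noise (log scale).
#' @param markers_per_cluster planted marker genes per cluster.
#' @param baseline_hazard baseline exponential event rate (per day).
#' @param library_size per-sample total count the mixture is scaled to.
#' @param fraction_jitter sd of the additive per-sample fraction jitter.
#' @param seed integer seed; same seed reproduces the cohort exactly.
#' @return list with `expression` (matrix), `clinical` (data.frame) and
#'   `truth` (true fractions, cluster labels, protective/risk gene sets,
#'   hazard parameters).
#' @export
simulate_cohort <- function(n_samples, k_true = 3,
                            signature = synthetic_signature_matrix(),
                            cluster_separation = 3,
                            de_effect_log2fc = 2,
                            hazard_beta = -1,
                            censor_rate = 0.3,
                            noise_sd = 0.2,
                            markers_per_cluster = 10,
                            baseline_hazard = 1 / 1000,
                            library_size = 1e5,
                            fraction_jitter = 0.02,
                            seed = 1) {
  if (k_true < 1) stopf("k_true must be >= 1")
  if (k_true > n_samples) stopf("k_true (%d) exceeds n_samples (%d)", k_true, n_samples)
  if (cluster_separation < 0 || de_effect_log2fc < 0 || noise_sd < 0)
    stopf("effect sizes must be >= 0")
  validate_signature_matrix(signature)
  n_ct <- ncol(signature)
  withr::with_seed(seed, {
    labels <- sample.int(k_true, n_samples, replace = TRUE)
    # cluster mean fraction vectors: Dirichlet draws pushed apart
    dominant <- ((seq_len(k_true) - 1L) %% n_ct) + 1L
    means <- rdirichlet(k_true, rep(1, n_ct))
    for (c in seq_len(k_true)) {
      m <- means[c, ] + cluster_separation * (seq_len(n_ct) == dominant[c])
      means[c, ] <- m / sum(m)
    }
    fractions <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_ct, sd = fraction_jitter), n_samples)
    fractions <- pmax(fractions, 1e-9)
    fractions <- fractions / rowSums(fractions)
    rownames(fractions) <- sprintf("sample_%03d", seq_len(n_samples))
    colnames(fractions) <- colnames(signature)

    expr <- signature %*% t(fractions)
    expr <- sweep(expr, 2, library_size / colSums(expr), "*")

    protective <- character(0)
    risk <- character(0)
    if (de_effect_log2fc > 0) {
      mk_names <- as.vector(t(outer(seq_len(k_true), seq_len(markers_per_cluster),
                                    function(c, g) sprintf("marker_c%d_%02d", c, g))))
      mk_cluster <- rep(seq_len(k_true), each = markers_per_cluster)
      base_level <- stats::rlnorm(length(mk_names), meanlog = log(20), sdlog = 0.3)
      mk <- matrix(rep(base_level, n_samples), ncol = n_samples)
      for (j in seq_len(n_samples)) {
        up <- mk_cluster == labels[j]
        mk[up, j] <- 2^(log2p1(mk[up, j]) + de_effect_log2fc) - 1
      }
      rownames(mk) <- mk_names
      colnames(mk) <- rownames(fractions)
      expr <- rbind(expr, mk)
      if (k_true >= 2) {
        protective <- mk_names[mk_cluster == 1L]
        risk <- mk_names[mk_cluster == 2L]
      }
    }
    if (noise_sd > 0)
      expr <- expr * exp(matrix(stats::rnorm(length(expr), sd = noise_sd),
                                nrow(expr)))
    colnames(expr) <- rownames(fractions)

    # latent TME axis: planted-gene score, standardised
    if (length(protective) || length(risk)) {
      score <- colSums(log2p1(expr[protective, , drop = FALSE])) -
        colSums(log2p1(expr[risk, , drop = FALSE]))
      z <- if (stats::sd(score) > 0) as.vector(scale(score)) else rep(0, n_samples)
    } else {
      z <- rep(0, n_samples)
    }
    rate <- baseline_hazard * exp(hazard_beta * z)
    t_event <- stats::rexp(n_samples, rate = rate)
    if (censor_rate > 0) {
      cens_frac <- function(M) mean(pmin(t_event / M, 1)) - censor_rate
      M <- tryCatch(stats::uniroot(cens_frac, c(1e-6, max(t_event) * 100))$root,
                    error = function(e) max(t_event) * 2)
      t_cens <- stats::runif(n_samples, 0, M)
      os_event <- as.integer(t_event <= t_cens)
      os_time <- pmax(pmin(t_event, t_cens), 1e-6)
    } else {
      os_event <- rep(1L, n_samples)
      os_time <- pmax(t_event, 1e-6)
    }
    clinical <- data.frame(sample_id = rownames(fractions),
                           os_time = os_time, os_event = os_event,
                           stringsAsFactors = FALSE)
    list(
      expression = validate_expression_table(expr),
      clinical = validate_clinical_table(clinical),
      truth = list(true_fractions = fractions,
                   true_cluster = stats::setNames(labels, rownames(fractions)),
                   protective_genes = protective,
                   risk_genes = risk,
                   hazard_beta = hazard_beta,
                   baseline_hazard = baseline_hazard,
                   latent_axis = stats::setNames(z, rownames(fractions)))
    )
  })
}

#' Synthetic 96-context mutational signatures
#'
#' Draws sparse Dirichlet probability vectors over the 96 trinucleotide
#' substitution contexts, rejecting draws until all pairwise cosine
#' similarities fall below `max_cosine` so the planted signatures are
#' well separated (as distinct mutational processes are).
#'
#' @param n_signatures number of signatures.
#' @param concentration Dirichlet concentration (< 1 gives sparse,
#'   peaked signatures like real mutational processes).
#' @param max_cosine maximum allowed pairwise cosine similarity.
#' @param seed integer seed.
#' @return 96 x n_signatures column-stochastic matrix with context rownames.
#' @export
synthetic_mutation_signatures <- function(n_signatures = 3, concentration = 0.1,
                                          max_cosine = 0.3, seed = 1) {
  cats <- context_categories()
  withr::with_seed(seed, {
    for (try in 1:200) {
      S <- t(rdirichlet(n_signatures, rep(concentration, 96)))
      if (n_signatures == 1L) break
      cm <- cosine_matrix(S, S)
      if (max(cm[upper.tri(cm)]) <= max_cosine) break
    }
    rownames(S) <- cats
    colnames(S) <- paste0("planted_", seq_len(n_signatures))
    S
  })
}

base_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(base_complement[ch])), collapse = ""), character(1))
}

#' Simulate a MAF drawn from planted mutational signatures
#'
#' Per-sample mutation burden (TMB) is negative-binomial; per-sample
#' signature exposures are Dirichlet; each mutation draws one of the 96
#' pyrimidine-strand substitution contexts from the exposure-weighted
#' signature mixture and is emitted as a MAF record whose `ref_context`
#' and alleles realise that context on either strand with probability 1/2.
#' When `coupling_score` is supplied, TMB values are re-assigned across
#' samples (Iman-Conover style rank reordering) so that the Spearman
#' correlation between TMB and the score is approximately `coupling_rho`;
#' `|coupling_rho| = 1` is realised exactly by sorted assignment.
#'
#' @param n_samples number of samples.
#' @param true_signatures 96 x R column-stochastic matrix (tolerance 1e-6).
#' @param exposure_concentration Dirichlet concentration of exposures.
#' @param tmb_mean,tmb_dispersion negative-binomial mean and size.
#' @param coupling_score optional per-sample numeric vector to couple TMB to.
#' @param coupling_rho target Spearman correlation with `coupling_score`.
#' @param gene_pool gene symbols mutations are assigned to (uniformly).
#' @param other_class_frac fraction of extra non-SNP (Frame_Shift_Del)
#'   records sprinkled in for summary-level testing; 0 keeps SNVs only.
#' @param seed integer seed.
#' @return list with `maf` (mutation table) and `truth`
#'   (signatures, exposures, tmb per sample).
#' @export
simulate_maf <- function(n_samples, true_signatures,
                         exposure_concentration = 1,
                         tmb_mean = 200, tmb_dispersion = 10,
                         coupling_score = NULL, coupling_rho = NULL,
                         gene_pool = sprintf("GENE%02d", 1:40),
                         other_class_frac = 0,
                         seed = 1) {
  if (nrow(true_signatures) != 96L) stopf("true_signatures must have 96 rows")
  if (any(abs(colSums(true_signatures) - 1) > 1e-6))
    stopf("true_signature columns must sum to 1 (tolerance 1e-6)")
  if (tmb_mean <= 0) stopf("tmb_mean must be > 0")
  R <- ncol(true_signatures)
  cats <- context_categories()
  withr::with_seed(seed, {
    tmb <- pmax(stats::rnbinom(n_samples, mu = tmb_mean, size = tmb_dispersion), 1L)
    if (!is.null(coupling_score)) {
      if (length(coupling_score) != n_samples)
        stopf("coupling_score must have length n_samples")
      if (is.null(coupling_rho)) stopf("coupling_rho required with coupling_score")
      sorted_tmb <- sort(tmb)
      if (abs(coupling_rho) >= 1) {
        ord <- order(coupling_score, decreasing = coupling_rho < 0)
        tmb[ord] <- sorted_tmb
      } else {
        target <- coupling_rho * scale(rank(coupling_score)) +
          sqrt(1 - coupling_rho^2) * stats::rnorm(n_samples)
        tmb[order(target)] <- sorted_tmb
      }
    }
    exposures <- rdirichlet(n_samples, rep(exposure_concentration, R))
    sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
    rownames(exposures) <- sample_ids
    colnames(exposures) <- colnames(true_signatures)

    recs <- vector("list", n_samples)
    pos_counter <- 0L
    for (i in seq_len(n_samples)) {
      p <- as.vector(true_signatures %*% exposures[i, ])
      n_mut <- tmb[i]
      cat_idx <- sample.int(96L, n_mut, replace = TRUE, prob = p)
      lab <- cats[cat_idx]
      five <- substr(lab, 1L, 1L)
      ref <- substr(lab, 3L, 3L)
      alt <- substr(lab, 5L, 5L)
      three <- substr(lab, 7L, 7L)
      ctx <- paste0(five, ref, three)
      flip <- stats::runif(n_mut) < 0.5
      ctx[flip] <- revcomp(ctx[flip])
      ref[flip] <- unname(base_complement[ref[flip]])
      alt[flip] <- unname(base_complement[alt[flip]])
      pos <- pos_counter + seq_len(n_mut)
      pos_counter <- pos_counter + n_mut
      recs[[i]] <- data.frame(
        sample_id = sample_ids[i],
        gene_symbol = sample(gene_pool, n_mut, replace = TRUE),
        chromosome = "1",
        position = pos * 10L,   # spaced, synthetic coordinates
        ref_allele = ref,
        alt_allele = alt,
        variant_classification = "Missense_Mutation",
        variant_type = "SNP",
        ref_context = ctx,
        stringsAsFactors = FALSE
      )
    }
    maf <- do.call(rbind, recs)
    if (other_class_frac > 0) {
      n_extra <- ceiling(other_class_frac * nrow(maf))
      extra <- data.frame(
        sample_id = sample(sample_ids, n_extra, replace = TRUE),
        gene_symbol = sample(gene_pool, n_extra, replace = TRUE),
        chromosome = "1",
        position = (pos_counter + seq_len(n_extra)) * 10L,
        ref_allele = "AC",
        alt_allele = "-",
        variant_classification = "Frame_Shift_Del",
        variant_type = "DEL",
        ref_context = NA_character_,
        stringsAsFactors = FALSE
      )
      maf <- rbind(maf, extra)
    }
    rownames(maf) <- NULL
    list(
      maf = validate_mutation_table(maf),
      truth = list(true_signatures = true_signatures,
                   true_exposures = exposures,
                   tmb_per_sample = stats::setNames(tmb, sample_ids))
    )
  })
}

#' Simulate miRNA and methylation matrices with planted group differences
#'
#' miRNA expression is log-normal with a planted `|log2FC| = log2fc` shift
#' in a random `frac_de` subset of features; methylation beta values are
#' Beta-distributed in (0,1) with a planted between-group mean difference
#' of `delta_beta` in a `frac_dm` subset. A further `survival_link_frac`
#' subset of each matrix is flagged as survival-linked for screening tests.
#'
#' @param n_samples number of samples (must match `group_labels`).
#' @param n_features features per omics layer.
#' @param group_labels binary vector (2 distinct values) of group membership.
#' @param frac_de fraction of differentially expressed miRNA features.
#' @param log2fc planted absolute log2 fold change for DE miRNAs.
#' @param frac_dm fraction of differentially methylated sites.
#' @param delta_beta planted group difference in mean beta (< 1).
#' @param survival_link_frac fraction of features flagged survival-linked.
#' @param beta_precision precision of the Beta distribution for methylation.
#' @param seed integer seed.
#' @return list with `mirna` (matrix), `methylation` (matrix) and `truth`
#'   (de_features, dm_features, survival_linked per layer).
#' @export
simulate_omics <- function(n_samples, n_features = 200, group_labels,
                           frac_de = 0.1, log2fc = 2,
                           frac_dm = 0.1, delta_beta = 0.3,
                           survival_link_frac = 0, beta_precision = 50,
                           seed = 1) {
  if (length(group_labels) != n_samples) stopf("group_labels must match n_samples")
  if (length(unique(group_labels)) != 2L) stopf("group_labels must be binary")
  if (any(c(frac_de, frac_dm, survival_link_frac) < 0) ||
      any(c(frac_de, frac_dm, survival_link_frac) > 1))
    stopf("fractions must lie in [0, 1]")
  if (delta_beta >= 1) stopf("delta_beta must be < 1 (beta values live in (0,1))")
  g2 <- group_labels == sort(unique(group_labels))[2L]
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  withr::with_seed(seed, {
    # miRNA: log2 values Gaussian around feature baselines
    mir_ids <- sprintf("mir_%03d", seq_len(n_features))
    n_de <- round(frac_de * n_features)
    de_idx <- if (n_de > 0) sample.int(n_features, n_de) else integer(0)
    mu <- stats::runif(n_features, 3, 8)
    logv <- matrix(stats::rnorm(n_features * n_samples, mean = mu, sd = 0.5),
                   nrow = n_features)
    if (n_de > 0) {
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      logv[de_idx, g2] <- logv[de_idx, g2] + sgn * log2fc
    }
    mirna <- 2^logv - 1
    mirna[mirna < 0] <- 0
    dimnames(mirna) <- list(mir_ids, sample_ids)

    # methylation: Beta draws around group means
    cpg_ids <- sprintf("cg_%03d", seq_len(n_features))
    n_dm <- round(frac_dm * n_features)
    dm_idx <- if (n_dm > 0) sample.int(n_features, n_dm) else integer(0)
    m0 <- stats::runif(n_features, 0.15, 0.85 - delta_beta)
    m <- matrix(rep(m0, n_samples), nrow = n_features)
    if (n_dm > 0) m[dm_idx, g2] <- m[dm_idx, g2] + delta_beta
    meth <- matrix(stats::rbeta(n_features * n_samples,
                                shape1 = m * beta_precision,
                                shape2 = (1 - m) * beta_precision),
                   nrow = n_features)
    meth <- pmin(pmax(meth, 1e-6), 1 - 1e-6)
    dimnames(meth) <- list(cpg_ids, sample_ids)

    n_sl <- round(survival_link_frac * n_features)
    list(
      mirna = mirna,
      methylation = meth,
      truth = list(
        de_features = mir_ids[sort(de_idx)],
        dm_features = cpg_ids[sort(dm_idx)],
        survival_linked = list(
          mirna = if (n_sl > 0) sort(sample(mir_ids, n_sl)) else character(0),
          methylation = if (n_sl > 0) sort(sample(cpg_ids, n_sl)) else character(0)
        )
      )
    )
  })
}
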