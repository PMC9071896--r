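# Somatic mutation spectrum analysis: MAF summaries, tumor mutation
# burden, the 96-trinucleotide-context catalog (COSMIC v2 ordering),
# de novo signature extraction by Kullback-Leibler NMF with multiplicative
# updates, cosine matching to a reference signature matrix, and per-gene
# mutation-rate comparison between sample groups.

#' The 96 substitution-context categories
#'
#' Labels of the form `A[C>A]A`, ordered by substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank,
#' alphabetically -- the COSMIC v2 row convention, so user-supplied
#' reference matrices align by row order.
#'
#' @return character vector of length 96.
#' @export
context_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f5 in bases) for (f3 in bases)
    out <- c(out, sprintf("%s[%s]%s", f5, s, f3))
  out
}

purines <- c("A", "G")

# map SNP records to pyrimidine-strand context labels; returns NA for
# records containing ambiguous bases
snv_context_label <- function(ref, alt, ctx) {
  n <- nchar(ctx)
  mid <- (n + 1L) %/% 2L
  f5 <- substr(ctx, mid - 1L, mid - 1L)
  f3 <- substr(ctx, mid + 1L, mid + 1L)
  flip <- ref %in% purines
  ref2 <- ifelse(flip, unname(base_complement[ref]), ref)
  alt2 <- ifelse(flip, unname(base_complement[alt]), alt)
  f5n <- ifelse(flip, unname(base_complement[f3]), f5)
  f3n <- ifelse(flip, unname(base_complement[f5]), f3)
  lab <- sprintf("%s[%s>%s]%s", f5n, ref2, alt2, f3n)
  ok <- f5 %in% c("A", "C", "G", "T") & f3 %in% c("A", "C", "G", "T") &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  lab[!ok] <- NA_character_
  lab
}

# pyrimidine-strand substitution class of a SNP (6 classes)
snv_class <- function(ref, alt) {
  flip <- ref %in% purines
  ref2 <- ifelse(flip, unname(base_complement[ref]), ref)
  alt2 <- ifelse(flip, unname(base_complement[alt]), alt)
  paste0(ref2, ">", alt2)
}

#' Summarise a mutation table
#'
#' Deterministic count tables in the style of a MAF summary plot: variant
#' classification counts, variant type counts, the six pyrimidine-strand
#' SNV classes (a G>A counts as C>T), per-sample variant counts, and the
#' `top_n` genes ranked by the fraction of samples carrying at least one
#' mutation (ties broken alphabetically).
#'
#' @param maf mutation table from [read_maf()] or [simulate_maf()].
#' @param top_n number of top genes to report.
#' @return list with `by_classification`, `by_type`, `by_snv_class`,
#'   `per_sample`, `top_genes`.
#' @export
summarize_maf <- function(maf, top_n = 10) {
  validate_mutation_table(maf)
  if (!nrow(maf)) stopf("empty mutation table")
  by_class <- table(maf$variant_classification)
  by_type <- table(maf$variant_type)
  snp <- maf$variant_type == "SNP"
  by_snv <- if (any(snp))
    table(factor(snv_class(maf$ref_allele[snp], maf$alt_allele[snp]),
                 levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  else table(factor(character(0), levels = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  per_sample <- table(maf$sample_id)
  n_samples <- length(per_sample)
  gene_frac <- vapply(split(maf$sample_id, maf$gene_symbol),
                      function(s) length(unique(s)) / n_samples, numeric(1))
  ord <- order(-gene_frac, names(gene_frac))
  top <- data.frame(gene_symbol = names(gene_frac)[ord],
                    mutated_fraction = unname(gene_frac[ord]),
                    stringsAsFactors = FALSE)[seq_len(min(top_n, length(gene_frac))), ]
  list(by_classification = by_class, by_type = by_type,
       by_snv_class = by_snv, per_sample = per_sample, top_genes = top)
}

#' Tumor mutation burden with median split
#'
#' TMB is the total number of somatic records per sample (all variant
#' classifications, no per-megabase normalisation). Samples in the
#' optional `roster` absent from the MAF get TMB 0. The high/low split is
#' at the cohort median, strictly greater than the median being "high".
#'
#' @param maf mutation table.
#' @param roster optional character vector of sample ids that must appear
#'   in the output even with zero mutations.
#' @return data.frame with sample_id, tmb, group; median in
#'   `attr(, "median")`.
#' @export
compute_tmb <- function(maf, roster = NULL) {
  validate_mutation_table(maf)
  if (!nrow(maf)) stopf("empty mutation table")
  counts <- table(maf$sample_id)
  ids <- union(names(counts), roster)
  tmb <- stats::setNames(rep(0L, length(ids)), ids)
  tmb[names(counts)] <- as.integer(counts)
  med <- stats::median(tmb)
  data.frame(sample_id = ids, tmb = unname(tmb),
             group = ifelse(tmb > med, "high", "low"),
             stringsAsFactors = FALSE) -> out
  attr(out, "median") <- med
  out
}

#' Build the 96-context substitution catalog
#'
#' Maps every SNP to its pyrimidine-strand trinucleotide category (records
#' with a purine reference are reverse-complemented, flanks included) and
#' accumulates counts per sample. Non-SNP records are ignored; records
#' with ambiguous bases (N) are skipped and counted in
#' `attr(, "n_skipped")`.
#'
#' @param maf mutation table; every SNP needs a `ref_context` (or supply
#'   `fasta`).
#' @param fasta optional reference FASTA to fill in missing contexts.
#' @return object of class `context_catalog`: 96 x samples integer matrix
#'   with category rownames.
#' @export
build_context_catalog <- function(maf, fasta = NULL) {
  validate_mutation_table(maf)
  snp <- maf[maf$variant_type == "SNP", , drop = FALSE]
  if (!nrow(snp)) stopf("no SNP records in mutation table")
  need <- is.na(snp$ref_context)
  if (any(need)) {
    if (is.null(fasta))
      stopf("SNP record(s) lacking ref_context and no FASTA given; first: %s %s:%d",
            snp$sample_id[need][1], snp$chromosome[need][1], snp$position[need][1])
    seqs <- read_fasta_seqs(fasta)
    snp$ref_context[need] <- extract_flank_context(seqs, snp$chromosome[need],
                                                   snp$position[need])
  }
  lab <- snv_context_label(snp$ref_allele, snp$alt_allele, snp$ref_context)
  n_skipped <- sum(is.na(lab))
  keep <- !is.na(lab)
  cats <- context_categories()
  counts <- table(factor(lab[keep], levels = cats),
                  factor(snp$sample_id[keep]))
  counts <- matrix(as.integer(counts), nrow = 96,
                   dimnames = list(cats, colnames(counts)))
  structure(counts, class = c("context_catalog", class(counts)),
            n_skipped = n_skipped)
}

# KL divergence D(V || WH), with the 0 log 0 convention
kl_divergence <- function(V, WH) {
  WH <- pmax(WH, 1e-12)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

# one KL-NMF run by multiplicative updates; returns W, H, divergence and
# the per-check divergence trace (non-increasing up to float tolerance)
nmf_kl_run <- function(V, rank, max_iter, tol) {
  nr <- nrow(V); nc <- ncol(V)
  W <- matrix(stats::runif(nr * rank, 0.1, 1), nr, rank)
  H <- matrix(stats::runif(rank * nc, 0.1, 1), rank, nc)
  eps <- 1e-12
  trace <- numeric(0)
  d_prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = nr)
    if (it %% 10L == 0L || it == max_iter) {
      d <- kl_divergence(V, W %*% H)
      trace <- c(trace, d)
      if (is.finite(d_prev) && abs(d_prev - d) < tol * max(abs(d_prev), 1)) break
      d_prev <- d
    }
  }
  list(W = W, H = H, divergence = kl_divergence(V, W %*% H), trace = trace)
}

#' Extract mutational signatures by KL-NMF
#'
#' Factorises the 96 x samples count catalog as `V ~ W H`, minimising the
#' generalised Kullback-Leibler divergence by multiplicative updates
#' (the somatic-signatures convention). The best of `n_restarts` random
#' restarts by final divergence is kept; signature columns are normalised
#' to probability vectors, moving the mass into the exposures.
#'
#' @param catalog a `context_catalog` (96 x samples counts).
#' @param rank number of signatures R (>= 1); the catalog must have at
#'   least R samples with nonzero counts.
#' @param n_restarts random restarts.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative divergence change (checked every 10 iterations)
#'   below which a run stops.
#' @param seed integer seed; the whole extraction is deterministic.
#' @return object of class `signature_decomposition`: list with
#'   `signatures` (96 x R, columns sum to 1), `exposures` (R x samples,
#'   >= 0), `rank`, `divergence`, `n_restarts`, `divergence_trace` of the
#'   winning run.
#' @export
extract_signatures <- function(catalog, rank, n_restarts = 20,
                               max_iter = 2000, tol = 1e-6, seed = 1) {
  V <- unclass(catalog)
  storage.mode(V) <- "double"
  if (nrow(V) != 96L) stopf("catalog must have 96 rows")
  if (all(V == 0)) stopf("all-zero catalog")
  if (rank < 1) stopf("rank must be >= 1")
  if (sum(colSums(V) > 0) < rank)
    stopf("catalog needs >= %d samples with nonzero counts", rank)
  runs <- withr::with_seed(seed, lapply(seq_len(n_restarts), function(i)
    nmf_kl_run(V, rank, max_iter, tol)))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "divergence"))]]
  s <- colSums(best$W)
  W <- sweep(best$W, 2, s, "/")
  H <- best$H * s
  rownames(W) <- rownames(V)
  colnames(W) <- paste0("signature_", seq_len(rank))
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(V)
  structure(list(signatures = W, exposures = H, rank = rank,
                 divergence = best$divergence, n_restarts = n_restarts,
                 divergence_trace = best$trace,
                 all_restart_signatures = lapply(runs, function(r)
                   sweep(r$W, 2, pmax(colSums(r$W), 1e-12), "/"))),
            class = "signature_decomposition")
}

#' @export
print.signature_decomposition <- function(x, ...) {
  cat(sprintf("signature_decomposition: rank %d, %d samples, KL divergence %.2f (%d restarts)\n",
              x$rank, ncol(x$exposures), x$divergence, x$n_restarts))
  invisible(x)
}

#' Match extracted signatures to a reference by cosine similarity
#'
#' @param extracted a `signature_decomposition` (or 96 x R matrix).
#' @param reference 96 x M column-stochastic matrix whose rows follow
#'   [context_categories()] order.
#' @return list with `cosine` (R x M matrix) and `best_match`
#'   (data.frame: signature, reference, cosine; argmax per extracted
#'   signature, ties to the lowest reference index).
#' @export
match_signatures <- function(extracted, reference) {
  W <- if (inherits(extracted, "signature_decomposition")) extracted$signatures
       else as.matrix(extracted)
  reference <- as.matrix(reference)
  if (nrow(reference) != 96L) stopf("reference must have 96 rows")
  if (nrow(W) != 96L) stopf("extracted signatures must have 96 rows")
  cm <- cosine_matrix(W, reference)
  rownames(cm) <- colnames(W)
  colnames(cm) <- colnames(reference)
  best_idx <- apply(cm, 1, which.max)   # which.max takes the first (lowest) tie
  best <- data.frame(signature = rownames(cm),
                     reference = colnames(cm)[best_idx],
                     cosine = cm[cbind(seq_len(nrow(cm)), best_idx)],
                     stringsAsFactors = FALSE, row.names = NULL)
  list(cosine = cm, best_match = best)
}

#' Choose the NMF rank by restart stability
#'
#' Scans candidate ranks; for each, runs [extract_signatures()] and
#' measures stability as the mean greedy-matched cosine similarity of
#' every restart's signatures against the best restart's. The selected
#' rank is the largest one that is both stable (stability >=
#' `stability_min`) and still explains structure (relative KL-divergence
#' improvement over the previous rank >= `gain_min`); rank 1 is the
#' fallback when nothing qualifies. Past the true rank, restarts split
#' signatures arbitrarily (stability collapses) and the divergence gain
#' flattens to noise, which is what this rule detects; below the true
#' rank, solutions may be unstable too (forced merges are ambiguous), so
#' intermediate ranks are not required to qualify.
#'
#' @param catalog a `context_catalog`.
#' @param ranks candidate ranks (scanned in increasing order).
#' @param n_restarts restarts per rank.
#' @param stability_min minimum mean matched cosine across restarts.
#' @param gain_min minimum relative divergence improvement over rank - 1.
#' @param max_iter,tol,seed passed to [extract_signatures()]; the scan
#'   defaults are lighter than the final-extraction defaults since only
#'   the rank decision is consumed.
#' @return list with `rank` (selected), `stability`, `divergence`,
#'   `gain` (per candidate rank), and `decompositions` (one per rank).
#' @export
select_signature_rank <- function(catalog, ranks = 1:6, n_restarts = 20,
                                  stability_min = 0.9, gain_min = 0.05,
                                  max_iter = 600, tol = 1e-5, seed = 1) {
  ranks <- sort(unique(as.integer(ranks)))
  decs <- list()
  stability <- divergence <- numeric(length(ranks))
  for (i in seq_along(ranks)) {
    r <- ranks[i]
    dec <- extract_signatures(catalog, r, n_restarts = n_restarts,
                              max_iter = max_iter, tol = tol,
                              seed = seed + i)
    decs[[i]] <- dec
    divergence[i] <- dec$divergence
    sims <- vapply(dec$all_restart_signatures, function(Wr)
      mean(greedy_cosine_match(Wr, dec$signatures)$cosine), numeric(1))
    stability[i] <- mean(sims)
  }
  gain <- c(NA_real_, 1 - divergence[-1] / divergence[-length(divergence)])
  # a rank qualifies when it is itself stable and still gains structure
  # over the previous rank; ranks below the truth may legitimately be
  # unstable (merging ambiguity), so no condition is placed on them
  ok <- stability >= stability_min & (is.na(gain) | gain >= gain_min)
  qualified <- ranks[ok]
  sel <- if (length(qualified)) max(qualified) else ranks[1]
  list(rank = sel, ranks = ranks, stability = stability,
       divergence = divergence, gain = gain, decompositions = decs)
}

#' Compare per-gene mutation rates between two sample groups
#'
#' For each gene mutated in at least `min_mutated` samples, builds the
#' 2 x 2 table of mutated/unmutated samples per group and runs a
#' two-sided Fisher exact test, with Benjamini-Hochberg adjustment across
#' the tested genes.
#'
#' @param maf mutation table.
#' @param groups named character vector (sample -> "high"/"low" or any
#'   two labels) covering the cohort; both groups must be non-empty.
#' @param min_mutated genes mutated in fewer samples are skipped.
#' @return data.frame: gene_symbol, n_mutated_g1, n_mutated_g2, frac_g1,
#'   frac_g2, p_value, adj_p, ordered by p.
#' @export
compare_gene_mutation_rates <- function(maf, groups, min_mutated = 5) {
  validate_mutation_table(maf)
  if (is.null(names(groups))) stopf("groups must be named by sample id")
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L) stopf("groups must have exactly 2 levels")
  g1 <- names(groups)[groups == lev[1]]
  g2 <- names(groups)[groups == lev[2]]
  if (!length(g1) || !length(g2)) stopf("both groups must be non-empty")
  mut_by_gene <- split(maf$sample_id, maf$gene_symbol)
  res <- lapply(names(mut_by_gene), function(g) {
    mut <- unique(mut_by_gene[[g]])
    if (length(mut) < min_mutated) return(NULL)
    a <- sum(g1 %in% mut); b <- length(g1) - a
    c <- sum(g2 %in% mut); d <- length(g2) - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
    data.frame(gene_symbol = g, n_mutated_g1 = a, n_mutated_g2 = c,
               frac_g1 = a / length(g1), frac_g2 = c / length(g2),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) {
    return(data.frame(gene_symbol = character(0), n_mutated_g1 = integer(0),
                      n_mutated_g2 = integer(0), frac_g1 = numeric(0),
                      frac_g2 = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), stringsAsFactors = FALSE))
  }
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), , drop = FALSE]
}
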