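# Fixtures built in code: tiny tables written to tempfiles, a toy MAF,
# and independent oracles used across test files.

write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_expression_file <- function(values = matrix(c(1, 3, 5, 2, 4, 6), nrow = 3),
                                genes = c("g1", "g2", "g3"),
                                samples = c("s1", "s2"), env = parent.frame()) {
  df <- data.frame(gene_id = genes, values, check.names = FALSE)
  colnames(df)[-1] <- samples
  path <- file.path(withr::local_tempdir(.local_envir = env), "expr.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_maf <- function() {
  data.frame(
    sample_id = c("tA", "tA", "tB", "tB"),
    gene_symbol = c("PIK3CA", "TP53", "PIK3CA", "TTN"),
    chromosome = "1",
    position = c(10L, 20L, 30L, 40L),
    ref_allele = c("C", "G", "T", "AC"),
    alt_allele = c("T", "A", "A", "-"),
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Frame_Shift_Del"),
    variant_type = c("SNP", "SNP", "SNP", "DEL"),
    ref_context = c("ACA", "TGC", "ATA", NA),
    stringsAsFactors = FALSE
  )
}

toy_maf_file <- function(env = parent.frame()) {
  maf <- toy_maf()
  df <- data.frame(
    Hugo_Symbol = maf$gene_symbol,
    Tumor_Sample_Barcode = maf$sample_id,
    Chromosome = maf$chromosome,
    Start_Position = maf$position,
    Reference_Allele = maf$ref_allele,
    Tumor_Seq_Allele2 = maf$alt_allele,
    Variant_Classification = maf$variant_classification,
    Variant_Type = maf$variant_type,
    stringsAsFactors = FALSE
  )
  path <- file.path(withr::local_tempdir(.local_envir = env), "toy.maf")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

small_signature <- function(seed = 1) {
  synthetic_signature_matrix(n_genes = 120,
                             cell_types = paste0("ct", 1:5), seed = seed)
}

# ---- independent oracles -------------------------------------------------

# brute-force Benjamini-Hochberg step-up
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}

# exhaustive pair-counting AUC
pair_count_auc_oracle <- function(response, predictor) {
  pos <- predictor[response == 1]
  neg <- predictor[response == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed)
wilcoxon_enum_oracle <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(all_v), nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # group 1 size
  n <- c + d          # group 2 size
  k <- a + c          # total mutated
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-rolled two-group log-rank chi-square
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi2 = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}
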