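test_that("moderated one-vs-rest tests find planted markers and respect the strict filters", {
  sig <- small_signature()
  # planted markers across several seeds: high sensitivity, controlled FPR
  sens <- fpr <- numeric(0)
  for (s in 1:8) {
    coh <- simulate_cohort(60, k_true = 3, signature = sig,
                           de_effect_log2fc = 2, seed = s)
    truth_markers <- grep("^marker_", rownames(coh$expression), value = TRUE)
    mk <- cluster_marker_genes(coh$expression, coh$truth$true_cluster)
    hit <- unique(mk$feature_id[mk$passes_filter])
    sens <- c(sens, mean(truth_markers %in% hit))
    # null genes here = non-marker, non-signature-block genes are not clean
    # nulls (cluster fractions shift signature genes); use a label-free
    # cohort for the FPR instead
    coh0 <- simulate_cohort(60, k_true = 1, signature = sig,
                            de_effect_log2fc = 0, seed = s + 100)
    fake_labels <- rep(1:3, length.out = 60)
    mk0 <- cluster_marker_genes(coh0$expression,
                                setNames(fake_labels, colnames(coh0$expression)))
    fpr <- c(fpr, mean(mk0$passes_filter))
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fpr), 0.01)
})

test_that("marker filter boundaries are strict and null genes never pass", {
  # 20 samples, 2 clusters; gene 'fc15' has fold change exactly 1.5 with
  # tiny within-group variance -> must fail the strict |log2FC| filter
  set.seed(1)
  n <- 20
  labels <- rep(c("c1", "c2"), each = n / 2)
  base <- matrix(rlnorm(50 * n, 3, 0.5), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:n)))
  fc15 <- 2^(ifelse(labels == "c1", log2(16) + log2(1.5), log2(16))) - 1
  flat <- rep(7, n)
  expr <- rbind(base, fc15 = fc15 + abs(rnorm(n, 0, 1e-4)), flat = flat)
  expr <- expr[, ] + 0  # keep matrix type
  expect_warning(mk <- cluster_marker_genes(expr, setNames(labels, colnames(expr))),
                 "zero-variance")
  fc_row <- mk[mk$feature_id == "fc15" & mk$contrast == "c1_vs_rest", ]
  expect_false(fc_row$passes_filter)          # |log2fc| not > log2(1.5)
  expect_equal(fc_row$log2fc, log2(1.5), tolerance = 1e-3)
  expect_false("flat" %in% mk$feature_id)     # zero-variance gene excluded
  # identical group means: log2fc ~ 0, cannot pass
  null_rows <- mk[mk$feature_id == "g01", ]
  expect_true(all(!null_rows$passes_filter))
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  set.seed(7)
  mat <- matrix(rnorm(200 * 12), nrow = 200)
  rownames(mat) <- paste0("g", 1:200)
  grp <- rep(c(TRUE, FALSE), each = 6)
  ours <- tmekit:::moderated_t_rows(mat, grp)
  design <- cbind(1, grp)
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(unname(ours$t), unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(unname(ours$p_value), unname(fit$p.value[, 2]), tolerance = 1e-9)
})

test_that("random-forest pruning keeps informative genes, drops noise, and is seeded", {
  sig <- small_signature()
  coh <- simulate_cohort(120, k_true = 3, signature = sig,
                         de_effect_log2fc = 3, markers_per_cluster = 2,
                         seed = 2)
  informative <- grep("^marker_", rownames(coh$expression), value = TRUE)[1:5]
  set.seed(3)
  noise <- matrix(rlnorm(50 * 120, 3, 1), nrow = 50,
                  dimnames = list(sprintf("noise%02d", 1:50),
                                  colnames(coh$expression)))
  expr <- rbind(coh$expression[informative, , drop = FALSE], noise)
  keep <- prune_redundant(expr, coh$truth$true_cluster,
                          c(informative, rownames(noise)),
                          n_trees = 300, seed = 2)
  expect_true(all(informative %in% keep))
  expect_lte(sum(rownames(noise) %in% keep), 8)
  # duplicate copies of an informative gene: at least one copy retained
  expr_dup <- rbind(expr, dup_copy = expr[informative[1], ])
  keep_dup <- prune_redundant(expr_dup, coh$truth$true_cluster,
                              c(informative, rownames(noise), "dup_copy"),
                              n_trees = 300, seed = 2)
  expect_true(any(c(informative[1], "dup_copy") %in% keep_dup))
  # seeded determinism
  keep2 <- prune_redundant(expr, coh$truth$true_cluster,
                           c(informative, rownames(noise)),
                           n_trees = 300, seed = 2)
  expect_identical(keep, keep2)
  # fewer candidates than classes: all retained with warning
  expect_warning(k3 <- prune_redundant(expr, coh$truth$true_cluster,
                                       informative[1:2], n_trees = 50),
                 "fewer candidates")
  expect_identical(k3, informative[1:2])
})

test_that("Cox sign split sends protective genes to X and handles edge cases", {
  sig <- small_signature()
  coh <- simulate_cohort(300, k_true = 3, signature = sig, hazard_beta = -1,
                         seed = 7)
  genes <- c(coh$truth$protective_genes, coh$truth$risk_genes)
  sets <- cox_sign_split(coh$expression, coh$clinical, genes)
  expect_gte(mean(coh$truth$protective_genes %in% sets$set_X), 0.7)
  expect_gte(mean(coh$truth$risk_genes %in% sets$set_Y), 0.7)
  expect_length(intersect(sets$set_X, sets$set_Y), 0)
  expect_true(all(is.finite(sets$coefficients$coef)))

  # survival-independent genes: small coefficients, mean ~ 0 across seeds
  cfs <- vapply(1:10, function(s) {
    coh0 <- simulate_cohort(100, k_true = 2, signature = sig,
                            hazard_beta = 0, seed = s)
    s0 <- cox_sign_split(coh0$expression, coh0$clinical,
                         rownames(coh0$expression)[1])
    s0$coefficients$coef
  }, numeric(1))
  expect_lt(abs(mean(cfs)), 0.15)

  # constant gene is excluded with a warning; no-event cohort errors
  expr <- coh$expression
  expr["sig_gene_001", ] <- 5
  expect_warning(s2 <- cox_sign_split(expr, coh$clinical,
                                      c("sig_gene_001", genes[1])),
                 "unfittable")
  expect_false("sig_gene_001" %in% s2$coefficients$gene_id)
  cl0 <- coh$clinical
  cl0$os_event <- 0
  expect_error(cox_sign_split(coh$expression, cl0, genes[1]), "no events")
})

test_that("the TMEscore is the log2 X-sum minus Y-sum with strict median split", {
  expr <- matrix(c(3, 1, 7, 0, 1, 3, 0, 7), nrow = 4,
                 dimnames = list(c("g1", "g2", "g3", "g4"), c("s1", "s2")))
  sets <- list(set_X = "g1", set_Y = "g2")
  sc <- compute_tmescore(expr, sets)
  expect_equal(sc$tmescore[sc$sample_id == "s1"], log2(4) - log2(2))  # = 1
  # X = {g1 (3), g3 (7)}, Y = {g2 (1)} -> 2 + 3 - 1 = 4
  sc2 <- compute_tmescore(expr, list(set_X = c("g1", "g3"), set_Y = "g2"))
  expect_equal(sc2$tmescore[sc2$sample_id == "s1"], 4)
  # all-zero expression scores 0 (log2(0 + 1) = 0)
  zero <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  sc0 <- compute_tmescore(zero, sets)
  expect_true(all(sc0$tmescore == 0))
  # median ties go to "low" (strict >)
  expect_true(all(sc0$group == "low"))
  # additivity over a disjoint union of X-sets
  scA <- compute_tmescore(expr, list(set_X = "g1", set_Y = character(0)))
  scB <- compute_tmescore(expr, list(set_X = "g3", set_Y = character(0)))
  scAB <- compute_tmescore(expr, list(set_X = c("g1", "g3"), set_Y = character(0)))
  expect_equal(scAB$tmescore, scA$tmescore + scB$tmescore)
  # absent genes dropped with warning; both sets absent is an error
  expect_warning(compute_tmescore(expr, list(set_X = c("g1", "gone"), set_Y = "g2")),
                 "absent")
  expect_error(suppressWarnings(
    compute_tmescore(expr, list(set_X = "gone", set_Y = "alsogone"))), "empty")
})

test_that("frozen signatures validate on new cohorts with the expected direction", {
  sig <- small_signature()
  train <- simulate_cohort(300, k_true = 3, signature = sig, hazard_beta = -1,
                           seed = 7)
  sets <- cox_sign_split(train$expression, train$clinical,
                         c(train$truth$protective_genes, train$truth$risk_genes))
  valid <- simulate_cohort(300, k_true = 3, signature = sig, hazard_beta = -1,
                           seed = 11)
  res <- validate_score(valid$expression, valid$clinical, sets)
  expect_lt(res$logrank_p, 0.01)
  expect_lt(res$hr, 1)   # high TMEscore group has lower hazard
  # constant score: HR undefined, reported missing
  const <- valid$expression
  const[c(sets$set_X, sets$set_Y), ] <- 1
  expect_warning(r0 <- validate_score(const, valid$clinical, sets), "constant")
  expect_true(is.na(r0$hr))
})

test_that("a noise score is calibrated: ~5% of null validations reach p < 0.05", {
  sig <- small_signature()
  hits <- 0
  n_rep <- 50
  for (s in 1:n_rep) {
    coh <- simulate_cohort(80, k_true = 2, signature = sig, hazard_beta = 0,
                           de_effect_log2fc = 0, seed = 1000 + s)
    # score = a random expression gene unrelated to survival
    sets <- list(set_X = rownames(coh$expression)[s %% 50 + 1],
                 set_Y = character(0))
    sc <- compute_tmescore(coh$expression, sets)
    grp <- setNames(sc$group, sc$sample_id)
    if (length(unique(grp)) < 2) next
    p <- cluster_survival(grp, coh$clinical)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits, qbinom(0.995, n_rep, 0.05))
})
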