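mk_scores <- function(values, ids = sprintf("s%02d", seq_along(values))) {
  out <- data.frame(sample_id = ids, tmescore = values,
                    group = ifelse(values > median(values), "high", "low"),
                    stringsAsFactors = FALSE)
  class(out) <- c("tmescore_table", "data.frame")
  out
}

test_that("Spearman correlation handles perfect monotone, hand ranks, and strata", {
  sc <- mk_scores(10:1)
  tmb <- setNames(1:10, sc$sample_id)
  res <- correlate_score_tmb(sc, tmb)
  expect_equal(res$rho[res$stratum == "overall"], -1)

  # hand pairs (1,2),(2,1),(3,4),(4,3),(5,5): sum d^2 = 4, rho = 1 - 24/120
  sc5 <- mk_scores(c(1, 2, 3, 4, 5))
  tmb5 <- setNames(c(2, 1, 4, 3, 5), sc5$sample_id)
  res5 <- correlate_score_tmb(sc5, tmb5)
  expect_equal(res5$rho, 0.8)

  # invariance under strictly monotone transforms of either variable
  res5b <- correlate_score_tmb(mk_scores(exp(c(1, 2, 3, 4, 5))), tmb5^3)
  expect_equal(res5b$rho, res5$rho)

  # small strata are skipped with a warning; kept strata are reported
  subtype <- setNames(c(rep("LumA", 6), rep("Basal", 2), "Her2", "Her2"),
                      sc$sample_id)
  w <- testthat::capture_warnings(rs <- correlate_score_tmb(sc, tmb, subtype = subtype))
  expect_match(w, "skipped", all = TRUE)
  expect_length(w, 2L)   # both Basal and Her2 have < 3 pairs
  expect_true("LumA" %in% rs$stratum)
  expect_false("Basal" %in% rs$stratum)

  # zero-variance ranks give missing rho
  r0 <- correlate_score_tmb(mk_scores(rep(3, 5)), setNames(1:5, sprintf("s%02d", 1:5)))
  expect_true(is.na(r0$rho[1]))
})

test_that("the generator achieves a requested TMEscore-TMB rank coupling", {
  S3 <- synthetic_mutation_signatures(3, seed = 2)
  score <- rnorm(1000)
  sm <- simulate_maf(1000, S3, tmb_mean = 100, coupling_score = score,
                     coupling_rho = -0.44, seed = 9)
  sc <- mk_scores(score, names(sm$truth$tmb_per_sample))
  res <- correlate_score_tmb(sc, sm$truth$tmb_per_sample)
  expect_gt(res$rho[1], -0.50)
  expect_lt(res$rho[1], -0.38)
  expect_lt(res$p_value[1], 1e-10)
})

test_that("differential features detect planted signal at the strict thresholds", {
  grp <- rep(c(0, 1), each = 50)
  detected <- null_rate <- numeric(0)
  for (s in 1:5) {
    om <- simulate_omics(100, n_features = 200, group_labels = grp,
                         frac_de = 0.1, log2fc = 2, frac_dm = 0.1,
                         delta_beta = 0.3, seed = s)
    labs <- setNames(grp, colnames(om$mirna))
    de <- differential_features(om$mirna, labs, kind = "mirna")
    hit <- de$feature_id[de$passes_filter]
    detected <- c(detected, mean(om$truth$de_features %in% hit))
    null_rate <- c(null_rate,
                   mean(setdiff(de$feature_id, om$truth$de_features) %in% hit))
    dm <- differential_features(om$methylation, labs, kind = "methylation")
    expect_gte(mean(om$truth$dm_features %in% dm$feature_id[dm$passes_filter]),
               0.9)
  }
  expect_gte(mean(detected), 0.95)
  expect_lte(mean(null_rate), 0.01)
})

test_that("differential filters are strict at the boundary and empty under the null", {
  # methylation site with delta beta exactly 0.15 cannot pass
  set.seed(3)
  n <- 40
  grp <- setNames(rep(c("a", "b"), each = n / 2), paste0("s", 1:n))
  meth <- matrix(runif(20 * n, 0.3, 0.5), nrow = 20,
                 dimnames = list(sprintf("cg%02d", 1:20), names(grp)))
  meth["cg01", ] <- 0.40 + ifelse(grp == "b", 0.15, 0) + rnorm(n, 0, 1e-6)
  dm <- differential_features(meth, grp, kind = "methylation")
  row <- dm[dm$feature_id == "cg01", ]
  expect_lt(row$adj_p, 0.05)
  expect_false(row$passes_filter)   # |delta| not strictly > 0.15
  expect_equal(row$log2fc, 0.15, tolerance = 1e-5)
  # beta values outside [0,1] are a hard error
  bad <- meth; bad[1, 1] <- 1.2
  expect_error(differential_features(bad, grp, kind = "methylation"), "beta")
  # a pure-noise matrix yields ~no calls after BH
  noise <- matrix(rlnorm(500 * n, 3, 1), nrow = 500)
  colnames(noise) <- names(grp)
  dn <- differential_features(noise, grp, kind = "mrna")
  expect_lte(sum(dn$passes_filter), 2)
})

test_that("survival screening flags the planted axis and stays calibrated on noise", {
  sig <- small_signature()
  coh <- simulate_cohort(300, k_true = 3, signature = sig, hazard_beta = -1,
                         seed = 7)
  planted <- colSums(log2(coh$expression[coh$truth$protective_genes, ] + 1)) -
    colSums(log2(coh$expression[coh$truth$risk_genes, ] + 1))
  feats <- rbind(planted = planted,
                 constant = rep(1, 300),
                 noise = rnorm(300))
  colnames(feats) <- coh$clinical$sample_id
  expect_warning(res <- survival_screen(feats, coh$clinical), "skipped")
  expect_false("constant" %in% res$feature_id)
  row <- res[res$feature_id == "planted", ]
  expect_lt(row$p_value, 0.01)
  expect_equal(row$direction, "high-better")

  # null calibration: raw-p pass rate of noise features ~ 5%
  set.seed(21)
  noise <- matrix(rnorm(100 * 300), nrow = 100)
  colnames(noise) <- coh$clinical$sample_id
  rownames(noise) <- paste0("n", 1:100)
  rn <- survival_screen(noise, coh$clinical)
  expect_lte(sum(rn$passes), qbinom(0.995, 100, 0.05))
  expect_gte(sum(rn$passes), qbinom(0.005, 100, 0.05))
})

test_that("AUC equals exhaustive pair counting and DeLong behaves at the edges", {
  # 6-sample hand case: 8 of 9 positive-negative pairs are concordant
  resp <- c(1, 1, 1, 0, 0, 0)
  pred <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  cmp <- compare_auc(resp, list(p = pred))
  expect_equal(unname(cmp$auc["p"]), 8 / 9)
  expect_equal(unname(cmp$auc["p"]), pair_count_auc_oracle(resp, pred))

  # rank formulation == pair counting on random small datasets (with ties)
  set.seed(4)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    r <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(unname(compare_auc(r, list(x = p))$auc["x"]),
                 pair_count_auc_oracle(r, p), tolerance = 1e-12)
  }

  # perfect predictor; self-comparison has z = 0, p = 1
  cmp2 <- compare_auc(resp, list(perfect = resp, copy = resp))
  expect_equal(unname(cmp2$auc["perfect"]), 1)
  expect_equal(cmp2$pairs$z, 0)
  expect_equal(cmp2$pairs$p_value, 1)

  # the default combined predictor appears when tmb and tme_group are given
  set.seed(5)
  resp2 <- rbinom(60, 1, 0.5)
  tmb <- rnorm(60) + resp2
  tme <- as.numeric(runif(60) < 0.3 + 0.4 * resp2)
  cmp3 <- compare_auc(resp2, list(tmb = tmb, tme_group = tme))
  expect_setequal(names(cmp3$auc), c("tmb", "tme_group", "combined"))
  expect_equal(nrow(cmp3$pairs), 3L)
  # DeLong p agrees with the reference implementation
  ref <- pROC::roc.test(pROC::roc(resp2, tmb, quiet = TRUE),
                        pROC::roc(resp2, tme, quiet = TRUE),
                        method = "delong")
  ours <- cmp3$pairs[cmp3$pairs$predictor_1 == "tmb" &
                     cmp3$pairs$predictor_2 == "tme_group", ]
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(compare_auc(rep(1, 5), list(x = rnorm(5))), "both classes")
})

test_that("rank-sum group tests are exact for small samples and sensitive to shifts", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1 by enumeration
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("lo", "hi"), each = 3)
  res <- group_score_test(vals, grp)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, wilcoxon_enum_oracle(vals[1:3], vals[4:6]))
  expect_equal(unname(res$medians), c(5, 2))

  # enumeration oracle agreement on random tie-free draws (n <= 12)
  set.seed(6)
  for (i in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- sample(100, nx); y <- sample(200:300, ny) / 7
    ours <- group_score_test(c(x, y), rep(c("a", "b"), c(nx, ny)))
    expect_equal(ours$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }

  # identical distributions: p = 1; large planted shift: tiny p
  same <- group_score_test(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  set.seed(7)
  big <- group_score_test(c(rnorm(200), rnorm(200, 2)),
                          rep(c("a", "b"), each = 200))
  expect_lt(big$p_value, 1e-10)
  expect_error(group_score_test(1:3, rep("a", 3)), "2 levels")
})

test_that("fixed-effect pooling reproduces identities, symmetry, and hand arithmetic", {
  one <- pool_hazard_ratios(data.frame(log_hr = 0.3, se = 0.1))
  expect_equal(one$hr, exp(0.3))
  sym <- pool_hazard_ratios(data.frame(log_hr = c(0.4, -0.4), se = c(0.2, 0.2)))
  expect_equal(sym$hr, 1)
  # weights 100, 25, 11.1: pooled = sum(w x)/sum(w)
  hand <- pool_hazard_ratios(data.frame(log_hr = c(0.2, 0.4, 0.6),
                                        se = c(0.1, 0.2, 0.3)))
  w <- 1 / c(0.1, 0.2, 0.3)^2
  expect_equal(hand$log_hr, sum(w * c(0.2, 0.4, 0.6)) / sum(w), tolerance = 1e-12)
  expect_equal(hand$log_hr, 0.26939, tolerance = 1e-4)
  # agreement with the reference meta-analysis implementation
  ref <- metafor::rma(yi = c(0.2, 0.4, 0.6), sei = c(0.1, 0.2, 0.3),
                      method = "FE")
  expect_equal(hand$log_hr, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(hand$se, ref$se, tolerance = 1e-10)
  # k identical inputs pool to the same estimate with se / sqrt(k)
  rep4 <- pool_hazard_ratios(data.frame(log_hr = rep(0.3, 4), se = rep(0.2, 4)))
  expect_equal(rep4$log_hr, 0.3)
  expect_equal(rep4$se, 0.2 / 2)
  expect_error(pool_hazard_ratios(data.frame(log_hr = 1, se = 0)), "se")
})

test_that("the landscape table left-joins on the score ids and orders by score", {
  sc <- mk_scores(c(2, 1, 3), c("a", "b", "c"))
  clin <- data.frame(sample_id = c("a", "b", "c"), os_time = c(10, 20, 30),
                     os_event = c(1, 0, 1), stage = c("II", "I", "III"))
  tmb <- data.frame(sample_id = c("a", "c"), tmb = c(5L, 9L))
  maf <- toy_maf(); maf$sample_id <- c("a", "a", "c", "c")
  ls <- assemble_landscape(sc, clin, tmb = tmb, maf = maf,
                           genes = c("PIK3CA", "TTN"))
  expect_equal(ls$sample_id, c("c", "a", "b"))       # descending tmescore
  expect_true(is.na(ls$tmb[ls$sample_id == "b"]))    # missing, not imputed
  expect_equal(ls$mut_PIK3CA, c(1L, 1L, 0L))
  expect_equal(ls$mut_TTN[ls$sample_id == "c"], 1L)
  dup <- rbind(tmb, tmb[1, ])
  expect_error(assemble_landscape(sc, clin, tmb = dup), "duplicated")
})
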