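# TMEscore derivation: cluster marker genes (moderated t, one-vs-rest),
# random-forest redundancy pruning, partition of the survivors by the sign
# of their univariate Cox coefficient, and the per-sample score
#   TMEscore = sum_{g in X} log2(expr_g + 1) - sum_{g in Y} log2(expr_g + 1)
# with X the hazard-decreasing and Y the hazard-increasing gene set, so a
# higher score predicts better survival. Samples are dichotomised at the
# cohort median (strictly greater than the median -> "high").

#' Cluster marker genes by moderated one-vs-rest tests
#'
#' For every cluster, each gene is tested cluster-vs-rest on
#' `log2(expr + 1)` with an empirical-Bayes moderated t-test;
#' Benjamini-Hochberg adjustment is applied across genes within each
#' contrast. A gene passes when `adj_p < p_thresh` and
#' `|log2FC| > log2(fc_thresh)` (both strict). Set `use_adjusted = FALSE`
#' to filter on raw p instead.
#'
#' @param expression expression matrix (genes x samples, linear scale).
#' @param labels per-sample cluster labels (named by sample id or in
#'   column order); >= 2 clusters with >= 3 samples each.
#' @param p_thresh significance threshold (default 0.05).
#' @param fc_thresh fold-change threshold on the linear scale
#'   (default 1.5, i.e. |log2FC| > log2(1.5)).
#' @param use_adjusted filter on BH-adjusted p (default) or raw p.
#' @return data.frame with feature_id, contrast, log2fc, p_value, adj_p,
#'   passes_filter; one row per gene per contrast.
#' @export
cluster_marker_genes <- function(expression, labels, p_thresh = 0.05,
                                 fc_thresh = 1.5, use_adjusted = TRUE) {
  validate_expression_table(expression)
  labels <- align_labels(labels, colnames(expression))
  tab <- table(labels)
  if (length(tab) < 2L) stopf("need >= 2 clusters")
  if (any(tab < 3L)) stopf("every cluster needs >= 3 samples")
  logm <- log2p1(expression)
  v <- apply(logm, 1, stats::var)
  if (any(v == 0)) {
    warnf("excluding %d zero-variance gene(s)", sum(v == 0))
    logm <- logm[v > 0, , drop = FALSE]
  }
  out <- lapply(names(tab), function(cl) {
    grp <- labels == cl
    tt <- moderated_t_rows(logm, grp)
    adj <- stats::p.adjust(tt$p_value, method = "BH")
    keep_p <- if (use_adjusted) adj else tt$p_value
    data.frame(feature_id = rownames(tt),
               contrast = paste0(cl, "_vs_rest"),
               log2fc = tt$effect,
               p_value = tt$p_value,
               adj_p = adj,
               passes_filter = keep_p < p_thresh &
                 abs(tt$effect) > log2(fc_thresh),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stopf("labels missing for sample(s): %s",
            paste(utils::head(missing, 5L), collapse = ", "))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stopf("unnamed labels must match the number of samples")
  }
  as.character(labels)
}

#' Prune redundant candidate genes with a random forest
#'
#' Fits a random-forest classifier of cluster label on `log2(expr + 1)`
#' over the candidate genes and computes out-of-bag permutation
#' importance. Genes with importance strictly above the mean importance
#' are retained; if that set is empty the top 10 genes by importance are
#' kept instead, so the retained set is never empty.
#'
#' @param expression expression matrix (genes x samples, linear scale).
#' @param labels per-sample cluster labels.
#' @param candidate_genes genes to consider (subset of rownames).
#' @param n_trees number of trees.
#' @param seed integer seed (forest growth is seeded).
#' @return character vector of retained gene ids.
#' @export
prune_redundant <- function(expression, labels, candidate_genes,
                            n_trees = 500, seed = 1) {
  validate_expression_table(expression)
  labels <- align_labels(labels, colnames(expression))
  missing <- setdiff(candidate_genes, rownames(expression))
  if (length(missing))
    stopf("candidate gene(s) not in expression: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  y <- factor(labels)
  if (length(candidate_genes) < nlevels(y)) {
    warnf("fewer candidates (%d) than classes (%d); retaining all",
          length(candidate_genes), nlevels(y))
    return(candidate_genes)
  }
  X <- t(log2p1(expression[candidate_genes, , drop = FALSE]))
  colnames(X) <- make.names(candidate_genes)   # forest needs syntactic names
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(rf, type = 1)[, 1]
  keep <- imp > mean(imp)
  retained <- candidate_genes[keep]
  if (!length(retained))
    retained <- candidate_genes[order(imp, decreasing = TRUE)][seq_len(min(10, length(imp)))]
  retained
}

#' Partition genes by the sign of their univariate Cox coefficient
#'
#' Each gene's `log2(expr + 1)`, z-scored across samples, enters a
#' univariate Cox proportional-hazards fit against overall survival.
#' Genes with a negative coefficient (hazard-decreasing) form `set_X`;
#' positive coefficients (hazard-increasing) form `set_Y`. Constant,
#' non-converging, or exactly-zero-coefficient genes are excluded with a
#' warning.
#'
#' @param expression expression matrix (genes x samples, linear scale).
#' @param clinical clinical table with os_time/os_event.
#' @param genes genes to fit (present in expression).
#' @return object of class `gene_signature_sets`: list with `set_X`,
#'   `set_Y` and `coefficients` (data.frame gene_id, coef, p_wald, set).
#' @export
cox_sign_split <- function(expression, clinical, genes) {
  validate_expression_table(expression)
  clinical <- validate_clinical_table(clinical)
  shared <- intersect(clinical$sample_id, colnames(expression))
  if (length(shared) < 3L) stopf("too few shared samples between expression and clinical")
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  if (sum(clinical$os_event) == 0) stopf("no events in clinical data")
  if (sum(clinical$os_event) < 10)
    warnf("only %d events; Cox coefficients will be unstable", sum(clinical$os_event))
  missing <- setdiff(genes, rownames(expression))
  if (length(missing))
    stopf("gene(s) not in expression: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  surv <- survival::Surv(clinical$os_time, clinical$os_event)
  res <- lapply(genes, function(g) {
    x <- log2p1(expression[g, shared])
    if (stats::sd(x) == 0) return(NULL)
    z <- as.vector(scale(x))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ z)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) return(NULL)
    cf <- unname(stats::coef(fit))
    if (cf == 0) return(NULL)
    data.frame(gene_id = g, coef = cf,
               p_wald = summary(fit)$coefficients[1, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  dropped <- genes[vapply(res, is.null, logical(1))]
  if (length(dropped))
    warnf("excluding %d unfittable gene(s): %s", length(dropped),
          paste(utils::head(dropped, 5L), collapse = ", "))
  coefs <- do.call(rbind, res)
  if (is.null(coefs) || !nrow(coefs)) stopf("no gene produced a finite Cox coefficient")
  coefs$set <- ifelse(coefs$coef < 0, "X", "Y")
  structure(list(set_X = coefs$gene_id[coefs$set == "X"],
                 set_Y = coefs$gene_id[coefs$set == "Y"],
                 coefficients = coefs),
            class = "gene_signature_sets")
}

#' @export
print.gene_signature_sets <- function(x, ...) {
  cat(sprintf("gene_signature_sets: |X| = %d (hazard-decreasing), |Y| = %d (hazard-increasing)\n",
              length(x$set_X), length(x$set_Y)))
  invisible(x)
}

#' Compute the per-sample TMEscore
#'
#' `TMEscore = sum over set_X of log2(expr + 1) - sum over set_Y of
#' log2(expr + 1)`. Samples are split at the cohort median of the score:
#' strictly greater than the median is "high", ties and below are "low".
#' Set genes absent from the expression matrix are dropped with a warning;
#' both sets empty after intersection is an error.
#'
#' @param expression expression matrix (genes x samples, linear scale).
#' @param sets a `gene_signature_sets` object (or list with set_X/set_Y).
#' @return data.frame (class `tmescore_table`) with sample_id, tmescore,
#'   group; the median used for the split is in `attr(, "median")`.
#' @export
compute_tmescore <- function(expression, sets) {
  validate_expression_table(expression)
  x_genes <- intersect(sets$set_X, rownames(expression))
  y_genes <- intersect(sets$set_Y, rownames(expression))
  n_drop <- length(sets$set_X) + length(sets$set_Y) - length(x_genes) - length(y_genes)
  if (n_drop > 0) warnf("dropping %d signature gene(s) absent from expression", n_drop)
  if (!length(x_genes) && !length(y_genes))
    stopf("both gene sets empty after intersecting with expression")
  logm <- log2p1(expression)
  score <- colSums(logm[x_genes, , drop = FALSE]) -
    colSums(logm[y_genes, , drop = FALSE])
  med <- stats::median(score)
  out <- data.frame(sample_id = colnames(expression),
                    tmescore = unname(score),
                    group = ifelse(score > med, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "median") <- med
  class(out) <- c("tmescore_table", "data.frame")
  out
}

#' Validate a frozen TMEscore signature on a new cohort
#'
#' Scores the new cohort with the frozen gene sets (no refitting), splits
#' at the new cohort's own score median, and reports the two-group
#' log-rank p and the Cox hazard ratio of high vs low with its 95%
#' confidence interval. A constant score (all samples in one group) gives
#' a missing HR with a warning.
#'
#' @param expression_new expression matrix of the validation cohort.
#' @param clinical_new clinical table of the validation cohort
#'   (>= 5 events).
#' @param sets frozen `gene_signature_sets`.
#' @return list with `scores` (tmescore_table), `logrank_p`, `hr`,
#'   `hr_ci` (length-2), and `km` step tables per group.
#' @export
validate_score <- function(expression_new, clinical_new, sets) {
  clinical_new <- validate_clinical_table(clinical_new)
  if (sum(clinical_new$os_event) < 5) stopf("validation cohort needs >= 5 events")
  scores <- compute_tmescore(expression_new, sets)
  shared <- intersect(scores$sample_id, clinical_new$sample_id)
  cl <- clinical_new[match(shared, clinical_new$sample_id), , drop = FALSE]
  sc <- scores[match(shared, scores$sample_id), , drop = FALSE]
  if (length(unique(sc$group)) < 2L) {
    warnf("constant score: all samples fall in one group; HR undefined")
    return(list(scores = scores, logrank_p = NA_real_, hr = NA_real_,
                hr_ci = c(NA_real_, NA_real_), km = NULL))
  }
  grp <- factor(sc$group, levels = c("low", "high"))
  surv <- survival::Surv(cl$os_time, cl$os_event)
  sd <- survival::survdiff(surv ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(surv ~ grp)
  hr <- unname(exp(stats::coef(cx)))
  ci <- unname(exp(stats::confint(cx)))
  km <- cluster_survival(stats::setNames(as.character(grp), sc$sample_id), cl)$km
  list(scores = scores, logrank_p = p, hr = hr, hr_ci = as.vector(ci), km = km)
}
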