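# Downstream association analyses: TMEscore vs TMB correlation,
# differential omics features between score groups, survival screening,
# ROC/DeLong comparison of immunotherapy-response predictors, rank-sum
# group tests, fixed-effect pooling of hazard ratios, and the integrated
# per-sample landscape table.

#' Spearman correlation between TMEscore and mutation burden
#'
#' Overall and, when subtype labels are given, per-subtype Spearman rank
#' correlation with two-sided p (t approximation; exact for n <= 9
#' without ties, the `cor.test` convention). Strata with fewer than 3
#' pairs are skipped with a warning; zero-variance ranks give a missing
#' rho.
#'
#' @param scores a `tmescore_table` (or data.frame sample_id/tmescore).
#' @param tmb named numeric vector of per-sample mutation counts, or the
#'   data.frame from [compute_tmb()].
#' @param subtype optional named character vector of per-sample subtype.
#' @return data.frame: stratum, n, rho, p_value.
#' @export
correlate_score_tmb <- function(scores, tmb, subtype = NULL) {
  if (is.data.frame(tmb)) tmb <- stats::setNames(tmb$tmb, tmb$sample_id)
  shared <- intersect(scores$sample_id, names(tmb))
  if (length(shared) < 3L) stopf("need >= 3 paired samples")
  s <- scores$tmescore[match(shared, scores$sample_id)]
  t_ <- tmb[shared]
  one <- function(label, x, y) {
    if (length(x) < 3L) return(NULL)
    if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
      return(data.frame(stratum = label, n = length(x), rho = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(stratum = label, n = length(x), rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- list(one("overall", s, t_))
  if (!is.null(subtype)) {
    st <- subtype[shared]
    for (lv in sort(unique(stats::na.omit(st)))) {
      sel <- !is.na(st) & st == lv
      if (sum(sel) < 3L) {
        warnf("stratum '%s' has < 3 pairs; skipped", lv)
        next
      }
      out <- c(out, list(one(lv, s[sel], t_[sel])))
    }
  }
  do.call(rbind, out)
}

#' Differential features between two sample groups
#'
#' mRNA and miRNA matrices are tested on `log2(x + 1)` with the moderated
#' t-test and filtered at `adj_p < 0.05` and `|log2FC| > 1` (strict);
#' methylation beta matrices are tested on the beta values themselves and
#' filtered at `adj_p < 0.05` and `|mean beta difference| > 0.15`
#' (strict). Benjamini-Hochberg adjustment is across all tested features.
#'
#' @param matrix feature x sample numeric matrix.
#' @param groups per-sample binary labels (named by sample id or in
#'   column order); each group needs >= 3 samples.
#' @param kind one of "mrna", "mirna", "methylation".
#' @param p_thresh adjusted-p threshold.
#' @param effect_thresh effect-size threshold; defaults to 1 (log2FC) for
#'   expression kinds and 0.15 (delta beta) for methylation.
#' @return data.frame: feature_id, log2fc (mean beta difference for
#'   methylation), p_value, adj_p, passes_filter.
#' @export
differential_features <- function(matrix, groups,
                                  kind = c("mrna", "mirna", "methylation"),
                                  p_thresh = 0.05, effect_thresh = NULL) {
  kind <- match.arg(kind)
  if (is.null(rownames(matrix))) rownames(matrix) <- paste0("f", seq_len(nrow(matrix)))
  groups <- align_labels(groups, colnames(matrix))
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stopf("groups must have exactly 2 levels")
  if (any(table(groups) < 3L)) stopf("each group needs >= 3 samples")
  if (kind == "methylation") {
    if (any(matrix < 0 | matrix > 1))
      stopf("methylation beta values must lie in [0, 1]")
    mat <- matrix
    if (is.null(effect_thresh)) effect_thresh <- 0.15
  } else {
    mat <- log2p1(matrix)
    if (is.null(effect_thresh)) effect_thresh <- 1
  }
  v <- apply(mat, 1, stats::var)
  if (any(v == 0)) {
    warnf("excluding %d zero-variance feature(s)", sum(v == 0))
    mat <- mat[v > 0, , drop = FALSE]
  }
  grp <- groups == lev[2]   # effect = second level minus first
  tt <- moderated_t_rows(mat, grp)
  adj <- stats::p.adjust(tt$p_value, method = "BH")
  data.frame(feature_id = rownames(tt),
             log2fc = tt$effect,
             p_value = tt$p_value,
             adj_p = adj,
             passes_filter = adj < p_thresh & abs(tt$effect) > effect_thresh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen features for survival association by median split
#'
#' Each feature's samples are split at the feature's median (strictly
#' greater -> "high") and tested with the two-group log-rank test.
#' Constant features, or features whose split leaves a group empty, are
#' skipped with a warning. The reported direction says which side lives
#' longer (fewer events than expected under the null).
#'
#' @param features feature x sample numeric matrix.
#' @param clinical clinical table (>= 10 events).
#' @param p_thresh raw-p pass threshold (default 0.05).
#' @param adjust apply BH across features and threshold the adjusted p
#'   instead (off by default, matching the screening convention).
#' @return data.frame: feature_id, p_value, direction
#'   ("high-better"/"low-better"), passes.
#' @export
survival_screen <- function(features, clinical, p_thresh = 0.05,
                            adjust = FALSE) {
  clinical <- validate_clinical_table(clinical)
  shared <- intersect(colnames(features), clinical$sample_id)
  if (length(shared) < 4L) stopf("too few shared samples")
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  features <- features[, shared, drop = FALSE]
  if (sum(clinical$os_event) < 10) stopf("need >= 10 events for screening")
  surv <- survival::Surv(clinical$os_time, clinical$os_event)
  res <- lapply(rownames(features), function(f) {
    x <- features[f, ]
    grp <- x > stats::median(x)
    if (length(unique(grp)) < 2L) return(NULL)
    sd <- survival::survdiff(surv ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    # second stratum is grp=TRUE (the high side)
    direction <- if (sd$obs[2] < sd$exp[2]) "high-better" else "low-better"
    data.frame(feature_id = f, p_value = p, direction = direction,
               stringsAsFactors = FALSE)
  })
  skipped <- vapply(res, is.null, logical(1))
  if (any(skipped))
    warnf("skipped %d constant/degenerate feature(s)", sum(skipped))
  res <- do.call(rbind, res)
  if (is.null(res)) stopf("no screenable features")
  if (adjust) {
    res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
    res$passes <- res$adj_p < p_thresh
  } else {
    res$passes <- res$p_value < p_thresh
  }
  res
}

# AUC by the rank (Mann-Whitney) formulation with tie correction
rank_auc <- function(response, predictor) {
  r <- rank(predictor)
  n1 <- sum(response == 1)
  n0 <- sum(response == 0)
  (sum(r[response == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong covariance machinery: placements per predictor
delong_placements <- function(response, predictor) {
  pos <- predictor[response == 1]
  neg <- predictor[response == 0]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare predictors of immunotherapy response by ROC AUC (DeLong)
#'
#' Computes the AUC of each predictor by the rank formulation (equivalent
#' to the Mann-Whitney statistic, with ties handled by average ranks) and
#' the paired DeLong two-sided z-test for every predictor pair. The
#' default combined predictor is the sum of the min-max-standardised TMB
#' and TME-group indicator; supply a `combined` element to override it.
#'
#' @param response per-sample binary response (0/1); both classes present.
#' @param predictors named list of per-sample numeric predictors, e.g.
#'   `list(tmb = ..., tme_group = ...)`; an element named `combined` is
#'   used as-is, otherwise one is built from `tmb` and `tme_group`.
#' @return object of class `auc_comparison`: list with `auc` (named
#'   vector) and `pairs` (data.frame predictor_1, predictor_2, z,
#'   p_value).
#' @export
compare_auc <- function(response, predictors) {
  response <- as.integer(response)
  if (!all(response %in% c(0L, 1L))) stopf("response must be binary 0/1")
  if (length(unique(response)) < 2L) stopf("response needs both classes")
  if (is.null(names(predictors))) stopf("predictors must be a named list")
  minmax <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  if (!"combined" %in% names(predictors) &&
      all(c("tmb", "tme_group") %in% names(predictors))) {
    predictors$combined <- minmax(predictors$tmb) + minmax(predictors$tme_group)
  }
  bad <- vapply(predictors, function(p) length(p) != length(response), logical(1))
  if (any(bad)) stopf("predictor(s) not aligned to response: %s",
                      paste(names(predictors)[bad], collapse = ", "))
  pl <- lapply(predictors, function(p) delong_placements(response, p))
  auc <- vapply(pl, `[[`, numeric(1), "auc")
  # sanity: placements mean equals the rank formulation
  n1 <- sum(response == 1); n0 <- sum(response == 0)
  nm <- names(predictors)
  pairs <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    d10 <- pl[[i]]$v10 - pl[[j]]$v10
    d01 <- pl[[i]]$v01 - pl[[j]]$v01
    v <- stats::var(pl[[i]]$v10 - pl[[j]]$v10) / n1 +
      stats::var(pl[[i]]$v01 - pl[[j]]$v01) / n0
    dauc <- auc[i] - auc[j]
    if (!is.finite(v) || v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- dauc / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      predictor_1 = nm[i], predictor_2 = nm[j], z = z, p_value = p,
      stringsAsFactors = FALSE)
  }
  structure(list(auc = auc, pairs = do.call(rbind, pairs)),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("AUC:\n")
  print(round(x$auc, 4))
  cat("pairwise DeLong tests:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test between score groups
#'
#' Exact p for combined n <= 20 without ties; normal approximation with
#' tie and continuity correction otherwise. Group medians are reported.
#'
#' @param values per-sample numeric values (e.g. TIDE or MSI scores).
#' @param grouping per-sample binary labels aligned with `values`.
#' @return list with `p_value`, `medians` (named), `method`.
#' @export
group_score_test <- function(values, grouping) {
  lev <- sort(unique(as.character(grouping)))
  if (length(lev) != 2L) stopf("grouping must have exactly 2 levels")
  x <- values[grouping == lev[1]]
  y <- values[grouping == lev[2]]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  n <- length(x) + length(y)
  use_exact <- n <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  list(p_value = wt$p.value,
       medians = stats::setNames(c(stats::median(x), stats::median(y)), lev),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Fixed-effect pooling of hazard ratios
#'
#' Inverse-variance pooling on the log-HR scale;
#' `CI = pooled log-HR +/- 1.96 * pooled se`, exponentiated.
#'
#' @param per_dataset data.frame (or list of lists) with columns/elements
#'   `log_hr` and `se`; every `se` must be finite and > 0.
#' @return list with `hr`, `ci` (length 2), `log_hr`, `se`.
#' @export
pool_hazard_ratios <- function(per_dataset) {
  if (!is.data.frame(per_dataset))
    per_dataset <- do.call(rbind, lapply(per_dataset, as.data.frame))
  if (!nrow(per_dataset)) stopf("need >= 1 dataset")
  if (anyNA(per_dataset$se) || any(!is.finite(per_dataset$se)) ||
      any(per_dataset$se <= 0))
    stopf("every se must be finite and > 0")
  w <- 1 / per_dataset$se^2
  lhr <- sum(w * per_dataset$log_hr) / sum(w)
  se <- sqrt(1 / sum(w))
  list(hr = exp(lhr), ci = exp(lhr + c(-1.96, 1.96) * se),
       log_hr = lhr, se = se)
}

#' Assemble the integrated per-sample landscape table
#'
#' Left-joins clinical covariates, TMB and per-gene mutation indicators
#' onto the score table (keyed by its sample ids), never imputing missing
#' covariates, and orders rows by descending TMEscore.
#'
#' @param scores a `tmescore_table`.
#' @param clinical clinical table.
#' @param tmb optional data.frame from [compute_tmb()] or named vector.
#' @param maf optional mutation table for gene indicator columns.
#' @param genes genes to add 0/1 mutation indicator columns for.
#' @param extra_columns optional data.frame with a sample_id column of
#'   additional covariates.
#' @return data.frame ordered by descending tmescore.
#' @export
assemble_landscape <- function(scores, clinical, tmb = NULL, maf = NULL,
                               genes = NULL, extra_columns = NULL) {
  out <- as.data.frame(scores)[, c("sample_id", "tmescore", "group")]
  if (anyDuplicated(out$sample_id)) stopf("duplicated sample id in scores")
  join <- function(out, df, what) {
    if (anyDuplicated(df$sample_id))
      stopf("duplicated sample id in %s", what)
    merge(out, df, by = "sample_id", all.x = TRUE, sort = FALSE)
  }
  out <- join(out, validate_clinical_table(clinical), "clinical")
  if (!is.null(tmb)) {
    if (!is.data.frame(tmb))
      tmb <- data.frame(sample_id = names(tmb), tmb = unname(tmb),
                        stringsAsFactors = FALSE)
    out <- join(out, tmb[, c("sample_id", "tmb")], "tmb")
  }
  if (!is.null(maf) && length(genes)) {
    for (g in genes) {
      mut <- unique(maf$sample_id[maf$gene_symbol == g])
      out[[paste0("mut_", g)]] <- as.integer(out$sample_id %in% mut)
    }
  }
  if (!is.null(extra_columns)) out <- join(out, extra_columns, "extra_columns")
  out[order(-out$tmescore), , drop = FALSE]
}
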