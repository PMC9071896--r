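# TME cluster discovery from cell-fraction profiles: cluster-number
# selection (within-cluster sum of squares elbow + gap statistic with the
# one-standard-error rule) and consensus k-means clustering, plus the
# cluster-survival association test.

kmeans_wss <- function(x, k, n_restarts) {
  if (k >= nrow(unique(x))) return(0)  # every distinct point its own center
  if (k == 1L) return(sum(scale(x, scale = FALSE)^2))
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = n_restarts,
                                       iter.max = 50))
  km$tot.withinss
}

#' Select the number of TME clusters
#'
#' Computes, for each `k` in `k_range`, the within-cluster sum of squares
#' (k-means, Euclidean, best of `n_restarts`) and the gap statistic
#' `gap(k) = mean(log(WSS_ref)) - log(WSS_obs)` over `n_ref` reference
#' datasets drawn uniformly from the bounding box of the observed
#' features, with `se(k) = sd(log WSS_ref) * sqrt(1 + 1/n_ref)`.
#' `k_gap` is the smallest k satisfying the one-standard-error rule
#' `gap(k) >= gap(k+1) - se(k+1)`; `k_elbow` maximises the second
#' difference of the WSS curve. The chosen k is `k_gap`, with `k_elbow`
#' reported alongside.
#'
#' @param fractions a `cell_fractions` object or samples x features matrix.
#' @param k_range integer vector of candidate k (within 1..n_samples-1).
#' @param n_ref number of uniform reference datasets (>= 10).
#' @param n_restarts k-means restarts per k.
#' @param seed integer seed.
#' @return object of class `k_selection`: list with `k_range`, `wss`,
#'   `gap`, `gap_se`, `k_elbow`, `k_gap`, `k_chosen`.
#' @export
select_k <- function(fractions, k_range = 1:10, n_ref = 50, n_restarts = 10,
                     seed = 1) {
  x <- fraction_matrix(fractions)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > n - 1)
    stopf("k_range must lie within [1, n_samples - 1]")
  if (n_ref < 10) stopf("n_ref must be >= 10")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    warnf("all samples identical; k_chosen = 1")
    return(structure(list(k_range = k_range,
                          wss = rep(0, length(k_range)),
                          gap = rep(NA_real_, length(k_range)),
                          gap_se = rep(NA_real_, length(k_range)),
                          k_elbow = 1L, k_gap = 1L, k_chosen = 1L),
                     class = "k_selection"))
  }
  withr::with_seed(seed, {
    wss <- vapply(k_range, function(k) kmeans_wss(x, k, n_restarts), numeric(1))
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    log_wss_ref <- matrix(NA_real_, n_ref, length(k_range))
    for (b in seq_len(n_ref)) {
      ref <- matrix(stats::runif(n * ncol(x), min = rep(lo, each = n),
                                 max = rep(hi, each = n)), nrow = n)
      log_wss_ref[b, ] <- log(vapply(k_range, function(k)
        kmeans_wss(ref, k, n_restarts), numeric(1)))
    }
    gap <- colMeans(log_wss_ref) - log(wss)
    gap_se <- apply(log_wss_ref, 2, stats::sd) * sqrt(1 + 1 / n_ref)
  })
  nk <- length(k_range)
  k_gap <- k_range[nk]
  for (i in seq_len(nk - 1L)) {
    if (gap[i] >= gap[i + 1L] - gap_se[i + 1L]) { k_gap <- k_range[i]; break }
  }
  k_elbow <- if (nk >= 3L) {
    d2 <- wss[1:(nk - 2L)] - 2 * wss[2:(nk - 1L)] + wss[3:nk]
    k_range[which.max(d2) + 1L]
  } else k_range[1L]
  structure(list(k_range = k_range, wss = wss, gap = gap, gap_se = gap_se,
                 k_elbow = k_elbow, k_gap = k_gap, k_chosen = k_gap),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("k_selection: k_chosen = %d (gap one-SE rule); k_elbow = %d\n",
              x$k_chosen, x$k_elbow))
  invisible(x)
}

#' Consensus k-means clustering of cell-fraction profiles
#'
#' Repeats k-means (Euclidean) on `n_reps` random subsamples of
#' `ceiling(p_item * n)` samples; the consensus matrix entry (i, j) is the
#' number of times i and j were assigned to the same cluster divided by
#' the number of times both were subsampled together (0, with a warning,
#' for pairs never co-sampled). Final labels come from agglomerative
#' clustering of `1 - consensus` with Ward linkage (`ward.D`) cut at `k`.
#'
#' @param fractions a `cell_fractions` object or samples x features matrix.
#' @param k number of clusters (>= 2).
#' @param n_reps number of subsampling repetitions (>= 2).
#' @param p_item subsample fraction in (0, 1].
#' @param n_restarts k-means restarts per subsample (guards against local
#'   optima so that clearly separated clusters co-cluster deterministically).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return object of class `consensus_model`: list with `consensus`
#'   (n x n matrix in [0,1], unit diagonal), `labels` (named integer vector
#'   in 1..k), `k`, `n_reps`.
#' @export
consensus_cluster <- function(fractions, k, n_reps = 1000, p_item = 0.8,
                              n_restarts = 5, seed = 1) {
  x <- fraction_matrix(fractions)
  n <- nrow(x)
  if (k < 2) stopf("k must be >= 2")
  if (n_reps < 2) stopf("n_reps must be >= 2")
  if (p_item <= 0 || p_item > 1) stopf("p_item must be in (0, 1]")
  m <- ceiling(p_item * n)
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(n, m)
      sub <- x[idx, , drop = FALSE]
      kk <- min(k, nrow(unique(sub)))
      cl <- suppressWarnings(stats::kmeans(sub, centers = kk,
                                           nstart = n_restarts,
                                           iter.max = 50))$cluster
      same <- outer(cl, cl, "==") * 1
      co_cluster[idx, idx] <- co_cluster[idx, idx] + same
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
    }
  })
  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never))
    warnf("%d sample pair(s) never co-sampled after %d reps; consensus set to 0",
          sum(never), n_reps)
  consensus <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(consensus) <- 1
  consensus <- (consensus + t(consensus)) / 2
  dimnames(consensus) <- list(rownames(x), rownames(x))
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "ward.D")
  labels <- stats::cutree(hc, k = k)
  structure(list(consensus = consensus, labels = labels, k = k,
                 n_reps = n_reps),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %d samples, k = %d, %d reps\n",
              nrow(x$consensus), x$k, x$n_reps))
  print(table(x$labels))
  invisible(x)
}

#' Test the association between cluster labels and overall survival
#'
#' Runs the multi-group log-rank test and returns per-group Kaplan-Meier
#' step functions. Empty groups are dropped with a warning.
#'
#' @param labels per-sample cluster labels, named by sample id (or in the
#'   row order of `clinical`).
#' @param clinical clinical table with sample_id, os_time, os_event.
#' @return list with `chi2`, `df`, `p_value` and `km` (named list of
#'   data.frames time/surv/n_risk/n_event per group, each starting at
#'   time 0 with survival 1).
#' @export
cluster_survival <- function(labels, clinical) {
  clinical <- validate_clinical_table(clinical)
  if (!is.null(names(labels))) {
    shared <- intersect(names(labels), clinical$sample_id)
    if (!length(shared)) stopf("no shared sample ids between labels and clinical")
    clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
    labels <- labels[shared]
  } else if (length(labels) != nrow(clinical)) {
    stopf("unnamed labels must match clinical rows")
  }
  grp <- factor(labels)
  empty <- levels(grp)[table(grp) == 0]
  if (length(empty)) {
    warnf("dropping empty group(s): %s", paste(empty, collapse = ", "))
    grp <- droplevels(grp)
  }
  if (nlevels(grp) < 2) stopf("need >= 2 non-empty groups")
  ev_by_grp <- tapply(clinical$os_event, grp, sum)
  if (any(ev_by_grp == 0))
    warnf("group(s) with zero events: %s",
          paste(names(ev_by_grp)[ev_by_grp == 0], collapse = ", "))
  sd <- survival::survdiff(survival::Surv(clinical$os_time, clinical$os_event) ~ grp)
  chi2 <- sd$chisq
  df <- nlevels(grp) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(clinical$os_time, clinical$os_event) ~ grp)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time))
            else sub("^grp=", "", as.character(sm$strata))
  km <- lapply(split(seq_along(sm$time), strata), function(i)
    rbind(data.frame(time = 0, surv = 1, n_risk = max(sm$n.risk[i]), n_event = 0),
          data.frame(time = sm$time[i], surv = sm$surv[i],
                     n_risk = sm$n.risk[i], n_event = sm$n.event[i])))
  list(chi2 = chi2, df = df, p_value = p, km = km)
}
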