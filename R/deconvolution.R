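# Bulk immune-cell deconvolution against an LM22-style signature matrix
# (nu-support-vector regression, CIBERSORT-style), plus marker-set
# abundance scores in the MCP-counter mould.

#' Estimate immune-cell fractions by nu-SVR deconvolution
#'
#' For each sample, the mixture is restricted to the genes shared with the
#' signature matrix; the signature matrix and the sample vector are each
#' standardised (matrix-wide z-scoring, the convention of the published
#' support-vector deconvolution); one linear nu-regression is fit per value
#' in `nu_grid` and the fit minimising the root-mean-square reconstruction
#' error is kept (ties go to the smallest nu). Negative coefficients are
#' clipped to zero and the remainder renormalised to sum 1; an all-zero
#' coefficient vector falls back to uniform fractions with a warning.
#' Deconvolution significance is an empirical permutation p-value: the
#' fraction of `n_perm` random mixtures (values resampled from the full
#' mixture matrix) whose reconstruction correlation reaches the observed
#' one, with add-one smoothing. The permutation null is shared across
#' samples of the same mixture matrix.
#'
#' @param mixture expression matrix (genes x samples, linear scale).
#' @param signature signature matrix (genes x cell types); at least half of
#'   its genes must be present in the mixture.
#' @param nu_grid nu values to scan, each in (0, 1).
#' @param n_perm number of permutations for the p-value (0 = skip, p = NA).
#' @param seed integer seed for the permutation draws.
#' @return object of class `cell_fractions`: list with `fractions`
#'   (samples x cell types, rows sum to 1) and `stats` (data.frame with
#'   sample_id, nu, rmse, pearson_r, p_value).
#' @export
estimate_fractions <- function(mixture, signature,
                               nu_grid = c(0.25, 0.5, 0.75),
                               n_perm = 0, seed = 1) {
  validate_expression_table(mixture)
  validate_signature_matrix(signature)
  if (length(nu_grid) < 1L || any(nu_grid <= 0 | nu_grid >= 1))
    stopf("nu_grid must be non-empty with values in (0, 1)")
  nu_grid <- sort(nu_grid)
  shared <- intersect(rownames(signature), rownames(mixture))
  if (length(shared) < 0.5 * nrow(signature)) {
    missing <- setdiff(rownames(signature), rownames(mixture))
    stopf("only %d/%d signature genes present in mixture (need >= 50%%); missing e.g.: %s",
          length(shared), nrow(signature),
          paste(utils::head(missing, 10L), collapse = ", "))
  }
  X <- signature[shared, , drop = FALSE]
  Xs <- (X - mean(X)) / stats::sd(X)
  Y <- mixture[shared, , drop = FALSE]

  fit_one <- function(y) {
    ys <- (y - mean(y)) / stats::sd(y)
    best <- NULL
    for (nu in nu_grid) {
      sv <- e1071::svm(x = Xs, y = ys, type = "nu-regression",
                       kernel = "linear", nu = nu, scale = FALSE)
      w <- as.vector(crossprod(sv$coefs, sv$SV))
      recon <- as.vector(Xs %*% w)
      rmse <- sqrt(mean((recon - ys)^2))
      if (is.null(best) || rmse < best$rmse - 1e-12)
        best <- list(nu = nu, w = w, rmse = rmse,
                     r = suppressWarnings(stats::cor(recon, ys)))
    }
    best
  }

  n_s <- ncol(Y)
  cts <- colnames(signature)
  fractions <- matrix(0, n_s, length(cts), dimnames = list(colnames(Y), cts))
  stats_df <- data.frame(sample_id = colnames(Y), nu = NA_real_,
                         rmse = NA_real_, pearson_r = NA_real_,
                         p_value = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(n_s)) {
    b <- fit_one(Y[, j])
    w <- pmax(b$w, 0)
    if (sum(w) == 0) {
      warnf("all-zero coefficient vector for sample '%s'; using uniform fractions",
            colnames(Y)[j])
      w <- rep(1, length(w))
    }
    fractions[j, ] <- w / sum(w)
    stats_df$nu[j] <- b$nu
    stats_df$rmse[j] <- b$rmse
    stats_df$pearson_r[j] <- b$r
  }
  if (n_perm >= 1) {
    pool <- as.vector(Y)
    null_r <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      yp <- sample(pool, length(shared), replace = TRUE)
      if (stats::sd(yp) == 0) return(0)
      fit_one(yp)$r
    }, numeric(1)))
    stats_df$p_value <- vapply(stats_df$pearson_r, function(r)
      (1 + sum(null_r >= r)) / (n_perm + 1), numeric(1))
  }
  structure(list(fractions = fractions, stats = stats_df),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat(sprintf("cell_fractions: %d samples x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  cat(sprintf("  mean rmse %.3f; mean pearson r %.3f\n",
              mean(x$stats$rmse), mean(x$stats$pearson_r)))
  invisible(x)
}

# extract the fraction matrix from a cell_fractions object or pass a
# plain matrix through
fraction_matrix <- function(x) {
  if (inherits(x, "cell_fractions")) return(x$fractions)
  if (is.matrix(x)) return(x)
  stopf("expected a 'cell_fractions' object or a numeric matrix")
}

#' Marker-set abundance scores (MCP-counter style)
#'
#' The abundance of a cell population in a sample is the arithmetic mean
#' of `log2(expr + 1)` over the population's marker genes present in the
#' mixture. Populations with no present marker genes are dropped with a
#' warning.
#'
#' @param mixture expression matrix (genes x samples, linear scale).
#' @param marker_sets named list mapping population -> character vector of
#'   marker genes.
#' @return numeric matrix, samples x populations.
#' @export
mcp_abundance <- function(mixture, marker_sets) {
  validate_expression_table(mixture)
  if (!length(marker_sets) || is.null(names(marker_sets)))
    stopf("marker_sets must be a named list")
  logm <- log2p1(mixture)
  out <- list()
  for (pop in names(marker_sets)) {
    present <- intersect(marker_sets[[pop]], rownames(mixture))
    if (!length(present)) {
      warnf("population '%s' has no marker genes in the mixture; dropped", pop)
      next
    }
    out[[pop]] <- colMeans(logm[present, , drop = FALSE])
  }
  if (!length(out)) stopf("no population has marker genes in the mixture")
  do.call(cbind, out)
}
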