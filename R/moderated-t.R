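# Empirical-Bayes moderated two-sample t-test. Gene-wise variances are
# shrunk toward a pooled prior fitted by moment matching on the log
# residual variances (the standard scaled inverse-chi-square / F-fit of
# the moderated-t literature); the moderated statistic gains the prior
# degrees of freedom.

# invert the trigamma function by Newton iteration
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

# fit the prior (d0, s0^2) for variances s2 on df degrees of freedom
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  df_prior <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# moderated two-sample t on the rows of `mat` (features x samples);
# `grp` is logical: TRUE = group of interest. Returns a data.frame with
# effect (mean TRUE - mean FALSE), t, p_value, df_total.
moderated_t_rows <- function(mat, grp) {
  n1 <- sum(grp)
  n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 samples")
  m1 <- rowMeans(mat[, grp, drop = FALSE])
  m2 <- rowMeans(mat[, !grp, drop = FALSE])
  ss1 <- rowSums((mat[, grp, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, !grp, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  prior <- fit_variance_prior(s2, df)
  if (is.finite(prior$df_prior)) {
    s2_post <- (prior$df_prior * prior$s2_prior + df * s2) / (prior$df_prior + df)
    df_total <- df + prior$df_prior
  } else {
    s2_post <- rep(prior$s2_prior, length(s2))
    df_total <- Inf
  }
  tstat <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(effect = m1 - m2, t = tstat, p_value = p,
             df_total = df_total, row.names = rownames(mat))
}
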