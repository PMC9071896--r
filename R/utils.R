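# Internal helpers shared across modules.

log2p1 <- function(x) log2(x + 1)

#' @importFrom stats rnorm runif
rdirichlet <- function(n, alpha) {
  # one Dirichlet draw per row; gamma representation
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# full cosine matrix between columns of A and columns of B
cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), .Machine$double.eps), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), .Machine$double.eps), "/")
  crossprod(An, Bn)
}

# greedy one-to-one matching of columns of A to columns of B by cosine;
# returns data.frame(a = , b = , cosine = ), one row per column of A
greedy_cosine_match <- function(A, B) {
  cm <- cosine_matrix(A, B)
  na <- ncol(A)
  out <- data.frame(a = integer(na), b = integer(na), cosine = numeric(na))
  used_a <- rep(FALSE, nrow(cm))
  used_b <- rep(FALSE, ncol(cm))
  for (step in seq_len(na)) {
    masked <- cm
    masked[used_a, ] <- -Inf
    masked[, used_b] <- -Inf
    ij <- arrayInd(which.max(masked), dim(masked))
    out$a[step] <- ij[1]
    out$b[step] <- ij[2]
    out$cosine[step] <- cm[ij[1], ij[2]]
    used_a[ij[1]] <- TRUE
    used_b[ij[2]] <- TRUE
  }
  out[order(out$a), , drop = FALSE]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}
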