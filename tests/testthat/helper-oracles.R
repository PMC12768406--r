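# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Sup-ECDF distance by dense-grid evaluation: both ECDFs are evaluated just
# at and just after every pooled point, so the supremum is hit exactly.
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  eval_at <- sort(c(pts - 1e-9, pts, pts + 1e-9))
  fa <- vapply(eval_at, function(v) mean(a <= v), numeric(1))
  fb <- vapply(eval_at, function(v) mean(b <= v), numeric(1))
  max(abs(fa - fb))
}

# Normal-normal conjugate posterior for a fixed residual SD, no random effect.
oracle_conjugate_posterior <- function(y, prior_mean, prior_sd, sigma) {
  prec <- 1 / prior_sd^2 + length(y) / sigma^2
  list(mean = (prior_mean / prior_sd^2 + sum(y) / sigma^2) / prec,
       sd = sqrt(1 / prec))
}

# Pearson statistic straight from the expected-counts formula.
oracle_chi2_q <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Two-sided Fisher p by exhaustive enumeration of the hypergeometric null
# on the first cell, conditioning on all margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  prob <- vapply(lo:hi, function(k) dhyper(k, r1, n - r1, c1), numeric(1))
  sum(prob[prob <= dhyper(tab[1, 1], r1, n - r1, c1) * (1 + 1e-7)])
}

# Poisson log-link GLM by hand-coded IRLS (independent of stats::glm).
oracle_poisson_irls <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    W <- mu
    z <- drop(X %*% beta) + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Crossing count by explicit pairwise enumeration.
oracle_crossings <- function(labels) {
  labels <- labels[!is.na(labels)]
  n <- 0L
  for (i in seq_along(labels)[-1]) if (labels[i] != labels[i - 1]) n <- n + 1L
  n
}

# All multisets of size k from a value grid (for exhaustive K-S checks).
all_multisets <- function(values, k) {
  if (k == 1) return(as.list(values))
  out <- list()
  rec <- function(start, cur) {
    if (length(cur) == k) { out[[length(out) + 1L]] <<- cur; return() }
    for (i in start:length(values)) rec(i, c(cur, values[i]))
  }
  rec(1, numeric(0))
  out
}
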