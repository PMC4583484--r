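# Fixture builders shared across the suite.  Everything is generated in code
# under explicit seeds; no data files.

# Random I x J x K count table with positive stratum totals.
random_table <- function(I = 2, J = 3, K = 1, lambda = 8) {
  repeat {
    a <- array(rpois(I * J * K, lambda), dim = c(I, J, K))
    totals <- apply(a, 3, sum)
    margins_ok <- all(apply(a, c(1, 3), sum) > 0) &&
      all(apply(a, c(2, 3), sum) > 0)
    if (all(totals >= 2) && margins_ok) return(a)
  }
}

# Small genotype matrix with optional missingness.
random_genotypes <- function(n = 50, m = 5, maf = 0.3, miss = 0) {
  codes <- matrix(rbinom(n * m, 2, maf), n, m)
  if (miss > 0) codes[runif(n * m) < miss] <- NA
  genotype_matrix(codes)
}

# Probability-weighted covariance of 2x2 cell counts over all tables with
# the given margins (multivariate hypergeometric): an exhaustive oracle for
# variance_matrix() on tiny strata.
hypergeom_cov_2x2 <- function(slice) {
  r <- rowSums(slice); s <- colSums(slice); n <- sum(slice)
  cells <- list(); probs <- numeric(0)
  for (a in max(0, r[1] + s[1] - n):min(r[1], s[1])) {
    tab <- matrix(c(a, r[1] - a, s[1] - a, n - r[1] - s[1] + a), 2, 2)
    cells[[length(cells) + 1]] <- as.vector(t(tab))
    probs <- c(probs, dhyper(a, s[1], n - s[1], r[1]))
  }
  X <- do.call(rbind, cells)
  mu <- colSums(X * probs)
  V <- matrix(0, 4, 4)
  for (i in seq_along(probs)) {
    d <- X[i, ] - mu
    V <- V + probs[i] * outer(d, d)
  }
  V
}

# Pearson chi-square statistic computed from first principles (oracle).
pearson_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
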