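#' Expected counts of a stratum under conditional independence
#'
#' For one \eqn{I \times J} stratum slice the null expectation of cell
#' \eqn{(i, j)} is the product of its margins over the stratum total,
#' \eqn{\mu_{ij} = n_{i+} n_{+j} / n_{++}}.
#'
#' @param stratum non-negative count matrix (one stratum of an I x J x K
#'   table); its total must be at least 1.
#' @return Numeric matrix of the same shape; its cells sum to the stratum
#'   total.
#' @examples
#' expected_counts(rbind(c(1, 0), c(0, 1)))
#' @export
expected_counts <- function(stratum) {
  stratum <- as.matrix(stratum)
  check_counts(stratum)
  n <- sum(stratum)
  if (n < 1) stop("empty stratum: expected counts undefined")
  outer(rowSums(stratum), colSums(stratum)) / n
}

#' Null covariance matrix of a stratum's cell counts
#'
#' Covariance of the vectorized cell counts of one \eqn{I \times J} stratum
#' under the multivariate hypergeometric distribution with both margins
#' fixed:
#' \deqn{Cov(n_{ij}, n_{i'j'}) =
#'   \frac{n_{i+}(\delta_{ii'} n - n_{i'+})\, n_{+j}(\delta_{jj'} n - n_{+j'})}
#'        {n^2 (n - 1)}}
#' with \eqn{n} the stratum total.  Cells are ordered row-major, i.e.
#' \eqn{(1,1), (1,2), \dots, (I,J)}, matching the observed/expected vectors
#' used by [cmh_test()].
#'
#' @param stratum non-negative count matrix with total at least 2.
#' @return Symmetric \eqn{(IJ) \times (IJ)} matrix.
#' @export
variance_matrix <- function(stratum) {
  stratum <- as.matrix(stratum)
  check_counts(stratum)
  n <- sum(stratum)
  if (n < 2) stop("degenerate stratum (total < 2): covariance undefined")
  r <- rowSums(stratum)
  s <- colSums(stratum)
  ## kronecker factorization of the hypergeometric covariance:
  ## R[i,i'] = r_i (delta n - r_i'), C[j,j'] = s_j (delta n - s_j')
  R <- -outer(r, r)
  diag(R) <- r * (n - r)
  C <- -outer(s, s)
  diag(C) <- s * (n - s)
  kronecker(R, C) / (n^2 * (n - 1))
}

check_counts <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("counts must be finite and non-missing")
  }
  if (any(x < 0)) stop("counts must be non-negative")
  invisible(x)
}

#' Generalized Cochran-Mantel-Haenszel test
#'
#' Tests conditional independence between the row and column variables of an
#' \eqn{I \times J \times K} contingency table, pooling evidence across the
#' \eqn{K} strata.  With observed count vector \eqn{n_k}, expectation
#' \eqn{\mu_k} and hypergeometric covariance \eqn{V_k} per stratum, and
#' \eqn{B_k = u \otimes v} the Kronecker product of the row and column score
#' matrices, the statistic is
#' \deqn{L^2 = \left[\sum_k B_k(n_k - \mu_k)\right]'
#'             \left[\sum_k B_k V_k B_k'\right]^{-1}
#'             \left[\sum_k B_k(n_k - \mu_k)\right]}
#' referred to a chi-square distribution.  Both margins nominal gives the
#' general association test on \eqn{(I-1)(J-1)} degrees of freedom; one
#' ordinal margin gives a mean-score test (\eqn{J-1} or \eqn{I-1} df); both
#' ordinal gives the correlation test on 1 df.
#'
#' Strata with fewer than two observations carry no information (the
#' covariance denominator \eqn{n(n-1)} vanishes) and are dropped; their count
#' is reported.  When the pooled covariance is singular -- common for sparse
#' tables -- its Moore-Penrose generalized inverse is used, the degrees of
#' freedom are reduced to the matrix rank, and `rank_deficient` is flagged.
#'
#' @param x a 3-dimensional count array (I x J x K), or a matrix for the
#'   unstratified K = 1 case.
#' @param row_scheme,col_scheme a [score_scheme()] for each margin, or
#'   `"nominal"`/`"ordinal"` shorthand, or a numeric score vector (ordinal).
#' @return An object of classes `"cmh_test"` and `"htest"` with components
#'   `statistic` (L^2), `parameter` (df), `p.value`, `test_type`
#'   (`"general"`, `"mean_score"` or `"correlation"`), `n_strata_used`,
#'   `n_strata_dropped`, and `rank_deficient`.
#' @examples
#' tab <- array(rpois(2 * 3 * 2, 8), dim = c(2, 3, 2))
#' cmh_test(tab)                       # general association
#' cmh_test(tab, col_scheme = 0:2)     # mean-score (additive coding)
#' @references
#' Agresti, A. (2013) *Categorical Data Analysis*, 3rd ed., ch. 6 --
#' generalized CMH tests for I x J x K tables.
#' @export
cmh_test <- function(x, row_scheme = "nominal", col_scheme = "nominal") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("'x' must be an I x J x K array (or an I x J matrix)")
  }
  check_counts(x)
  I <- dim(x)[1L]
  J <- dim(x)[2L]
  K <- dim(x)[3L]
  if (I < 2L || J < 2L) stop("both margins need at least two levels")

  row_scheme <- as_score_scheme(row_scheme)
  col_scheme <- as_score_scheme(col_scheme)
  U <- score_matrix(I, row_scheme)
  V <- score_matrix(J, col_scheme)
  B <- kronecker(U, V)  # rows: contrasts; cols: cells in row-major order
  q <- nrow(B)

  test_type <- switch(paste(row_scheme$kind, col_scheme$kind),
    "nominal nominal" = "general",
    "ordinal ordinal" = "correlation",
    "mean_score"
  )

  G <- numeric(q)
  S <- matrix(0, q, q)
  dropped <- 0L
  for (k in seq_len(K)) {
    slice <- x[, , k, drop = FALSE]
    dim(slice) <- c(I, J)
    nk <- sum(slice)
    if (nk < 2) {
      dropped <- dropped + 1L
      next
    }
    d <- as.vector(t(slice)) - as.vector(t(expected_counts(slice)))
    G <- G + B %*% d
    S <- S + B %*% variance_matrix(slice) %*% t(B)
  }
  used <- K - dropped
  if (used == 0L) stop("all strata are degenerate (totals < 2): untestable")

  ## Moore-Penrose inverse via the symmetric eigendecomposition; df drops to
  ## the rank when the pooled covariance is singular.
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  tol <- q * .Machine$double.eps * max(ev$values, 0)
  keep <- ev$values > tol
  rank <- sum(keep)
  rank_deficient <- rank < q
  if (rank == 0L) {
    stat <- 0
    df <- 0L
    p <- 1
  } else {
    z <- crossprod(ev$vectors[, keep, drop = FALSE], G)
    stat <- sum(z^2 / ev$values[keep])
    df <- if (rank_deficient) rank else q
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }

  method <- paste0("Generalized Cochran-Mantel-Haenszel test (",
                   sub("_", " ", test_type), ")")
  structure(
    list(
      statistic = c("L^2" = stat),
      parameter = c(df = df),
      p.value = p,
      method = method,
      data.name = deparse1(substitute(x)),
      test_type = test_type,
      n_strata_used = used,
      n_strata_dropped = dropped,
      rank_deficient = rank_deficient
    ),
    class = c("cmh_test", "htest")
  )
}

#' @export
print.cmh_test <- function(x, ...) {
  NextMethod()
  cat("strata used:", x$n_strata_used,
      " dropped:", x$n_strata_dropped,
      if (x$rank_deficient) " (rank-deficient covariance; df reduced)" else "",
      "\n")
  invisible(x)
}
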