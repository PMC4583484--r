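#' Genotype matrix of minor-allele counts
#'
#' Wraps a samples x SNPs integer matrix of minor-allele counts (0, 1, 2,
#' with `NA` for missing calls) and validates it.  All downstream code --
#' stratification, stepwise selection, QC -- consumes this class.
#'
#' @param codes numeric/integer matrix, samples in rows, SNPs in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param snp_ids unique SNP identifiers; defaults to existing column names
#'   or `snp1, snp2, ...`.
#' @param sample_ids sample identifiers; defaults to existing row names or
#'   `s1, s2, ...`.
#' @return An integer matrix of class `"genotype_matrix"` with `snp_ids` as
#'   column names and `sample_ids` as row names.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1), c(2, NA), c(1, 0)))
#' g
#' @export
genotype_matrix <- function(codes, snp_ids = NULL, sample_ids = NULL) {
  codes <- unclass(as.matrix(codes))
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("genotype code out of range {0,1,2,NA} at sample ", idx[1L],
         ", SNP ", idx[2L], ": ", codes[bad][1L])
  }
  storage.mode(codes) <- "integer"
  if (is.null(snp_ids)) snp_ids <- colnames(codes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  if (length(snp_ids) != ncol(codes)) stop("snp_ids length mismatch")
  if (is.null(sample_ids)) sample_ids <- rownames(codes)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(codes)))
  if (length(sample_ids) != nrow(codes)) stop("sample_ids length mismatch")
  dimnames(codes) <- list(sample_ids, snp_ids)
  class(codes) <- c("genotype_matrix", "matrix", "array")
  codes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "samples x", ncol(x), "SNPs;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

snp_index <- function(genos, snp_set) {
  idx <- match(snp_set, colnames(genos))
  if (anyNA(idx)) {
    stop("unknown SNP id(s): ", paste(snp_set[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Per-sample sum of minor allele counts
#'
#' The stratification key of the capped MAC scheme: for each sample, the sum
#' of minor-allele counts over a set of SNPs.  Samples missing any genotype
#' in the set get `NA` (they are excluded from tables built on this key).
#'
#' @param genos a [genotype_matrix()].
#' @param snp_set character vector of SNP ids (may be empty: the sum is 0).
#' @return Integer vector, one value per sample.
#' @export
mac_sum <- function(genos, snp_set) {
  if (length(snp_set) == 0L) return(integer(nrow(genos)))
  idx <- snp_index(genos, snp_set)
  sub <- genos[, idx, drop = FALSE]
  out <- as.integer(rowSums(sub))
  out[rowSums(is.na(sub)) > 0L] <- NA_integer_
  out
}

#' Assign samples to strata from a conditioning SNP set
#'
#' Builds the stratification used when testing a target SNP conditional on a
#' set of already-selected SNPs.  Two schemes:
#' \describe{
#'   \item{`full_cross`}{one stratum per distinct genotype tuple of the
#'     conditioning set; with `p` SNPs the stratum count can reach
#'     \eqn{3^p}, which is impractical beyond a handful of SNPs.}
#'   \item{`mac_sum`}{strata are the per-sample sums of minor allele counts
#'     0, 1, ..., `cap - 2`, with every sum of `cap - 1` or more merged into
#'     one final stratum, so \eqn{K \le \min(2p + 1, cap)}.  Samples with a
#'     similar minor-allele burden across the conditioning set are pooled,
#'     keeping strata well-populated at genome-wide scale.}
#' }
#' Only keys actually observed produce strata (empty strata are inert in the
#' CMH statistic anyway).  An empty conditioning set gives a single stratum.
#'
#' @param genos a [genotype_matrix()].
#' @param snp_set character vector of conditioning SNP ids.
#' @param scheme `"mac_sum"` (default) or `"full_cross"`.
#' @param cap maximum stratum count for `mac_sum` (at least 2; default 10).
#' @return An object of class `"strata_assignment"`: list with
#'   `stratum_index` (integer in `1..K` per sample, `NA` when a conditioning
#'   genotype is missing), `K`, `scheme`, `cap`, and `conditioning_set`.
#' @examples
#' g <- genotype_matrix(cbind(a = c(0, 1, 2, 2), b = c(0, 2, 2, 1)))
#' assign_strata(g, c("a", "b"), scheme = "mac_sum", cap = 4)
#' @export
assign_strata <- function(genos, snp_set,
                          scheme = c("mac_sum", "full_cross"), cap = 10L) {
  scheme <- match.arg(scheme)
  n <- nrow(genos)
  if (length(snp_set) == 0L) {
    key <- integer(n)
  } else if (scheme == "mac_sum") {
    if (is.na(cap) || cap < 2) stop("'cap' must be at least 2")
    s <- mac_sum(genos, snp_set)
    key <- pmin(s, as.integer(cap) - 1L)
  } else {
    idx <- snp_index(genos, snp_set)
    sub <- genos[, idx, drop = FALSE]
    ## base-3 encoding of the genotype tuple; NA propagates
    key <- as.integer(sub %*% 3^(seq_along(idx) - 1L))
  }
  levs <- sort(unique(key[!is.na(key)]))
  structure(
    list(
      stratum_index = match(key, levs),
      K = length(levs),
      scheme = scheme,
      cap = if (scheme == "mac_sum") as.integer(cap) else NA_integer_,
      conditioning_set = as.character(snp_set)
    ),
    class = "strata_assignment"
  )
}

#' @export
print.strata_assignment <- function(x, ...) {
  cat("Strata assignment (", x$scheme, "): K = ", x$K,
      ", conditioning on {", paste(x$conditioning_set, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Build the trait x genotype x stratum contingency table for one SNP
#'
#' Cross-tabulates the trait against the target SNP's genotype (columns
#' always 0/1/2) within each stratum.  Samples with a missing trait, a
#' missing target genotype, or no stratum (missing conditioning genotype)
#' are dropped, so the grand total equals the complete-case count for this
#' particular test.
#'
#' @param pheno trait vector with I >= 2 levels (factor, character or
#'   integer); factor level order is kept, otherwise levels are sorted.
#' @param target_snp id of the SNP under test; must not belong to the
#'   conditioning set.
#' @param strata a [assign_strata()] result (or `NULL` for a single stratum).
#' @param genos a [genotype_matrix()].
#' @return An I x 3 x K count array with dimnames (trait levels, 0:2,
#'   stratum index).
#' @export
build_table <- function(pheno, target_snp, strata, genos) {
  if (length(pheno) != nrow(genos)) {
    stop("phenotype length does not match the number of samples")
  }
  if (!is.null(strata) && target_snp %in% strata$conditioning_set) {
    stop("target SNP '", target_snp, "' is in the conditioning set")
  }
  f <- if (is.factor(pheno)) pheno else factor(pheno)
  I <- nlevels(f)
  if (I < 2L) stop("the trait needs at least two observed levels")
  g <- genos[, snp_index(genos, target_snp)] + 1L
  if (is.null(strata)) {
    k <- rep.int(1L, nrow(genos))
    K <- 1L
  } else {
    k <- strata$stratum_index
    K <- max(strata$K, 1L)
  }
  i <- as.integer(f)
  ok <- !is.na(i) & !is.na(g) & !is.na(k)
  code <- i[ok] + I * (g[ok] - 1L) + (3L * I) * (k[ok] - 1L)
  array(tabulate(code, nbins = I * 3L * K),
        dim = c(I, 3L, K),
        dimnames = list(levels(f), 0:2, seq_len(K)))
}
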