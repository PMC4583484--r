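#' Read a genotype matrix from disk
#'
#' Two layouts are supported:
#' \describe{
#'   \item{`delimited`}{header row of SNP ids, first column the sample id,
#'     remaining cells minor-allele counts; tab, comma or whitespace
#'     separated; missing calls encoded as `NA` or `-9`.}
#'   \item{`plink_raw`}{an additive-recoded table as written by
#'     `plink --recode A`: columns `FID IID PAT MAT SEX PHENOTYPE` followed
#'     by one counted-allele column per SNP (ids taken from the header,
#'     trailing `_A` allele suffix stripped); `IID` becomes the sample id.}
#' }
#'
#' @param path file path.
#' @param format `"auto"` (default; `plink_raw` is detected from the
#'   `FID IID ...` header), `"delimited"` or `"plink_raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "delimited", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  if (format == "auto") {
    lead <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1L]]
    format <- if (length(lead) >= 6L && identical(toupper(lead[1:2]),
                                                  c("FID", "IID"))) {
      "plink_raw"
    } else {
      "delimited"
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-9"))
  if (format == "plink_raw") {
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(toupper(names(df)[1:2]) == c("FID", "IID"))) {
      stop("not a PLINK additive-recoded file: missing FID/IID columns")
    }
    sample_ids <- as.character(df[["IID"]])
    keep <- !(toupper(names(df)) %in% meta)
    codes <- as.matrix(df[, keep, drop = FALSE])
    snp_ids <- sub("_[ACGT0-9]+$", "", names(df)[keep])
  } else {
    sample_ids <- as.character(df[[1L]])
    codes <- as.matrix(df[, -1L, drop = FALSE])
    snp_ids <- names(df)[-1L]
  }
  suppressWarnings(storage.mode(codes) <- "double")
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code in ", path, " at row ", idx[1L],
         " (sample ", sample_ids[idx[1L]], "), SNP ", snp_ids[idx[2L]])
  }
  genotype_matrix(codes, snp_ids = snp_ids, sample_ids = sample_ids)
}

#' Write a genotype matrix as a delimited table
#'
#' Tab-separated, one header row of SNP ids with a leading `sample` column;
#' the exact layout [read_genotypes()] reads back.
#'
#' @param genos a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genos, path) {
  df <- data.frame(sample = rownames(genos),
                   unclass(genos)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two columns: sample id and trait value.  Values are returned in the file's
#' sample order unless `genos` is given, in which case they are aligned to
#' its samples (missing samples get `NA`).
#'
#' @param path file path (tab/comma/whitespace separated, header optional).
#' @param genos optional [genotype_matrix()] to align against.
#' @return Named trait vector (factor).
#' @export
read_phenotype <- function(path, genos = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  has_header <- !grepl("^\\S+[,\\s]+[0-9.+-]+$", trimws(first), perl = TRUE)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-9"))
  if (ncol(df) < 2L) stop("phenotype file needs two columns: sample, trait")
  pheno <- factor(df[[2L]])
  names(pheno) <- as.character(df[[1L]])
  if (!is.null(genos)) pheno <- pheno[rownames(genos)]
  pheno
}

#' SNP quality-control filter
#'
#' Drops SNPs with a folded sample minor allele frequency below `maf_min`
#' or a call rate (non-missing fraction) below `callrate_min`.  Both
#' comparisons are strict, so boundary SNPs are retained.  The MAF is
#' computed on non-missing codes and folded to at most 0.5 (the coded
#' allele's frequency may exceed 0.5 in a sample).
#'
#' @param genos a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param callrate_min minimum call rate (default 0.95).
#' @return List with `genotypes` (filtered matrix) and `report` (a
#'   `"qc_report"`: input/removed/output SNP counts and thresholds).
#' @export
qc_filter <- function(genos, maf_min = 0.01, callrate_min = 0.95) {
  stopifnot(maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  callrate <- colMeans(!is.na(genos))
  p <- colMeans(genos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNP: fails call rate anyway
  drop_maf <- maf < maf_min
  drop_cr <- callrate < callrate_min
  keep <- !(drop_maf | drop_cr)
  report <- structure(
    list(n_input_snps = ncol(genos),
         n_removed_maf = sum(drop_maf),
         n_removed_callrate = sum(drop_cr & !drop_maf),
         n_removed_ld = 0L,
         n_output_snps = sum(keep),
         maf_min = maf_min, callrate_min = callrate_min, r2_max = NA_real_),
    class = "qc_report"
  )
  list(genotypes = genos[, keep, drop = FALSE] |> genotype_matrix(),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input_snps, "SNPs in ->", x$n_output_snps, "out\n")
  cat("  removed: MAF <", x$maf_min, ":", x$n_removed_maf,
      "| call rate <", x$callrate_min, ":", x$n_removed_callrate,
      "| LD pruned:", x$n_removed_ld, "\n")
  invisible(x)
}

#' Prune SNPs in high linkage disequilibrium
#'
#' Sliding window (step 1) over the SNPs in their positional order: a SNP is
#' dropped when its squared Pearson correlation of allele counts with any
#' retained earlier SNP among the previous `window - 1` positions exceeds
#' `r2_max` (strictly).  The earlier member of a correlated pair is always
#' the one kept.  Correlations use pairwise-complete observations.
#'
#' @param genos a [genotype_matrix()]; column order is the positional order.
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @param window window size in SNPs (default 50).
#' @return List with `genotypes` and a `"qc_report"` (only `n_removed_ld`
#'   is populated).
#' @export
ld_prune <- function(genos, r2_max = 0.5, window = 50L) {
  stopifnot(r2_max >= 0, window >= 2)
  n_snps <- ncol(genos)
  keep <- rep(TRUE, n_snps)
  for (i in seq_len(n_snps)[-1]) {
    lo <- max(1L, i - as.integer(window) + 1L)
    prev <- which(keep[lo:(i - 1L)]) + lo - 1L
    for (j in prev) {
      r <- suppressWarnings(
        stats::cor(genos[, i], genos[, j], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) {
        keep[i] <- FALSE
        break
      }
    }
  }
  report <- structure(
    list(n_input_snps = n_snps,
         n_removed_maf = 0L, n_removed_callrate = 0L,
         n_removed_ld = sum(!keep),
         n_output_snps = sum(keep),
         maf_min = NA_real_, callrate_min = NA_real_, r2_max = r2_max),
    class = "qc_report"
  )
  list(genotypes = genos[, keep, drop = FALSE] |> genotype_matrix(),
       report = report)
}
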