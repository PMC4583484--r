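#' Multiplicative-odds disease model for case-control simulation
#'
#' Defines the generative model behind [simulate_gwas()]: each causal SNP
#' multiplies a baseline disease odds \eqn{\alpha} by 1, \eqn{1+\theta_1} or
#' \eqn{1+\theta_2} according to its genotype (0/1/2 copies of the minor
#' allele), disease probability is odds/(1+odds), and subjects are sampled
#' retrospectively until the case and control quotas are met.  Equivalently,
#' on the logit scale this is a logistic model with intercept
#' \eqn{\log\alpha} and per-SNP codominant coefficients
#' \eqn{\log(1+\theta_1)}, \eqn{\log(1+\theta_2)}.
#'
#' The baseline \eqn{\alpha} is normally left `NULL` and solved from
#' `total_penetrance` (the population case proportion) via [solve_alpha()],
#' assuming Hardy-Weinberg equilibrium and linkage equilibrium among the
#' causal SNPs.
#'
#' @param theta1 heterozygote effect (odds multiplier \eqn{1+\theta_1});
#'   default 0.7.
#' @param theta2 minor-homozygote effect; default 0.5.
#' @param causal_mafs minor allele frequencies of the causal SNPs, one per
#'   causal SNP, each in (0, 0.5].
#' @param total_penetrance population case proportion in (0, 1); used to
#'   solve `alpha` when it is `NULL`.  Default 0.1.
#' @param alpha baseline odds; overrides `total_penetrance` when given.
#' @param n_null_snps number of non-causal SNPs, independent of the trait.
#' @param null_maf_law either a length-2 numeric range from which null-SNP
#'   MAFs are drawn uniformly (default `c(0.05, 0.5)`), or the string
#'   `"causal"` to reuse the causal MAFs (recycled).
#' @param n_cases,n_controls retrospective sampling quotas.
#' @return A list of class `"sim_model"`.
#' @export
sim_model <- function(theta1 = 0.7, theta2 = 0.5,
                      causal_mafs = c(0.1, 0.1),
                      total_penetrance = 0.1,
                      alpha = NULL,
                      n_null_snps = 98L,
                      null_maf_law = c(0.05, 0.5),
                      n_cases = 1000L, n_controls = 1000L) {
  stopifnot(1 + theta1 > 0, 1 + theta2 > 0,
            all(causal_mafs > 0), all(causal_mafs <= 0.5),
            total_penetrance > 0, total_penetrance < 1,
            n_null_snps >= 0, n_cases >= 1, n_controls >= 1)
  if (!is.null(alpha) && alpha <= 0) stop("'alpha' must be positive")
  structure(
    list(theta1 = theta1, theta2 = theta2,
         causal_mafs = as.numeric(causal_mafs),
         total_penetrance = total_penetrance,
         alpha = alpha,
         n_null_snps = as.integer(n_null_snps),
         null_maf_law = null_maf_law,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls)),
    class = "sim_model"
  )
}

#' Odds multiplier of one genotype
#'
#' @param g genotype code(s) in {0, 1, 2}.
#' @param theta1,theta2 heterozygote and minor-homozygote effects.
#' @return 1, `1 + theta1` or `1 + theta2` for g = 0, 1, 2.
#' @export
genotype_factor <- function(g, theta1, theta2) {
  if (anyNA(g) || !all(g %in% c(0, 1, 2))) {
    stop("genotype codes must be 0, 1 or 2")
  }
  c(1, 1 + theta1, 1 + theta2)[g + 1]
}

#' Penetrance of a multi-locus genotype
#'
#' Disease probability under the multiplicative-odds model:
#' odds \eqn{= \alpha \prod_s f(g_s)} with \eqn{f} the per-SNP
#' [genotype_factor()], penetrance = odds / (1 + odds).
#'
#' @param genotypes vector of genotype codes, one per causal SNP (or a
#'   matrix, one row per subject).
#' @param alpha baseline odds (> 0).
#' @param theta1,theta2 per-SNP effects.
#' @return Penetrance value(s) in (0, 1).
#' @examples
#' penetrance(c(1, 1, 0), alpha = 1, theta1 = 0.7, theta2 = 0.5)  # 2.89/3.89
#' @export
penetrance <- function(genotypes, alpha, theta1, theta2) {
  if (alpha <= 0) stop("'alpha' must be positive")
  if (is.matrix(genotypes)) {
    f <- matrix(genotype_factor(as.vector(genotypes), theta1, theta2),
                nrow = nrow(genotypes))
    odds <- alpha * exp(rowSums(log(f)))
  } else {
    odds <- alpha * prod(genotype_factor(genotypes, theta1, theta2))
  }
  odds / (1 + odds)
}

## HWE genotype probabilities ((1-q)^2, 2q(1-q), q^2) for MAF q
hwe_probs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Solve the baseline odds for a target population prevalence
#'
#' Finds \eqn{\alpha} such that the population mean penetrance -- the sum of
#' [penetrance()] over all multi-locus genotypes weighted by their
#' Hardy-Weinberg/linkage-equilibrium probabilities -- equals the target.
#' The expectation is continuous and strictly increasing in \eqn{\alpha}, so
#' a bracketed root search on \eqn{\log\alpha} converges reliably.
#'
#' @param target_penetrance desired population case proportion in (0, 1).
#' @param mafs causal-SNP minor allele frequencies.
#' @param theta1,theta2 per-SNP effects.
#' @return The baseline odds `alpha`, accurate to |mean penetrance -
#'   target| <= 1e-10.
#' @export
solve_alpha <- function(target_penetrance, mafs, theta1, theta2) {
  stopifnot(target_penetrance > 0, target_penetrance < 1)
  p <- length(mafs)
  combos <- as.matrix(expand.grid(rep(list(0:2), p)))
  w <- apply(vapply(seq_len(p),
                    function(s) hwe_probs(mafs[s])[combos[, s] + 1],
                    numeric(nrow(combos))), 1L, prod)
  fac <- vapply(seq_len(nrow(combos)),
                function(r) prod(genotype_factor(combos[r, ], theta1, theta2)),
                numeric(1))
  f <- function(log_alpha) {
    odds <- exp(log_alpha) * fac
    sum(w * odds / (1 + odds)) - target_penetrance
  }
  root <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-14)
  alpha <- exp(root$root)
  err <- f(log(alpha))
  if (abs(err) > 1e-10) stop("alpha root-finding failed to converge")
  alpha
}

#' Simulate a case-control GWAS dataset
#'
#' Draws a retrospective case-control sample from the model in
#' [sim_model()]: population subjects get causal genotypes under
#' Hardy-Weinberg and linkage equilibrium, a Bernoulli disease status with
#' probability equal to their [penetrance()], and are kept until exactly
#' `n_cases` cases and `n_controls` controls are collected (rejection
#' sampling).  Non-causal SNPs are independent of the trait, so they are
#' drawn under HWE for the retained subjects only, with MAFs from
#' `null_maf_law`.  Causal SNPs are placed at seeded-random positions among
#' the columns.
#'
#' @param model a [sim_model()].
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return A list of class `"sim_gwas"`: `genotypes` (a
#'   [genotype_matrix()] of all causal + null SNPs), `trait` (factor with
#'   levels `control`, `case`), `causal` (ids of the causal SNPs),
#'   `null_mafs` (drawn null MAFs), `alpha` (baseline odds used), and
#'   `model`.
#' @export
simulate_gwas <- function(model, seed = NULL) {
  stopifnot(inherits(model, "sim_model"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$causal_mafs)
  alpha <- model$alpha
  if (is.null(alpha)) {
    alpha <- solve_alpha(model$total_penetrance, model$causal_mafs,
                         model$theta1, model$theta2)
  }

  need_case <- model$n_cases
  need_ctrl <- model$n_controls
  prev <- model$total_penetrance
  batch <- ceiling(1.3 * max(need_case / prev, need_ctrl / (1 - prev)))
  batch <- min(max(batch, 1000L), 2e6)

  causal <- matrix(NA_integer_, 0L, p)
  trait <- integer(0)
  attempts <- 0L
  while ((sum(trait == 1L) < need_case || sum(trait == 0L) < need_ctrl)) {
    attempts <- attempts + 1L
    if (attempts > 200L) {
      stop("case/control quotas unattainable after 200 sampling batches; ",
           "check the penetrance model")
    }
    g <- vapply(model$causal_mafs,
                function(q) stats::rbinom(batch, 2L, q),
                integer(batch))
    pen <- penetrance(g, alpha, model$theta1, model$theta2)
    y <- stats::rbinom(batch, 1L, pen)
    causal <- rbind(causal, g)
    trait <- c(trait, y)
  }
  keep <- c(which(trait == 1L)[seq_len(need_case)],
            which(trait == 0L)[seq_len(need_ctrl)])
  keep <- sort(keep)  # preserve draw order: no case/control blocking
  causal <- causal[keep, , drop = FALSE]
  trait <- trait[keep]

  n <- length(trait)
  m <- model$n_null_snps
  if (identical(model$null_maf_law, "causal")) {
    null_mafs <- rep_len(model$causal_mafs, m)
  } else {
    law <- model$null_maf_law
    stopifnot(is.numeric(law), length(law) == 2L)
    null_mafs <- stats::runif(m, law[1L], law[2L])
  }
  nulls <- if (m > 0L) {
    matrix(stats::rbinom(n * m, 2L, rep(null_mafs, each = n)), nrow = n)
  } else {
    matrix(integer(0), n, 0L)
  }

  total <- p + m
  ids <- sprintf("snp%0*d", max(4L, nchar(total)), seq_len(total))
  causal_pos <- sort(sample.int(total, p))
  codes <- matrix(NA_integer_, n, total)
  codes[, causal_pos] <- causal
  codes[, setdiff(seq_len(total), causal_pos)] <- nulls
  genos <- genotype_matrix(codes, snp_ids = ids,
                           sample_ids = paste0("s", seq_len(n)))
  structure(
    list(genotypes = genos,
         trait = factor(trait, levels = c(0, 1),
                        labels = c("control", "case")),
         causal = ids[causal_pos],
         null_mafs = null_mafs,
         alpha = alpha,
         model = model),
    class = "sim_gwas"
  )
}

#' @export
print.sim_gwas <- function(x, ...) {
  cat("Simulated case-control GWAS:", nrow(x$genotypes), "samples,",
      ncol(x$genotypes), "SNPs (", length(x$causal), "causal:",
      paste(x$causal, collapse = ", "), ")\n")
  cat("cases:", sum(x$trait == "case"),
      " controls:", sum(x$trait == "control"),
      " baseline odds alpha:", format(x$alpha, digits = 4), "\n")
  invisible(x)
}

#' Simulate an ordinal trait from the same linear predictor
#'
#' Extension beyond the binary case-control design: draws an ordered
#' categorical trait from a proportional-odds model whose linear predictor
#' is the log-odds of the multiplicative model,
#' \eqn{P(Y \le c) = logit^{-1}(\zeta_c - \eta)} with
#' \eqn{\eta = \log\alpha + \sum_s \log f(g_s)}.  Sampling is prospective
#' (no quotas).  This mirrors how an ordinal phenotype such as a 4-level
#' BMI class can be analysed with ordinal row scores.
#'
#' @param model a [sim_model()]; `alpha` / `total_penetrance` set the
#'   location of the linear predictor.
#' @param n number of subjects.
#' @param cutpoints increasing vector \eqn{\zeta_1 < ... < \zeta_{C-1}} of
#'   proportional-odds thresholds (C categories).
#' @param seed integer seed.
#' @return A list of class `"sim_gwas"` whose `trait` is an ordered factor
#'   with levels `1..C`.
#' @export
simulate_ordinal_gwas <- function(model, n, cutpoints = c(-1, 0, 1),
                                  seed = NULL) {
  stopifnot(inherits(model, "sim_model"), n >= 1,
            all(diff(cutpoints) > 0))
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$causal_mafs)
  alpha <- model$alpha
  if (is.null(alpha)) {
    alpha <- solve_alpha(model$total_penetrance, model$causal_mafs,
                         model$theta1, model$theta2)
  }
  g <- vapply(model$causal_mafs, function(q) stats::rbinom(n, 2L, q),
              integer(n))
  if (p == 1L) g <- matrix(g, ncol = 1L)
  eta <- log(alpha) +
    rowSums(matrix(log(genotype_factor(as.vector(g), model$theta1,
                                       model$theta2)), nrow = n))
  cum <- vapply(cutpoints, function(z) stats::plogis(z - eta), numeric(n))
  u <- stats::runif(n)
  y <- 1L + rowSums(u > cum)
  m <- model$n_null_snps
  if (identical(model$null_maf_law, "causal")) {
    null_mafs <- rep_len(model$causal_mafs, m)
  } else {
    null_mafs <- stats::runif(m, model$null_maf_law[1L],
                              model$null_maf_law[2L])
  }
  nulls <- if (m > 0L) {
    matrix(stats::rbinom(n * m, 2L, rep(null_mafs, each = n)), nrow = n)
  } else {
    matrix(integer(0), n, 0L)
  }
  total <- p + m
  ids <- sprintf("snp%0*d", max(4L, nchar(total)), seq_len(total))
  causal_pos <- sort(sample.int(total, p))
  codes <- matrix(NA_integer_, n, total)
  codes[, causal_pos] <- g
  codes[, setdiff(seq_len(total), causal_pos)] <- nulls
  structure(
    list(genotypes = genotype_matrix(codes, snp_ids = ids,
                                     sample_ids = paste0("s", seq_len(n))),
         trait = factor(y, levels = seq_len(length(cutpoints) + 1L),
                        ordered = TRUE),
         causal = ids[causal_pos],
         null_mafs = null_mafs,
         alpha = alpha,
         model = model),
    class = "sim_gwas"
  )
}
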