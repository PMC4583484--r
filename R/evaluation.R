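#' Stepwise logistic regression baseline
#'
#' Comparative baseline that mirrors the stepwise driver of
#' [cmh_stepwise()] exactly -- same forward/backward policy, thresholds and
#' restart rule -- but scores each candidate by the joint Wald test (df = 2)
#' of its two genotype dummies (heterozygote, minor homozygote) added to a
#' logistic model already containing dummies for the selected SNPs, the
#' test classical stepwise-logistic software applies to fitted
#' coefficients.  On sparse genotype cells the coefficient standard errors
#' inflate and the Wald p-value drifts toward 1 -- the characteristic
#' failure mode of logistic selection that the margin-based CMH covariance
#' avoids.  Non-convergence, or an addition whose dummies are all aliased,
#' is recorded as p = 1.
#'
#' @param genos a [genotype_matrix()].
#' @param pheno binary trait: factor (second level = case) or 0/1 vector.
#' @param config a [stepwise_config()]; `entry_threshold`,
#'   `removal_threshold`, `backward_enabled` and `max_set_size` are
#'   honoured (stratification settings do not apply).
#' @return An object of class `"logistic_stepwise"` with the same shape as
#'   a [cmh_stepwise()] result (`snp_sets`, `trace`, `config`).
#' @export
logistic_stepwise <- function(genos, pheno, config = stepwise_config()) {
  y <- if (is.factor(pheno)) as.integer(pheno) - 1L else as.integer(pheno)
  if (!all(y %in% c(0L, 1L), na.rm = TRUE)) {
    stop("the logistic baseline needs a binary trait")
  }
  dummies <- function(snps) {
    if (length(snps) == 0L) return(NULL)
    g <- genos[, snp_index(genos, snps), drop = FALSE]
    out <- cbind(g == 1L, g == 2L)
    storage.mode(out) <- "double"
    out
  }
  fit_logit <- function(X, rows, start = NULL) {
    suppressWarnings(stats::glm.fit(X[rows, , drop = FALSE], y[rows],
                                    family = stats::binomial(),
                                    start = start))
  }
  ## Joint Wald test of `extra` added to the model with design X0: fit the
  ## augmented model, pull the estimated coefficients and covariance block
  ## of the added dummies from the weighted QR, and refer b' V^{-1} b to a
  ## chi-square on the number of estimable added dummies.  The null fit is
  ## computed once per step and only supplies warm-start values.
  wald_p <- function(extra, X0, rows0, f0) {
    X1 <- cbind(X0, extra)
    tryCatch({
      rows <- rows0
      if (anyNA(extra)) {
        rows <- rows0 & stats::complete.cases(extra)
        f0 <- fit_logit(X0, rows)
      }
      start <- c(f0$coefficients, numeric(ncol(X1) - ncol(X0)))
      f1 <- tryCatch(fit_logit(X1, rows, start = start),
                     error = function(e) fit_logit(X1, rows))
      if (!f0$converged || !f1$converged) return(1)
      rank <- f1$rank
      piv <- f1$qr$pivot[seq_len(rank)]
      cov_all <- matrix(NA_real_, ncol(X1), ncol(X1))
      cov_all[piv, piv] <- chol2inv(f1$qr$qr[seq_len(rank), seq_len(rank),
                                             drop = FALSE])
      added <- seq(ncol(X0) + 1L, ncol(X1))
      est <- added[added %in% piv]  # non-aliased added dummies
      if (length(est) == 0L) return(1)
      b <- f1$coefficients[est]
      V <- cov_all[est, est, drop = FALSE]
      w <- tryCatch(drop(crossprod(b, solve(V, b))), error = function(e) 0)
      stats::pchisq(max(w, 0), df = length(est), lower.tail = FALSE)
    }, error = function(e) 1)
  }
  null_design <- function(selected) {
    base <- dummies(selected)
    intercept <- rep(1, length(y))
    X0 <- if (is.null(base)) cbind(intercept) else cbind(intercept, base)
    rows0 <- !is.na(y) & stats::complete.cases(X0)
    list(X0 = X0, rows0 = rows0, f0 = fit_logit(X0, rows0))
  }
  forward_fn <- function(selected, candidates) {
    empty <- list(snp = NULL, p_value = NA_real_, statistic = NA_real_,
                  df = NA_integer_,
                  tests = data.frame(snp = character(), p_value = numeric()))
    if (length(candidates) == 0L) return(empty)
    nd <- null_design(selected)
    ps <- vapply(candidates, function(s) {
      wald_p(dummies(s), nd$X0, nd$rows0, nd$f0)
    }, numeric(1))
    tests <- data.frame(snp = candidates, p_value = unname(ps))
    best <- order(tests$p_value, seq_along(candidates))[1L]
    if (tests$p_value[best] < config$entry_threshold) {
      list(snp = tests$snp[best], p_value = tests$p_value[best],
           statistic = NA_real_, df = 2L, tests = tests)
    } else {
      empty$tests <- tests
      empty
    }
  }
  backward_fn <- function(selected) {
    ps <- vapply(seq_along(selected), function(m) {
      nd <- null_design(selected[-m])
      wald_p(dummies(selected[m]), nd$X0, nd$rows0, nd$f0)
    }, numeric(1))
    tests <- data.frame(snp = selected, p_value = ps)
    worst <- which.max(ps)
    if (ps[worst] > config$removal_threshold) {
      list(snp = selected[worst], p_value = ps[worst], tests = tests)
    } else {
      list(snp = NULL, p_value = NA_real_, tests = tests)
    }
  }
  fit <- stepwise_driver(colnames(genos), forward_fn, backward_fn, config)
  class(fit) <- "logistic_stepwise"
  fit
}

#' @export
print.logistic_stepwise <- function(x, ...) {
  cat("Stepwise logistic selection:", length(x$snp_sets), "SNP set(s)\n")
  for (i in seq_along(x$snp_sets)) {
    cat(sprintf("  set %d: %s\n", i, paste(x$snp_sets[[i]], collapse = ", ")))
  }
  if (length(x$snp_sets) == 0L) cat("  (no significant SNPs)\n")
  invisible(x)
}

#' Score one replicate's selection against the simulation truth
#'
#' Detection is counted per true causal SNP: the captured fraction is
#' |selected intersect truth| / |truth| (false positives do not reduce it),
#' and the replicate counts toward power only when every causal SNP is
#' captured.
#'
#' @param selected character vector of selected SNP ids (typically
#'   [selected_snps()] of a stepwise fit, i.e. the union over all
#'   discovered sets).
#' @param truth non-empty character vector of causal SNP ids.
#' @return List with `fraction` in \[0, 1\] and `all_captured` flag.
#' @export
score_replicate <- function(selected, truth) {
  if (length(truth) == 0L) stop("'truth' must be non-empty")
  fraction <- length(intersect(selected, truth)) / length(truth)
  list(fraction = fraction, all_captured = fraction == 1)
}

#' Replicate power study over a scenario grid
#'
#' For each scenario (a row of `scenarios`) and each method, simulates
#' `n_replicates` case-control datasets via [simulate_gwas()], runs the
#' stepwise selection, and aggregates two accuracy measures: the detection
#' probability `dprob` (mean captured fraction of the true causal SNPs) and
#' `power` (fraction of replicates capturing all of them).  Per-replicate
#' seeds are derived deterministically from `seed`, so the study is
#' reproducible and invariant to the order in which scenarios and methods
#' are evaluated.
#'
#' @param scenarios data frame with columns `maf` (causal MAF, shared by
#'   all causal SNPs), `n_causal`, `n_snps` (total SNP count), and
#'   `threshold` (entry = removal significance level).  Optional columns
#'   `n_cases`, `n_controls`, `theta1`, `theta2`, `total_penetrance`
#'   override the defaults of [sim_model()].
#' @param n_replicates replicates per scenario.
#' @param methods subset of `c("stepwise_cmh", "stepwise_logistic")`.
#' @param seed master seed.
#' @param cap stratum cap passed to the CMH method.
#' @return Data frame with one row per scenario x method: the scenario
#'   columns plus `method`, `dprob`, `power`, `n_replicates`.
#' @export
run_study <- function(scenarios, n_replicates,
                      methods = c("stepwise_cmh", "stepwise_logistic"),
                      seed = 1L, cap = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates == 0L || nrow(scenarios) == 0L) {
    out <- scenarios[integer(0), , drop = FALSE]
    out$method <- character(0)
    out$dprob <- numeric(0)
    out$power <- numeric(0)
    out$n_replicates <- integer(0)
    return(out)
  }
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(scenarios) * n_replicates),
                      nrow = nrow(scenarios))
  rows <- list()
  for (sc in seq_len(nrow(scenarios))) {
    s <- scenarios[sc, ]
    grab <- function(col, default) if (col %in% names(s)) s[[col]] else default
    model <- sim_model(
      theta1 = grab("theta1", 0.7),
      theta2 = grab("theta2", 0.5),
      causal_mafs = rep(s$maf, s$n_causal),
      total_penetrance = grab("total_penetrance", 0.1),
      n_null_snps = s$n_snps - s$n_causal,
      n_cases = grab("n_cases", 1000L),
      n_controls = grab("n_controls", 1000L)
    )
    config <- stepwise_config(entry_threshold = s$threshold,
                              removal_threshold = s$threshold,
                              cap = cap)
    caught <- matrix(NA_real_, n_replicates, length(methods),
                     dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      sim <- simulate_gwas(model, seed = rep_seeds[sc, r])
      for (m in methods) {
        sel <- tryCatch({
          fit <- switch(m,
            stepwise_cmh = cmh_stepwise(sim$genotypes, sim$trait, config),
            stepwise_logistic = logistic_stepwise(sim$genotypes, sim$trait,
                                                  config)
          )
          selected_snps(fit)
        }, error = function(e) {
          warning("replicate ", r, " failed for ", m, ": ",
                  conditionMessage(e))
          character(0)
        })
        caught[r, m] <- score_replicate(sel, sim$causal)$fraction
      }
    }
    for (m in methods) {
      row <- s
      row$method <- m
      row$dprob <- mean(caught[, m])
      row$power <- mean(caught[, m] == 1)
      row$n_replicates <- n_replicates
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
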