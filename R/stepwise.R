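#' Configuration for stepwise SNP selection
#'
#' Collects the tuning parameters of the stepwise CMH procedure (and of the
#' stepwise logistic baseline, which honours the thresholds and trait type).
#'
#' @param entry_threshold significance level a candidate must beat to enter
#'   the selected set.
#' @param removal_threshold significance level above which a member is
#'   eliminated in the backward step.  Default: same as entry.
#' @param scheme stratification scheme for the conditioning set,
#'   `"mac_sum"` (default) or `"full_cross"`; see [assign_strata()].
#' @param cap maximum stratum count under `mac_sum`.
#' @param trait_type `"binary"`, `"nominal"` or `"ordinal"`.  Binary and
#'   nominal traits use nominal row weighting (general association test);
#'   ordinal traits use row scores 1..I (mean-score or correlation test).
#' @param genetic_model genotype (column) weighting: `"codominant"`
#'   (nominal, 2 df per SNP), or mean-score codings `"additive"` (0,1,2),
#'   `"dominant"` (0,1,1), `"recessive"` (0,0,1).
#' @param backward_enabled run the backward elimination step (default TRUE).
#' @param max_set_size hard limit on the size of one selected set (guards
#'   termination).
#' @return A list of class `"stepwise_config"`.
#' @export
stepwise_config <- function(entry_threshold = 5e-5,
                            removal_threshold = entry_threshold,
                            scheme = c("mac_sum", "full_cross"),
                            cap = 10L,
                            trait_type = c("binary", "nominal", "ordinal"),
                            genetic_model = c("codominant", "additive",
                                              "dominant", "recessive"),
                            backward_enabled = TRUE,
                            max_set_size = 20L) {
  stopifnot(entry_threshold > 0, entry_threshold <= 1,
            removal_threshold > 0, removal_threshold <= 1,
            max_set_size >= 1)
  structure(
    list(
      entry_threshold = entry_threshold,
      removal_threshold = removal_threshold,
      scheme = match.arg(scheme),
      cap = as.integer(cap),
      trait_type = match.arg(trait_type),
      genetic_model = match.arg(genetic_model),
      backward_enabled = isTRUE(backward_enabled),
      max_set_size = as.integer(max_set_size)
    ),
    class = "stepwise_config"
  )
}

row_scheme_for <- function(config, pheno) {
  if (config$trait_type == "ordinal") {
    f <- if (is.factor(pheno)) pheno else factor(pheno)
    score_scheme("ordinal", scores = seq_len(nlevels(f)))
  } else {
    score_scheme("nominal")
  }
}

col_scheme_for <- function(config) {
  switch(config$genetic_model,
    codominant = score_scheme("nominal"),
    additive   = score_scheme("ordinal", scores = c(0, 1, 2)),
    dominant   = score_scheme("ordinal", scores = c(0, 1, 1)),
    recessive  = score_scheme("ordinal", scores = c(0, 0, 1))
  )
}

## Test one candidate SNP conditioned on `selected`, reusing a precomputed
## strata assignment.  Returns p, statistic and df (p = 1 when the test is
## undefined, e.g. the candidate is monomorphic among complete cases).
cmh_conditional <- function(candidate, strata, genos, pheno,
                            row_scheme, col_scheme) {
  tab <- build_table(pheno, candidate, strata, genos)
  ## drop unobserved genotype columns so monomorphic candidates degrade
  ## gracefully instead of zero-inflating the covariance rank
  keep <- apply(tab, 2L, sum) > 0
  res <- tryCatch({
    if (sum(keep) < 2L) stop("candidate has fewer than two observed genotypes")
    cs <- col_scheme
    if (cs$kind == "ordinal") {
      cs <- score_scheme("ordinal", scores = cs$scores[keep])
    }
    cmh_test(tab[, keep, , drop = FALSE], row_scheme, cs)
  }, error = function(e) NULL)
  if (is.null(res)) {
    list(p = 1, statistic = NA_real_, df = NA_integer_)
  } else {
    list(p = res$p.value, statistic = unname(res$statistic),
         df = unname(res$parameter))
  }
}

#' One forward step of the stepwise CMH procedure
#'
#' Tests every candidate SNP as the column variable of a trait x genotype x
#' stratum table, stratified on the currently selected set (a single stratum
#' when nothing is selected yet).  The candidate with the smallest p-value is
#' added if that p-value is below the entry threshold.  Ties on p are broken
#' by the larger statistic, then by candidate order.
#'
#' @param selected character vector of already selected SNP ids.
#' @param candidates character vector of candidate SNP ids (disjoint from
#'   `selected`).
#' @param genos a [genotype_matrix()].
#' @param pheno trait vector.
#' @param config a [stepwise_config()].
#' @return List with `snp` (the added SNP id, or `NULL` if none qualified),
#'   `p_value`, `statistic`, `df`, and `tests` (data frame of all candidate
#'   tests this step).
#' @export
forward_step <- function(selected, candidates, genos, pheno, config) {
  if (length(intersect(selected, candidates)) > 0L) {
    stop("'selected' and 'candidates' must be disjoint")
  }
  empty <- list(snp = NULL, p_value = NA_real_, statistic = NA_real_,
                df = NA_integer_,
                tests = data.frame(snp = character(), p_value = numeric(),
                                   statistic = numeric(), df = integer()))
  if (length(candidates) == 0L) return(empty)
  strata <- if (length(selected) == 0L) NULL else {
    assign_strata(genos, selected, scheme = config$scheme, cap = config$cap)
  }
  rs <- row_scheme_for(config, pheno)
  cs <- col_scheme_for(config)
  res <- lapply(candidates, cmh_conditional, strata = strata, genos = genos,
                pheno = pheno, row_scheme = rs, col_scheme = cs)
  tests <- data.frame(
    snp = candidates,
    p_value = vapply(res, `[[`, numeric(1), "p"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, function(r) as.integer(r$df), integer(1))
  )
  ## minimum p; ties -> larger statistic; remaining ties -> input order
  stat_key <- ifelse(is.na(tests$statistic), -Inf, tests$statistic)
  best <- order(tests$p_value, -stat_key, seq_along(candidates))[1L]
  if (tests$p_value[best] < config$entry_threshold) {
    list(snp = tests$snp[best], p_value = tests$p_value[best],
         statistic = tests$statistic[best], df = tests$df[best],
         tests = tests)
  } else {
    empty$tests <- tests
    empty
  }
}

#' One backward step of the stepwise CMH procedure
#'
#' Retests every member of the selected set conditioned on all the other
#' members.  If any p-value exceeds the removal threshold, the single worst
#' offender (largest p) is removed; otherwise nothing changes.
#'
#' @inheritParams forward_step
#' @return List with `snp` (the removed SNP id or `NULL`), `p_value`, and
#'   `tests` (data frame of all member tests).
#' @export
backward_step <- function(selected, genos, pheno, config) {
  if (length(selected) == 0L) stop("backward step needs a non-empty set")
  rs <- row_scheme_for(config, pheno)
  cs <- col_scheme_for(config)
  res <- lapply(seq_along(selected), function(m) {
    others <- selected[-m]
    strata <- if (length(others) == 0L) NULL else {
      assign_strata(genos, others, scheme = config$scheme, cap = config$cap)
    }
    cmh_conditional(selected[m], strata, genos, pheno, rs, cs)
  })
  tests <- data.frame(
    snp = selected,
    p_value = vapply(res, `[[`, numeric(1), "p"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, function(r) as.integer(r$df), integer(1))
  )
  worst <- which.max(tests$p_value)
  if (tests$p_value[worst] > config$removal_threshold) {
    list(snp = tests$snp[worst], p_value = tests$p_value[worst], tests = tests)
  } else {
    list(snp = NULL, p_value = NA_real_, tests = tests)
  }
}

#' Stepwise CMH discovery of disjoint SNP sets
#'
#' Alternates forward addition and backward elimination until a forward step
#' adds nothing; the accumulated set is then closed, its members are removed
#' from the candidate pool, and the procedure restarts from the empty set.
#' It terminates when the first forward step of a round finds no significant
#' SNP.  A visited-state check and `max_set_size` guard against add/remove
#' oscillation.
#'
#' @param genos a [genotype_matrix()].
#' @param pheno trait vector (binary, nominal or ordinal; see
#'   [stepwise_config()]).
#' @param config a [stepwise_config()].
#' @return An object of class `"cmh_stepwise"`: list with `snp_sets` (list of
#'   character vectors, pairwise disjoint, in discovery order), `trace`
#'   (data frame of every step: round, step kind, SNP acted on, p-value, df,
#'   action), and `config`.
#' @examples
#' sim <- simulate_gwas(sim_model(causal_mafs = c(0.2, 0.2), n_null_snps = 8,
#'                                n_cases = 300, n_controls = 300), seed = 7)
#' fit <- cmh_stepwise(sim$genotypes, sim$trait,
#'                     stepwise_config(entry_threshold = 5e-3))
#' fit
#' @export
cmh_stepwise <- function(genos, pheno, config = stepwise_config()) {
  fit <- stepwise_driver(
    pool = colnames(genos),
    forward_fn = function(selected, candidates) {
      forward_step(selected, candidates, genos, pheno, config)
    },
    backward_fn = function(selected) {
      backward_step(selected, genos, pheno, config)
    },
    config = config
  )
  class(fit) <- "cmh_stepwise"
  fit
}

## Shared forward/backward selection loop.  Both the CMH procedure and the
## logistic baseline run through this, so they differ only in the
## conditional test, never in selection policy.
stepwise_driver <- function(pool, forward_fn, backward_fn, config) {
  sets <- list()
  trace <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    selected <- character()
    visited <- character()
    first_forward <- TRUE
    repeat {
      fw <- forward_fn(selected, setdiff(pool, selected))
      if (is.null(fw$snp)) {
        trace[[length(trace) + 1L]] <- data.frame(
          round = round, step = "forward", snp = NA_character_,
          p_value = suppressWarnings(min(fw$tests$p_value, Inf)),
          df = NA_integer_, action = "stop")
        break
      }
      selected <- c(selected, fw$snp)
      first_forward <- FALSE
      trace[[length(trace) + 1L]] <- data.frame(
        round = round, step = "forward", snp = fw$snp, p_value = fw$p_value,
        df = fw$df, action = "add")
      state <- paste(sort(selected), collapse = "|")
      if (state %in% visited || length(selected) >= config$max_set_size) {
        break  # cycle or size guard: close the set as it stands
      }
      visited <- c(visited, state)
      if (config$backward_enabled && length(selected) > 1L) {
        bw <- backward_fn(selected)
        if (!is.null(bw$snp)) {
          selected <- setdiff(selected, bw$snp)
          trace[[length(trace) + 1L]] <- data.frame(
            round = round, step = "backward", snp = bw$snp,
            p_value = bw$p_value, df = NA_integer_, action = "remove")
        }
      }
    }
    if (length(selected) > 0L) {
      sets[[length(sets) + 1L]] <- selected
      pool <- setdiff(pool, selected)
    }
    ## the whole procedure stops when a round's FIRST forward step adds
    ## nothing (or the pool is exhausted)
    if (first_forward || length(pool) == 0L) break
  }
  list(snp_sets = sets,
       trace = do.call(rbind, trace),
       config = config)
}

#' @export
print.cmh_stepwise <- function(x, ...) {
  cat("Stepwise CMH selection:", length(x$snp_sets), "SNP set(s)\n")
  for (i in seq_along(x$snp_sets)) {
    cat(sprintf("  set %d: %s\n", i, paste(x$snp_sets[[i]], collapse = ", ")))
  }
  if (length(x$snp_sets) == 0L) cat("  (no significant SNPs)\n")
  invisible(x)
}

#' Union of all SNPs discovered by a stepwise fit
#'
#' @param fit a [cmh_stepwise()] (or [logistic_stepwise()]) result.
#' @return Character vector of all selected SNP ids.
#' @export
selected_snps <- function(fit) {
  unique(unlist(fit$snp_sets, use.names = FALSE))
}
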