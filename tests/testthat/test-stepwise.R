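# A small dataset with one overwhelming causal SNP and a handful of nulls,
# reused across the stepwise contract tests.
strong_sim <- function(seed = 101, maf = 0.2, n_null = 8) {
  simulate_gwas(sim_model(causal_mafs = maf, n_null_snps = n_null,
                          n_cases = 500, n_controls = 500),
                seed = seed)
}

test_that("the first forward step picks the strong causal SNP", {
  hits <- 0L
  for (seed in 1:8) {
    sim <- strong_sim(seed)
    fw <- forward_step(character(0), colnames(sim$genotypes),
                       sim$genotypes, sim$trait,
                       stepwise_config(entry_threshold = 5e-3))
    expect_lt(fw$p_value, 5e-3)
    hits <- hits + identical(fw$snp, sim$causal)
  }
  expect_gte(hits, 7L)  # the causal SNP wins the minimum-p race
})

test_that("forward step returns none when nothing clears the threshold", {
  sim <- strong_sim(3)
  fw <- forward_step(character(0), colnames(sim$genotypes),
                     sim$genotypes, sim$trait,
                     stepwise_config(entry_threshold = 1e-30))
  expect_null(fw$snp)
  expect_equal(nrow(fw$tests), ncol(sim$genotypes))
  # empty candidate pool is not an error
  fw0 <- forward_step(character(0), character(0), sim$genotypes, sim$trait,
                      stepwise_config())
  expect_null(fw0$snp)
  expect_error(forward_step("snp1", c("snp1", "snp2"), sim$genotypes,
                            sim$trait, stepwise_config()), "disjoint")
})

test_that("backward step removes only the single worst offender", {
  sim <- strong_sim(5)
  null_snps <- setdiff(colnames(sim$genotypes), sim$causal)[1:2]
  sel <- c(sim$causal, null_snps)
  cfg <- stepwise_config(entry_threshold = 0.5, removal_threshold = 0.05)
  bw <- backward_step(sel, sim$genotypes, sim$trait, cfg)
  expect_true(bw$snp %in% null_snps)  # the causal SNP survives
  expect_identical(bw$snp, bw$tests$snp[which.max(bw$tests$p_value)])
  # with a removal threshold of 1 nothing can be removed
  bw2 <- backward_step(sel, sim$genotypes, sim$trait,
                       stepwise_config(entry_threshold = 0.5,
                                       removal_threshold = 1))
  expect_null(bw2$snp)
  # singleton set: tested unconditionally
  bw3 <- backward_step(sim$causal, sim$genotypes, sim$trait, cfg)
  expect_null(bw3$snp)
})

test_that("discovered sets are disjoint and their SNPs never reappear", {
  sim <- simulate_gwas(sim_model(causal_mafs = c(0.2, 0.2), n_null_snps = 18,
                                 n_cases = 800, n_controls = 800), seed = 17)
  fit <- cmh_stepwise(sim$genotypes, sim$trait,
                      stepwise_config(entry_threshold = 5e-2))
  all_members <- unlist(fit$snp_sets)
  expect_identical(anyDuplicated(all_members), 0L)
  # every set after the first contains no SNP from earlier sets
  if (length(fit$snp_sets) > 1) {
    for (i in 2:length(fit$snp_sets)) {
      expect_length(intersect(fit$snp_sets[[i]],
                              unlist(fit$snp_sets[1:(i - 1)])), 0L)
    }
  }
})

test_that("every addition in the trace cleared the entry threshold", {
  sim <- simulate_gwas(sim_model(causal_mafs = c(0.1, 0.1), n_null_snps = 18,
                                 n_cases = 600, n_controls = 600), seed = 23)
  cfg <- stepwise_config(entry_threshold = 1e-2)
  fit <- cmh_stepwise(sim$genotypes, sim$trait, cfg)
  adds <- fit$trace[fit$trace$action == "add", ]
  expect_true(all(adds$p_value < cfg$entry_threshold))
  # with backward enabled, every final member is below the removal
  # threshold conditioned on its co-members
  for (set in fit$snp_sets) {
    tests <- backward_step(set, sim$genotypes, sim$trait, cfg)$tests
    expect_true(all(tests$p_value <= cfg$removal_threshold))
  }
})

test_that("the procedure is deterministic for fixed data and config", {
  sim <- strong_sim(29, n_null = 12)
  cfg <- stepwise_config(entry_threshold = 5e-2)
  a <- cmh_stepwise(sim$genotypes, sim$trait, cfg)
  b <- cmh_stepwise(sim$genotypes, sim$trait, cfg)
  expect_identical(a$snp_sets, b$snp_sets)
  expect_identical(a$trace, b$trace)
})

test_that("null data yields an empty selection at a strict threshold", {
  sim <- simulate_gwas(sim_model(theta1 = 0, theta2 = 0,
                                 causal_mafs = c(0.2, 0.2),
                                 total_penetrance = 0.5, n_null_snps = 28,
                                 n_cases = 400, n_controls = 400), seed = 31)
  fit <- cmh_stepwise(sim$genotypes, sim$trait,
                      stepwise_config(entry_threshold = 5e-4))
  expect_length(fit$snp_sets, 0L)
})

test_that("max_set_size caps a runaway round", {
  sim <- simulate_gwas(sim_model(causal_mafs = c(0.2, 0.2), n_null_snps = 18,
                                 n_cases = 500, n_controls = 500), seed = 37)
  fit <- cmh_stepwise(sim$genotypes, sim$trait,
                      stepwise_config(entry_threshold = 0.9,
                                      removal_threshold = 1,
                                      max_set_size = 3))
  expect_true(all(lengths(fit$snp_sets) <= 3))
})

test_that("ordinal traits use mean-score rows through the stepwise path", {
  sim <- simulate_ordinal_gwas(sim_model(causal_mafs = 0.3, n_null_snps = 5),
                               n = 800, seed = 41)
  cfg <- stepwise_config(entry_threshold = 5e-2, trait_type = "ordinal",
                         genetic_model = "additive")
  fw <- forward_step(character(0), colnames(sim$genotypes), sim$genotypes,
                     sim$trait, cfg)
  # both margins ordinal: the per-candidate tests are correlation tests, 1 df
  expect_true(all(fw$tests$df[!is.na(fw$tests$df)] == 1L))
})
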