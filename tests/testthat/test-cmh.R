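test_that("expected counts are the product of margins over the total", {
  expect_equal(as.vector(expected_counts(rbind(c(1, 0), c(0, 1)))),
               rep(0.5, 4))
  # uniform slice: observed counts already satisfy independence
  u <- matrix(3, 2, 3)
  expect_equal(expected_counts(u), u)
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rpois(6, 5), 2, 3)
    if (sum(m) < 1) next
    mu <- expected_counts(m)
    for (a in 1:2) for (b in 1:3) {
      expect_equal(mu[a, b], rowSums(m)[a] * colSums(m)[b] / sum(m))
    }
    expect_equal(sum(mu), sum(m))
  }
  expect_error(expected_counts(matrix(0, 2, 2)), "empty stratum")
})

test_that("covariance matrix matches the hypergeometric formula and oracle", {
  m <- rbind(c(3, 1, 2), c(2, 4, 1))
  n <- sum(m); r <- rowSums(m); s <- colSums(m)
  V <- variance_matrix(m)
  # diagonal: n_{i+}(n - n_{i+}) n_{+j}(n - n_{+j}) / (n^2 (n-1))
  expect_equal(V[1, 1], r[1] * (n - r[1]) * s[1] * (n - s[1]) / (n^2 * (n - 1)))
  expect_equal(V, t(V))
  expect_true(all(abs(rowSums(V)) < 1e-12))  # margins are fixed

  # zero row margin forces zero variance everywhere
  expect_equal(variance_matrix(rbind(c(2, 3), c(0, 0))), matrix(0, 4, 4))

  # exhaustive multivariate-hypergeometric enumeration on tiny 2x2 strata
  set.seed(11)
  for (i in 1:20) {
    sl <- matrix(rpois(4, 1.2), 2, 2)
    if (sum(sl) < 2) next
    expect_equal(variance_matrix(sl), hypergeom_cov_2x2(sl),
                 tolerance = 1e-12)
  }
  expect_error(variance_matrix(matrix(c(1, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("count validation rejects negative and non-finite tables", {
  expect_error(cmh_test(matrix(c(1, -1, 2, 3), 2, 2)), "non-negative")
  expect_error(cmh_test(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
  expect_error(cmh_test(matrix(c(1, Inf, 2, 3), 2, 2)), "finite")
})

test_that("test type and degrees of freedom follow the score schemes", {
  tab <- random_table(2, 3, 2)
  g <- cmh_test(tab)
  expect_identical(g$test_type, "general")
  expect_identical(unname(g$parameter), 2L)  # (I-1)(J-1)
  ms <- cmh_test(tab, col_scheme = 0:2)
  expect_identical(ms$test_type, "mean_score")
  expect_identical(unname(ms$parameter), 1L)  # rows stay nominal: I-1
  ms2 <- cmh_test(random_table(3, 3, 2), row_scheme = 1:3)
  expect_identical(unname(ms2$parameter), 2L) # columns nominal: J-1
  co <- cmh_test(tab, row_scheme = 1:2, col_scheme = 0:2)
  expect_identical(co$test_type, "correlation")
  expect_identical(unname(co$parameter), 1L)
})

test_that("a table with proportional rows gives a zero statistic", {
  m <- rbind(c(2, 4, 6), c(4, 8, 12))  # rows proportional: n = mu exactly
  r <- cmh_test(m)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
})

test_that("unstratified general CMH equals (n-1)/n times Pearson chi-square", {
  set.seed(21)
  for (i in 1:50) {
    m <- random_table(2, 3, 1)[, , 1]
    n <- sum(m)
    expect_equal(unname(cmh_test(m)$statistic),
                 (n - 1) / n * pearson_chisq(m), tolerance = 1e-10)
  }
})

test_that("unstratified correlation CMH equals (n-1) r^2", {
  set.seed(22)
  for (i in 1:50) {
    m <- random_table(2, 3, 1)[, , 1]
    n <- sum(m)
    rows <- rep(rep(1:2, 3), as.vector(m))
    cols <- rep(rep(c(0, 1, 2), each = 2), as.vector(m))
    r2 <- cor(rows, cols)^2
    expect_equal(unname(cmh_test(m, row_scheme = 1:2,
                                 col_scheme = c(0, 1, 2))$statistic),
                 (n - 1) * r2, tolerance = 1e-10)
  }
})

test_that("2x2xK general CMH is the classical MH statistic, uncorrected", {
  set.seed(23)
  for (i in 1:30) {
    a <- random_table(2, 2, 3)
    num <- 0; den <- 0
    for (k in 1:3) {
      sl <- a[, , k]; n <- sum(sl)
      num <- num + sl[1, 1] - rowSums(sl)[1] * colSums(sl)[1] / n
      den <- den + prod(rowSums(sl)) * prod(colSums(sl)) / (n^2 * (n - 1))
    }
    expect_equal(unname(cmh_test(a)$statistic), num^2 / den,
                 tolerance = 1e-10)
    # and agrees with the standard library routine
    expect_equal(unname(cmh_test(a)$statistic),
                 unname(mantelhaen.test(a, correct = FALSE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("statistic is invariant under stratum permutation and inert strata", {
  set.seed(24)
  tab <- random_table(2, 3, 4)
  base <- cmh_test(tab)
  perm <- cmh_test(tab[, , c(3, 1, 4, 2)])
  expect_equal(base$statistic, perm$statistic)
  expect_equal(base$p.value, perm$p.value)
  # appending an all-zero stratum changes nothing but the dropped count
  padded <- array(0, dim = c(2, 3, 5))
  padded[, , 1:4] <- tab
  pad <- cmh_test(padded)
  expect_equal(pad$statistic, base$statistic)
  expect_equal(pad$parameter, base$parameter)
  expect_equal(pad$p.value, base$p.value)
  expect_identical(pad$n_strata_dropped, 1L)
})

test_that("general statistic is invariant to level relabeling", {
  set.seed(25)
  tab <- random_table(3, 3, 2)
  base <- cmh_test(tab)
  rel <- cmh_test(tab[c(2, 3, 1), c(3, 1, 2), ])
  expect_equal(base$statistic, rel$statistic, tolerance = 1e-10)
})

test_that("correlation statistic is invariant to affine score changes", {
  set.seed(26)
  tab <- random_table(2, 3, 3)
  base <- cmh_test(tab, row_scheme = c(0, 1), col_scheme = c(0, 1, 2))
  scaled <- cmh_test(tab, row_scheme = c(10, 30),
                     col_scheme = 5 + 2 * c(0, 1, 2))
  expect_equal(base$statistic, scaled$statistic, tolerance = 1e-10)
})

test_that("randomized tables always give finite L2 >= 0 and p in [0,1]", {
  set.seed(27)
  for (i in 1:100) {
    tab <- array(rpois(2 * 3 * 2, 2), dim = c(2, 3, 2))
    if (all(apply(tab, 3, sum) < 2)) next
    r <- cmh_test(tab)
    expect_gte(unname(r$statistic), 0)
    expect_gte(r$p.value, 0)
    expect_lte(r$p.value, 1)
  }
})

test_that("degenerate strata are dropped; all-degenerate tables refuse", {
  a <- array(0, dim = c(2, 2, 2))
  a[1, 1, 1] <- 1  # single observation: no information
  expect_error(cmh_test(a), "untestable")
  b <- array(c(1, 0, 0, 0,  5, 2, 3, 4), dim = c(2, 2, 2))
  r <- cmh_test(b)
  expect_identical(r$n_strata_used, 1L)
  expect_identical(r$n_strata_dropped, 1L)
})

test_that("singular pooled covariance reduces df and flags rank deficiency", {
  # an unobserved genotype column makes the pooled covariance singular
  m <- rbind(c(5, 5, 0), c(2, 2, 0))
  r <- cmh_test(m)
  expect_true(r$rank_deficient)
  expect_lt(unname(r$parameter), 2)
  expect_gte(unname(r$statistic), 0)
  expect_lte(r$p.value, 1)
})
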