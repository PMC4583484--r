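---
title: "Methods: stepwise generalized CMH selection of jointly associated SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stepwise generalized CMH selection of jointly associated SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmhstep)
```

## The problem

Single-marker association scans miss genetic architecture that only shows up
jointly: several SNPs, each of modest marginal effect, acting together on a
categorical trait. The standard multi-marker tool, logistic regression over
genotype dummies, degrades exactly where joint analysis is most interesting
-- when conditioning on several SNPs fragments the data into sparse genotype
cells, the Wald/likelihood machinery inflates standard errors and p-values
drift toward one, and refitting a full model for every candidate SNP at
genome scale is expensive.

`cmhstep` takes a contingency-table route instead. Each candidate SNP is
tested for conditional independence from the trait *given* the
already-selected SNPs, using the generalized Cochran-Mantel-Haenszel (CMH)
statistic on a stratified trait x genotype x stratum table. The CMH
covariance is built from stratum margins only, so sparse interior cells do
not destabilize it, and the statistic is a closed-form matrix expression --
no iterative fitting.

## The generalized CMH statistic

For an $I \times J \times K$ table with observed cell-count vector $n_k$ in
stratum $k$, null expectation $\mu_{ijk} = n_{i+k} n_{+jk} / n_{++k}$ and
the multivariate hypergeometric covariance

$$\mathrm{Cov}(n_{ijk}, n_{i'j'k}) =
  \frac{n_{i+k}(\delta_{ii'} n_{++k} - n_{i'+k})\;
        n_{+jk}(\delta_{jj'} n_{++k} - n_{+j'k})}
       {n_{++k}^2 (n_{++k} - 1)},$$

the statistic is

$$L^2 = \Big[\textstyle\sum_k B_k (n_k - \mu_k)\Big]'
        \Big[\textstyle\sum_k B_k V_k B_k'\Big]^{-1}
        \Big[\textstyle\sum_k B_k (n_k - \mu_k)\Big],$$

where $B_k = u \otimes v$ is the Kronecker product of a row and a column
score matrix. Nominal margins contribute the $(L-1) \times L$ contrast
$(\mathbf{I} \mid -\mathbf{1})$; ordinal margins contribute a single score
row. The scheme combination selects the test and its reference chi-square
degrees of freedom:

| rows    | columns | test               | df             |
|---------|---------|--------------------|----------------|
| nominal | nominal | general association| $(I-1)(J-1)$   |
| one ordinal margin | | mean score      | $J-1$ or $I-1$ |
| ordinal | ordinal | correlation        | $1$            |

Genetic models are column score choices: codominant = nominal columns
(2 df per SNP), additive = scores $(0,1,2)$, dominant = $(0,1,1)$,
recessive = $(0,0,1)$. Tied ordinal scores are deliberately legal for this
reason. Ordinal traits (e.g. a 4-level BMI class) use row scores
$1, \dots, I$.

### Numerical choices

* **Singular pooled covariance.** Sparse or degenerate tables can make
  $\sum_k B_k V_k B_k'$ singular (e.g. an unobserved genotype column). We
  use the Moore-Penrose inverse via the symmetric eigendecomposition,
  count the rank as the number of eigenvalues above
  $q \cdot \varepsilon \cdot \lambda_{max}$ ($q$ = matrix dimension,
  $\varepsilon$ = machine epsilon), reduce the degrees of freedom to that
  rank, and flag `rank_deficient`. This keeps the statistic defined for
  exactly the sparse tables the method is meant to survive.
* **Strata with fewer than two subjects** are dropped from both sums: the
  covariance denominator $n(n-1)$ vanishes, and such strata carry no
  information. All-zero strata are therefore inert by construction.
* **No continuity correction** anywhere; the p-value is the upper tail of
  the chi-square at $L^2$.
* Inside the stepwise path, genotype columns unobserved among a candidate's
  complete cases are removed before testing (with ordinal scores subset
  accordingly) so monomorphic candidates degrade to a smaller table instead
  of an artificially rank-padded one; a candidate with fewer than two
  observed genotype levels is untestable and recorded with p = 1.

## Stratification of the conditioning set

Conditioning on $p$ selected SNPs by their full genotype cross gives up to
$3^p$ strata -- already 19,683 at $p = 9$ -- which shreds a cohort of a few
thousand into uninformative fragments. The operative scheme is therefore the
**MAC sum**: subjects are stratified by their total minor allele count over
the conditioning set, on the premise that subjects with a similar
minor-allele burden carry similar risk. Sums $0, 1, \dots, \mathrm{cap}-2$
are individual strata and everything at or above $\mathrm{cap}-1$ is merged
into one final stratum, so $K \le \min(2p + 1, \mathrm{cap})$ no matter how
many SNPs are conditioned on. Only the upper tail is merged: rare large
burdens are pooled, while the common low-burden strata stay resolved.

The default cap is 10 strata. With sample sizes in the low thousands this
keeps average per-stratum counts in the hundreds, large enough for the
hypergeometric covariance to be well-conditioned; it is configurable, and
the full-cross scheme remains available for small conditioning sets.
Strata are indexed by sorted observed keys, so unobserved genotype tuples
never create empty strata.

Missingness is handled per test, complete-case: a subject is excluded from
one candidate's table only if it is missing the trait, the candidate
genotype, or a genotype in the conditioning set. This preserves the most
data per test at the cost of test-to-test sample variation, which the
statistic tolerates because every table is self-contained.

## The stepwise procedure

Within one round:

1. **Forward.** Every candidate is tested conditioned on the current set
   (unstratified for the first step). The minimum-p candidate enters iff
   its p-value is below the entry threshold. Ties on p are broken by the
   larger statistic, then by input order -- fully deterministic.
2. **Backward** (optional, on by default). Each member is retested given
   the others; the single worst offender above the removal threshold
   leaves.
3. The round ends when a forward step adds nothing; the accumulated set is
   closed, removed from the pool, and a new round starts from scratch.
   The whole procedure stops when a round's *first* forward step finds
   nothing significant.

Two guards ensure termination on any finite input: a `max_set_size` cap,
and a visited-state check that closes the set if a forward addition
recreates a previously seen selected-set state (forward/backward stepwise
can oscillate; the guard makes the worst case a closed set rather than a
loop). Both entry and removal thresholds default to $5 \times 10^{-5}$, a
Bonferroni-style level for genome-wide panels after LD pruning; simulation
work typically uses $5 \times 10^{-4}$ or $5 \times 10^{-3}$ on panels of
100--1000 SNPs.

The discovered sets are pairwise disjoint by construction, and every
reported member was significant in the presence of its co-members when the
backward step is enabled.

## The simulation model

The generator draws causal genotypes under Hardy-Weinberg equilibrium and
linkage equilibrium, then assigns disease by a multiplicative odds model:
genotype 0/1/2 at each causal SNP multiplies a baseline odds $\alpha$ by
$1$, $(1+\theta_1)$ or $(1+\theta_2)$, and the penetrance is
$\mathrm{odds}/(1+\mathrm{odds})$. This is exactly a logistic model with
intercept $\log\alpha$ and codominant coefficients $\log(1+\theta_1)$,
$\log(1+\theta_2)$ -- an identity the test suite verifies by parameter
recovery. Defaults $\theta_1 = 0.7$, $\theta_2 = 0.5$ give a deliberately
non-monotone codominant effect (heterozygote odds 1.7, minor homozygote
1.5) that an additive single-marker scan under-serves.

Sampling is retrospective by rejection: population subjects are drawn and
kept until the case and control quotas (default 1000/1000) are exactly
filled. Because non-causal SNPs are independent of the trait, they are
drawn only for the retained subjects -- distributionally identical to
genotyping the whole population, and far cheaper. Null-SNP MAFs are drawn
uniformly on $[0.05, 0.5]$ by default (an option clones the causal MAFs
instead); causal SNPs sit at seeded-random column positions.

Two generator constants are package choices, made once:

* **Total penetrance (population prevalence) defaults to 0.1**, a typical
  complex-disease figure that keeps retrospective sampling cheap while
  leaving cases genuinely enriched for risk genotypes. $\alpha$ is solved
  from it by bracketed root finding on $\log\alpha$ (the population mean
  penetrance is continuous and strictly increasing in $\alpha$), to
  $|{\rm error}| \le 10^{-10}$.
* **The null-MAF law** $U[0.05, 0.5]$ spans common variation without
  producing near-monomorphic columns that would mostly test the QC filter
  rather than the statistic.

An ordinal-trait generator (`simulate_ordinal_gwas()`) extends the same
linear predictor through a proportional-odds link. It is an extension for
exercising the ordinal test path, not part of the case-control design, and
is documented as such.

## Evaluation

`run_study()` scores each replicate by the **detection probability**
(captured fraction of true causal SNPs, counting the union of all
discovered sets; false positives do not reduce it) and **power** (all
causal SNPs captured). `power <= dprob` always holds and is asserted.
Per-replicate seeds derive from the master seed, so results are independent
of evaluation order.

The comparator is a **stepwise logistic baseline** that shares the exact
selection driver -- same thresholds, tie policy, restart rule -- and differs
only in the conditional test: the joint Wald test (df = 2) of the
candidate's two genotype dummies added to a logistic model of the selected
SNPs' dummies, with non-convergence or fully aliased dummies recorded as
p = 1. The Wald form was a deliberate design choice over a likelihood-ratio
test, for two reasons. First, it is what classical stepwise-logistic
software applies to fitted coefficients, so it is the procedure a
practitioner's "stepwise logistic regression" actually runs. Second, it
carries the failure mode that motivates the CMH route in the first place:
with near-empty genotype cells the coefficient standard errors inflate and
the Wald statistic collapses (the Hauck-Donner effect), pushing p toward 1
even for real signals. A likelihood-ratio version is largely immune to that
collapse; in our replicate studies it tracks the CMH procedure closely,
which says something useful about LRT-based selection but no longer
represents the baseline whose sparse-cell fragility is under study.

## What the tests do and do not show

The simulated conditions carry Hardy-Weinberg and linkage equilibrium,
independent null SNPs, and a correctly specified multiplicative effect.
Real cohorts violate all of these -- LD between markers, population
structure, genotyping artefacts, effect heterogeneity -- so passing
simulation checks demonstrates correctness of the machinery and its
comparative behaviour under the stated model, not field performance. The
QC layer (MAF $\ge$ 1%, call rate $\ge$ 95%, $r^2 \le 0.5$ sliding-window
pruning over 50-SNP windows, strict inequalities, earlier SNP of a
correlated pair kept) covers the standard preprocessing for real panels,
but imputation, covariate adjustment and relatedness are out of scope.

Monte-Carlo problem sizes in the checks are package choices balancing
resolution against runtime: 2000 replicates of 50 SNPs at $n = 2000$ for
the null-calibration band, $10^6$ prospective subjects for prevalence
recovery, $2 \times 10^5$ for coefficient recovery, and 100 replicates per
MAF (50 in the summary script) for the detection-probability comparison at
panel size 100. Under the null the prevalence is set to 0.5 in those runs
-- with no genetic effects the trait is independent of every genotype, so
the choice is distributionally irrelevant and halves the rejection-sampling
cost.

## Known limitations

* Strata keys are burden sums; weighted or risk-score stratification is out
  of scope.
* No LD-aware simulation: the generator cannot reproduce detection
  probabilities for correlated panels.
* P-values along the stepwise path are not adjusted for selection; the
  thresholds play that role, as is conventional for stepwise testing.
* The full-cross scheme is exponential in the conditioning-set size by
  design; it exists for small sets and for validating the MAC scheme
  against it.
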