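Package: cmhstep
Title: Stepwise Generalized Cochran-Mantel-Haenszel Tests for Joint SNP Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint identification of multiple SNPs associated with a categorical
    trait by a stepwise procedure built on the generalized Cochran-Mantel-Haenszel
    (CMH) statistic for stratified I x J x K contingency tables. Supports general
    association, mean-score and correlation tests; stratification of the
    conditioning SNP set either by the full genotype cross or by a capped
    sum-of-minor-allele-counts (MAC) scheme that keeps the stratum count bounded
    at genome-wide scale; forward/backward stepwise selection of disjoint SNP
    sets; a case-control simulator under a multiplicative-odds penetrance model
    with retrospective sampling; power and detection-probability evaluation
    against a stepwise logistic baseline; genotype file readers with the usual
    MAF, call-rate and LD-pruning quality-control filters; and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
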