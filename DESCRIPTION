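Package: snpcohort
Title: Case-Control SNP Association, Gene-Environment Interaction, and
    Cardiovascular Survival Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for small candidate-gene case-control and
    prospective cohort studies of coronary artery disease. Implements
    Hardy-Weinberg testing (chi-square and exact enumeration), case-control
    odds ratios with Woolf confidence intervals under dominant, additive,
    recessive and allele-level inheritance contrasts, logistic-regression
    adjustment, EM haplotype frequency estimation with D-prime/r-squared
    linkage disequilibrium and Gabriel-style block detection, additive and
    multiplicative gene-environment interaction measures (RERI, AP, synergy
    index, multiplicative synergy index) with asymmetric MOVER and
    delta-method confidence intervals from 4x2 tables, Kaplan-Meier and
    log-rank survival analysis over truncated follow-up horizons, and a
    seeded synthetic cohort generator emulating the design of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
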