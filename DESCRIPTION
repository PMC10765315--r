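Package: targetmr
Title: Cis-Mendelian Randomization for Drug-Target Prioritization with
    Correlated Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization from GWAS
    summary statistics using cis protein quantitative trait loci
    (cis-pQTLs) as correlated instruments. Implements instrument
    construction by p-value filtering and greedy linkage-disequilibrium
    clumping, Wald-ratio and generalized-least-squares inverse-variance
    weighted estimators with fixed or multiplicative random effects,
    correlation-adjusted MR-Egger, principal-components IVW, Steiger
    directionality filtering, a sensitivity battery with a
    three-criterion robustness verdict, false-discovery-rate control,
    phenome-wide scans with beneficial/adverse classification,
    approximate-Bayes-factor colocalization, sample-size-weighted
    meta-regression of gestational biomarker trajectories, and a
    summary-statistics simulator with known linkage disequilibrium and
    causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
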