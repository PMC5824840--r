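Package: comolq
Title: Joint cis-eQTL and cis-meQTL Mapping, Co-Localization, and Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of genetic effects on gene
    expression and DNA methylation in cis. Implements covariate-adjusted
    cis-QTL scans with adaptive permutations and beta-distribution-adjusted
    empirical P-values, Storey q-values, lead-SNP selection, pairwise
    linkage-disequilibrium utilities (r-squared, LD score, greedy pruning),
    selection of candidate eProbe-CpG pairs sharing an associated SNP,
    Bayesian co-localization with approximate Bayes factors and
    QTL-count-derived priors including internal empirical calibration of
    the shared-causal prior, and causal analyses on an overlap panel:
    partial correlation after genotype residualization, Sobel mediation
    tests under SNP-methylation-expression and SNP-expression-methylation
    models, direction-of-effect summaries, opposite-direction secondary
    CpG search, and conditional secondary-signal scans. A synthetic-data
    module simulates dosage genotypes with block LD together with
    expression and methylation phenotypes under known causal structures
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    vcfR
Config/testthat/edition: 3
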