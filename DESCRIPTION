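Package: ssrpopgen
Title: Population Genetics of Diploid Microsatellite (SSR) Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of diploid codominant microsatellite
    (SSR) genotype data: reading and writing GENEPOP and wide-table
    formats, genotyping-error quality control from replicate runs,
    detection and contraction of identical or near-identical multilocus
    genotypes (clones), probability-of-identity and marker
    informativeness statistics, per-population diversity statistics
    (allelic richness by rarefaction, heterozygosities, inbreeding
    coefficients with bootstrap confidence intervals, Hardy-Weinberg
    permutation tests), among-group differentiation (GST, G''ST, Jost's
    D) with permutation significance, Evanno delta-K model selection
    from Bayesian clustering log-probabilities, TreeMix microsatellite
    input export, Monte-Carlo cross-validated population assignment,
    and a Balding-Nichols style simulator of structured SSR data sets
    with clones, scoring error and missingness for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
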