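Package: rvburden
Title: Rare-Variant Gene-Set Burden Analysis for Extreme-Phenotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end rare-variant gene-set burden analysis for small
    case-control whole-genome-sequencing cohorts with extreme phenotypes,
    as used to study schizophrenia expression in 22q11.2 deletion syndrome.
    Prioritizes high-quality rare variants into loss-of-function, damaging
    missense and splicing-regulatory categories with a priori exclusion of
    the intact 22q11.2 region and chromosome X; computes percent-normalized
    per-subject gene-set burdens with one-sided t tests, a screening rule
    and a joint multivariate Hotelling T-squared stage; estimates
    ratio-of-means effect sizes and Cohen's d with noncentral-t power
    projections; scores polygenic risk with association p-value threshold
    sweeps and negative-control bins; and tests conservation-restricted
    long intergenic noncoding RNA burden. A synthetic-cohort generator
    emulates the study's statistical structure so the whole pipeline is
    testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
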