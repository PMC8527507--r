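Package: mtmim
Title: Multitrait Multiple Interval Mapping for Biparental RIL Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantitative trait locus (QTL) analysis for
    recombinant inbred line (RIL) populations evaluated in multi-environment
    trials. Provides genotype filtering and linkage-map construction from
    HapMap-format SNP calls with error-tolerant hidden Markov model genotype
    probabilities, REML mixed-model analysis of lattice-design trials
    (adjusted means, Cullis generalized heritability, genetic
    variance-covariance structure selection, GGE biplots), and a multitrait
    multiple interval mapping (MT-MIM) engine using Haley-Knott regression
    with resampling-based genome-wide score-statistic thresholds, seemingly
    unrelated regression pruning of environment-specific effects, LOD-1.5
    support intervals and per-trial explained variances. A synthetic-data
    generator emulates a biparental RIL population and lattice trial design
    so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, LinkageDisequilibrium, Software
RoxygenNote: 7.3.3
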