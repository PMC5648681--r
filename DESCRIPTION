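Package: qstfst
Title: Quantitative-Genetic and Neutral Divergence Analysis for
    Common-Garden Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing quantitative-trait divergence (Q_ST) with
    neutral molecular divergence (F_ST) among populations studied in
    common-garden breeding designs.  Implements nested half-sib variance
    component estimation and Q_ST, multiallelic Weir-Cockerham theta from
    microsatellite genotypes (GENEPOP format supported), Markov-chain exact
    Hardy-Weinberg tests, genotypic linkage-disequilibrium permutation tests,
    ANCOVA-style trait comparisons with Tukey HSD and least-square means,
    offspring size-number trade-off analysis, Colwell
    predictability/constancy/contingency statistics for seasonal
    environmental series, and Mantel-style Spearman permutation comparison of
    Q_ST and F_ST distance matrices.  Includes simulators for genotypes
    (Balding-Nichols), hierarchical breeding experiments, and monthly climate
    series, so the full pipeline can be exercised and validated on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
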