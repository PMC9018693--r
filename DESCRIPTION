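Package: epiamplicon
Title: Epiallele Analysis of Targeted Deep Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of targeted deep bisulfite amplicon
    sequencing at single-molecule resolution. Generates synthetic paired-end
    bisulfite reads from configurable epiallele mixtures (with incomplete
    conversion, inappropriate conversion and sequencing error, plus a fully
    unmethylated spike-in control), merges and quality-filters read pairs,
    calls per-molecule binary CpG methylation profiles (epialleles), builds
    sample-by-epiallele count tables with rarefaction and ordination
    (Bray-Curtis PCoA or PCA), computes epiallele-class distributions and
    mean/per-CpG methylation, derives relative expression from qPCR Ct values
    (2^-dCt), and correlates methylation and epiallele abundances with
    expression (one-way ANOVA, pairwise t tests, Pearson correlation
    heatmaps). An end-to-end pipeline driver with reproducible seeds ties the
    stages together.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    biomformat,
    jsonlite,
    stats,
    utils,
    vegan,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
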