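Package: haplodot
Title: Regulatory Variance and Dosage Outlier Testing from
    Haplotype-Level Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-gene genetic regulatory variability (the standard
    deviation of the latent log allelic fold change, V^G) from population-scale
    haplotype-aggregated allele-specific expression counts under a
    binomial-logit-normal model, with parametric-bootstrap confidence
    intervals.  Provides the matching per-sample dosage outlier test with
    Benjamini-Hochberg FDR control, screening of false-positive-prone genes
    via exact Clopper-Pearson bounds on cohort outlier rates, rare-variant
    enrichment (relative risk) among outlier individual-gene pairs,
    cross-population comparison of variance estimates by confidence-interval
    overlap, readers and writers for haplotype count formats, and a
    ground-truth simulator covering every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
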