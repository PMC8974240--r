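Package: panelgwas
Title: Mixed-Model GWAS, QTL Region Calling, and Trait Networks for Inbred Diversity Panels
Version: 0.1.0
Authors@R: person("Panel", "GWAS Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of structured inbred
    diversity panels such as the USDA rice minicore: a Balding-Nichols style
    synthetic panel simulator with planted quantitative trait loci (QTL) and a
    known trait causal graph, REML variance components and best linear unbiased
    predictions (BLUPs) from replicated phenotypes, per-marker mixed linear
    model association scans with centered-genotype kinship and principal
    component covariates, a rule-based QTL region caller with cross-panel
    merging and effect-sign splitting, cross-trait QTL co-location and
    peak-allele pivot analysis, candidate gene proximity annotation, and
    Gaussian Bayesian network learning of trait relationships under
    growth-stage blacklists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
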