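Package: boaGBLUP
Title: Breed-of-Origin Aware Genomic Prediction for Crossbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how SNP-allele effects for crossbred performance
    depend on the parental breed an allele was inherited from. Implements
    breed-of-origin assignment of alleles in three-way crossbred animals from
    a purebred haplotype library, construction of breed-specific partial
    genomic relationship matrices, a multi-trait GBLUP animal model with
    purebred and crossbred traits (BOA model) fitted by average-information
    REML, back-solving of breed-of-origin SNP-allele effects from genomic
    breeding values, linkage-disequilibrium block segmentation via Fisher's
    exact test on gametic counts with per-block genetic-variance
    decomposition, and a focal-locus (major-gene) haplotype and
    allele-substitution analysis. A gene-dropping simulator of diverged
    purebred lines and their terminal three-way cross provides fully
    labelled synthetic data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
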