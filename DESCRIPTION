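Package: phenoscreen
Title: Design and Analysis of Pooled Phenotype-Sequencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for phenotype sequencing: identifying the genes that cause a
    selected phenotype directly from pooled sequencing of independent mutant
    strains. Implements a generative model of mutant strains conditioned on
    passing a phenotype screen (conditional Poisson with truncated multinomial
    sampling, uniform or variable gene sizes with GC-biased mutability), a
    binomial model of SNP-call false negatives and false positives under
    library pooling, Poisson-tail gene scoring with Bonferroni correction and
    yield-at-FDR estimation, experiment design and cost optimization for
    library- and tag-pooling, a VCF-based pipeline that filters, annotates and
    ranks candidate causal genes, and a synthetic-data generator producing toy
    genomes, mutant strains and pooled VCFs with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    BiocGenerics,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
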