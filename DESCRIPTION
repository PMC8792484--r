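Package: hybridzone
Title: Hybrid-Zone Introgression Analysis for Reduced-Representation SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for detecting and characterising
    interspecific hybridization from ddRADseq SNP genotypes and mitochondrial
    haplotype alignments.  Covers genotype quality filtering, nuclear and
    mitochondrial diversity statistics (heterozygosity, nucleotide diversity,
    Tajima's D, Ramos-Onsins & Rozas R2 with fixed-S coalescent null
    distributions), pairwise Weir-Cockerham FST and Jost's D, PCA and k-means
    clustering with BIC model selection, maximum-likelihood hybrid index and
    interspecific heterozygosity with triangle-plot generation classes,
    ABBA-BABA (Patterson's D) introgression tests with block-jackknife
    significance, a PCA-correlation outlier-locus scan with
    Benjamini-Hochberg FDR control, folded site-frequency-spectrum
    construction, and a seeded two-species hybrid-zone simulator that
    exercises the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    MASS,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
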