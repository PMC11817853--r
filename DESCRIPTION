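Package: karyoscan
Title: Detection and Genotyping of Polymorphic Chromosomal Inversions from
    SNP Genotype Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate chromosomal inversions in diploid SNP
    genotype data and genotypes individuals for the alternative arrangements.
    Implements windowed local principal component analysis with
    window-to-window covariance distances, classical multidimensional scaling
    with Tukey-fence outlier windows, linkage-disequilibrium block detection,
    three-cluster karyotype calling from PC1 with diagnostic SNPs,
    heterozygosity-by-karyotype diagnostics, per-site Weir-Cockerham FST scans
    between homokaryotypes, and Fisher exact GO-term enrichment of genes in
    candidate regions. Includes a coalescent-free cohort simulator
    (hierarchical Balding-Nichols lineages plus inversion loci with suppressed
    recombination) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
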