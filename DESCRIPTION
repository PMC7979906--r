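Package: radclone
Title: Population Structure and Clonality Analysis for Reduced-Representation
    SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-genotyping population-genomic analysis for reduced
    representation (RAD-Seq) SNP panels in partly clonal plant collections.
    Reads and filters biallelic genotype matrices from VCF (call rate, one
    SNP per locus, minor allele frequency), computes identity-by-state
    distances with UPGMA clustering and Patterson-scaled genotype PCA,
    detects graft-propagated (clonal) individuals through a pairwise
    conserved-heterozygosity statistic, and estimates population statistics
    (observed/expected heterozygosity, Fis, Weir-Cockerham Fst, Patterson
    f3/f4 with block-jackknife standard errors). A truth-tracked synthetic
    genotype simulator (Balding-Nichols divergence, admixture, clonal
    duplicates with allelic dropout) provides a self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
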