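Package: segqtl
Title: Expression QTL Mapping in Recombinant Haploid Crosses Genotyped from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for RNA-seq-driven genetics of haploid two-parent segregant
    libraries. Infers parental origin at polymorphic sites from expressed-variant
    calls (quality filtering, isolated-discordance correction, haplotype-block
    imputation, marker collapsing), quantifies strand-specific sense and antisense
    expression over coding sequences with strain-specific coordinate liftover,
    maps expression and growth QTLs with missing-genotype randomized forests,
    kinship-eigenvector population-structure covariates, selection-frequency
    scoring and a shared-permutation empirical FDR, and performs downstream
    hotspot detection (Poisson bins), cis/trans classification, effect
    directionality, candidate-regulator voting and gene-pair-orientation
    enrichment. A synthetic-cross simulator generates genomes, recombinant
    segregants, counts, read placements and genotype calls with the statistical
    structure the pipeline assumes, so the whole analysis runs without external
    data. Growth parameters (efficiency, AUC, maximum specific growth rate, lag
    and doubling time) are extracted from optical-density time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
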