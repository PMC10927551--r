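Package: paleokaryo
Title: Karyotype Evolution, Ancestral Chromosome Reconstruction and
    Whole-Genome Duplication Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Chromosome-scale tools for studying whole-genome duplication
    (WGD) in early vertebrate evolution. Simulates karyotype evolution under
    duplication, triplication, fusion, fission, gene loss, translocation and
    small-scale duplication with full ground truth; reconstructs ancestral
    chromosomes from cross-species homology via reciprocal best hits and
    chi-squared enrichment with FDR control; computes gene-retention profiles
    and the 'overlapping ratio' (OR) to call ohnologous and orthologous
    chromosomes and per-ancestral-chromosome multiplicity; classifies rooted
    gene trees as compatible with one or two shared WGD rounds; and classifies
    post-WGD duplicate expression fates and accessible-chromatin genomic
    context.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    limma,
    methods,
    phangorn,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
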