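Package: sweepmap
Title: Pooled-Segregant Mapping, Insertion Genotyping and Expression
    Quantification for Flowering-Time Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map a causal locus from pooled extreme-phenotype
    segregant sequencing using a LOESS-smoothed allele-frequency difference
    (delta-f) scan, to genotype a known structural insertion from
    junction-spanning short reads with a core-mapping read rule, to quantify
    per-nucleotide expression profiles, exon usage and delta-delta-Ct
    relative expression, and to date a shared insertion allele with a
    neutral mutation clock.  A synthetic-data module simulates F2/F3
    segregant pools, breakpoint reads, coverage profiles, Ct tables and
    expression-phenotype pairs so every stage can be exercised and
    validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
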