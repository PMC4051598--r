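Package: poolsweep
Title: Two-Strain Pooled-Sequencing Divergence and Selective-Sweep Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genome analysis of two laboratory strains of common
    origin under divergent selection, from pooled-sequencing allele
    frequencies. Provides outgroup-based polarization of alleles into old
    (ancestral, outgroup-matching) and new (derived) classes, per-strain
    fixation classification and shared/unique fixed-allele tallies with the
    associated chi-square and binomial excess tests, variant quality
    filtering on central and flanking PHRED scores, read depth and variant
    frequency, sliding-window F_ST from population heterozygosities with
    between-strain nucleotide diversity (d_xy) and extreme-window flagging,
    amino-acid-change annotation of coding variants with per-arm gene burden
    tables and consensus ORF extraction, and a Wright-Fisher two-strain
    simulator with optional directional selection that generates fully
    ground-truthed synthetic studies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
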