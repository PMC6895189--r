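Package: seqbug
Title: Pileup-Driven Single-Nucleotide Correction of Genome Assemblies
Version: 0.1.0
Authors@R:
    person("seqbug", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and corrects single-nucleotide errors in draft genome
    assemblies from per-base read-alignment metrics (bam-readcount style
    pileups). A reference base is replaced by the most frequent read base when
    its support is at most one fifth of that base's support, subject to
    coverage (10-200x) and indel-fraction (10%) eligibility filters.
    Corrections are projected through Ensembl-dialect GTF gene models into
    codons and classified as synonymous, non-synonymous, stop or start
    changes; corrected sites can be cross-validated against an independent
    individual's pileup. Auxiliary evolutionary-site utilities scan
    multi-species protein alignments for focal-lineage unique substitutions,
    compute root-to-tip divergences from gene trees, and aggregate
    multi-signal evidence of adaptation. A fully specified synthetic-data
    generator with known ground truth supports end-to-end testing without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ape,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
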