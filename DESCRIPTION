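Package: straingraph
Title: Strain-Aware De Bruijn Graph Assembly for Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A de Bruijn graph assembler for shotgun metagenomes that
    preserves strain-level variation. Builds a canonical-k-mer graph from
    FASTA/FASTQ reads, prunes sequencing-error artefacts (tips, low
    coverage), and extracts contigs with three traversal strategies: a
    coverage-guided consensus walk with a collective-coverage bubble rule
    that also emits local variants as GFA2/FASTG sequence graphs; a
    subtractive walk that decomposes shared coverage into one contig per
    variant using a normalized coverage-change statistic and linearly
    interpolated coverage subtraction; and plain unitig extraction. A
    companion graph walk reconstructs per-strain contigs from a sequence
    graph plus a segment-to-strain mapping-score table, and a synthetic
    community simulator (reference genomes, mutated strains, abundance-
    weighted error-bearing reads) supports end-to-end evaluation with
    alignment-free genome-fraction and N50 metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
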