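Package: lncclass
Title: Positional Classification and Comparative Analysis of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates candidate long non-coding RNA transcripts relative to
    protein-coding gene models and runs the comparative analyses built on that
    annotation. Transcripts are classified as intergenic, intronic, overlapped
    or UTR-related; intergenic transcripts are assigned a neighbor gene with
    distance, facing gene end and sense/antisense orientation (strand inferred
    from splice-site dinucleotides where unknown). Downstream layers score
    per-interval conservation from per-base tracks against length-matched
    un-transcribed control regions, account for overlap with external ncRNA
    catalogs, test neighbor-gene GO over-representation with the conservative
    EASE variant of Fisher's exact test, and measure cross-species conservation
    of ncRNA/neighbor-gene pairs by symbol and by sequence similarity. A seeded
    synthetic-data generator produces genomes, gene models, planted ncRNAs with
    known classes and biases, conservation tracks, GO annotations and species
    trios so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
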