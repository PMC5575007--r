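Package: arnscan
Title: Scanning Bacterial RNAs for Hfq Distal-Site (ARN)X Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating A-rich (ARN)X motifs -- the repeated
    adenine/purine/any-base triplets bound by the distal face of the
    bacterial RNA chaperone Hfq -- in small regulatory RNAs and mRNA
    5' regions.  Generates permuted degenerate pattern sets (ARN triplets
    interleaved with bounded non-functional triplets and single-nucleotide
    gaps), scans sequences exhaustively, merges overlapping matches into
    motif regions, searches sRNA/mRNA pairs for minimal complementary seed
    regions (seven consecutive base pairs, or six pairs plus a one-nucleotide
    bulge plus two pairs), and maps motif regions against secondary-structure
    elements, 3' poly(U) tails, 5' UTR windows and homolog conservation.
    A synthetic-data generator with full ground truth makes every stage
    testable without external sequence retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
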