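Package: mirsig
Title: Positional GC Signature Analysis for Plant MicroRNA Biogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composition statistics and positional nucleotide-bias analysis
    for plant microRNA precursors and mature miRNAs: per-segment GC content
    of hairpin precursors, position-specific nucleotide and dinucleotide
    frequency matrices, a dinucleotide-preserving (Euler-path) shuffle null,
    and classification of miRNA families as conserved or less-conserved from
    dicot/monocot co-occurrence. Encodes the flexible 21-nt positional GC
    signature of plant miRNAs (G/C preference at positions 8-9 and 18-19,
    A/U preference at positions 5, 7, 10 and 15, with looser flanking
    preferences) and scores sequences against it; analyses target-site
    complementarity on mRNAs with background-normalized positional GC
    tracks; quantifies collapsed small-RNA reads on precursors by exact
    matching with size/GC-band/signature class summaries; ranks and designs
    artificial miRNAs (star strand with canonical 19-bp duplex geometry and
    2-nt 3' overhangs, backbone embedding). A synthetic-data module
    generates every input at desk scale for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
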