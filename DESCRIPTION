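Package: exonproxy
Title: Isoform Quantification from 3'-Terminal Exon Proxies in Short-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Makes 3'-biased short-read RNA-seq (notably 10X Chromium single-cell
    data) splicing-isoform-sensitive for isoforms that differ at their 3' ends.
    Computes the 3'-terminal genomic regions that uniquely distinguish groups of
    transcripts of one gene (exon "proxies"), rewrites the gene annotation so each
    proxy becomes a separately countable pseudo-gene, counts read placements over
    proxies, normalizes to transcripts per million (TPM) and isoform fractions,
    grafts a terminal exon onto a related genome's gene model after locating it by
    local alignment, and validates the proxy approach with a 3'-biased read
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Config/testthat/edition: 3
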