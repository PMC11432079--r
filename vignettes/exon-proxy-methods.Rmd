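---
title: "Quantifying 3'-distinguishable splicing isoforms with exon proxies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3'-distinguishable splicing isoforms with exon proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonproxy)
```

## The problem

Short-read 3'-tag RNA-seq libraries (10X Chromium and similar protocols)
sequence a single ~91 bp cDNA read per captured molecule, drawn from near the
transcript's 3' end. This defeats full-length isoform quantification, but for
isoforms that differ **precisely at their 3' ends** it is an opportunity: each
molecule's read lands in the very region that distinguishes the isoforms.

The canonical example is the thyroid hormone receptor alpha gene *THRA*. Its
two major splicing isoforms share exons 1–9a; *THRA1* reads through into an
extended terminal exon ("exon 9b", chr17:40,089,334–40,092,627 after trimming
at the exon 9a boundary), while *THRA2* splices from exon 9a to a distinct
downstream terminal exon ("exon 10", chr17:40,093,020–40,093,867). Because the
ratio of the T3-responsive THRα1 to the dominant-negative THRα2 tunes the
thyroid-hormone response of a cell, the isoform fraction is the biologically
meaningful statistic, and it can be read off a 3'-tag library — provided the
annotation is rewritten so a gene-level quantifier counts the two terminal
regions separately.

exonproxy automates that annotation surgery and the associated quantification
and validation steps.

## The method

1. **Partition** a gene's transcripts into isoform groups — explicitly
   (`partition_transcripts(gene, groups = list(THRA1 = ..., THRA2 = ...))`) or
   automatically by identical 3'-terminal exon (`auto = TRUE`).
2. **Terminal region** per group: the strand-aware union over member
   transcripts of the 3'-most exon(s), the annotated 3'UTR and the stop codon.
   On the "+" strand the 3'-most exon is the one with the largest end, on "−"
   the smallest start. The UTR is included because tag reads pile up there.
3. **Proxy region** (`distinguishing_region()`): the terminal region minus the
   merged exonic bases of *every* transcript outside the group — other groups
   and unassigned transcripts alike. Trimming the read-through exon 9b at the
   exon 9a boundary is the special case of this subtraction; using the full
   exonic union generalizes it to arbitrary annotations. Empty results (the
   groups are not 3'-distinguishable) are an error naming the colliding
   group; results below `min_length` (default 100 bp, warning below 300 bp)
   are rejected, since a ~91 bp read needs room to land uniquely.
4. **Annotation rewrite** (`split_gene()`): each proxy becomes a pseudo-gene —
   fresh `gene_id`/`transcript_id`, `gene_name` set to the group name, biotype
   inherited from the source gene so default biotype filters still count it.
   The original gene keeps its identity and all exonic bases outside the
   proxies; exon records straddling a proxy boundary have their coordinates
   edited. Exonic bases are conserved exactly and disjointly (checked
   internally). All records of other genes pass through byte-identically.
5. **Quantification** (`count_reads()`, `tpm()`, `sum_group_tpm()`,
   `isoform_fraction()`): featureCounts-like counting (≥ 1 bp overlap of any
   aligned block, one count per read, unstranded by default, reads bridging
   two groups dropped and logged), TPM normalization, and per-sample isoform
   fractions.
6. **Cross-species port** (`locate_exon()`, `graft_terminal_exon()`): when a
   related genome lacks the second isoform's annotation, the terminal exon is
   located in a syntenic locus slice by full Smith–Waterman local alignment
   over both strands and grafted onto the related gene model as a new terminal
   exon, with optional 3'UTR and stop-codon records.

## Interval semantics

All coordinates are 1-based inclusive (GTF convention); BED import/export
converts to 0-based half-open at the boundary. Interval union and subtraction
use closed-interval semantics: book-ended intervals (gap 0) merge, a 1 bp gap
does not. Region arithmetic requires a single seqname and an explicit strand —
`"."` is accepted only on auxiliary records. The test suite checks `merge` and
`subtract` against a per-base bitmap oracle on 1,000 randomized instances and
asserts `|A ∪ B| + |A ∩ B| = |A| + |B|`.

## Which abundance scale for fractions?

`isoform_fraction()` accepts any abundance matrix, and the choice matters:

* **3'-tag data** (one read per UMI-collapsed molecule): proxy **counts** are
  molecule counts; use them directly. Length normalization would be wrong
  here — reads concentrate near the 3' end regardless of proxy length, so
  dividing by proxy length (3,294 bp for exon 9b vs 848 bp for exon 10) would
  skew the ratio.
* **Bulk full-length data**: reads per region scale with region length, so
  proxy counts are normalized by proxy length to TPM before taking fractions
  (the exon-proxy analogue of transcript-level TPM). Note `tpm()` normalizes
  over the features present in the supplied table, not the whole
  transcriptome; proxy-only tables are therefore on their own TPM scale, and
  shorter features inflate TPM for equal counts — visible when comparing
  proxy-based with full-transcript-length TPM values.

Group-level transcript TPM (`sum_group_tpm()`) mirrors the full-length route:
a group's abundance is the sum of its member transcripts' TPM.

## The simulator and what it does (not) show

`simulate_reads()` is the package's validation instrument. It draws each
molecule's isoform from a molar mixture and places a single 91 bp read per
molecule:

* `bias = "threeprime"` (default): the read's 3'-end distance from the
  transcript 3' end follows an exponential of scale `bias_scale` (default
  400 bp), truncated to the transcript. The default scale is a deliberately
  simple stand-in for the empirical 10X coverage decay: most reads fall
  within a few hundred bases of the polyadenylation site, i.e. inside any
  proxy of a few hundred bp or more.
* `bias = "uniform"`: bulk-like fragmentation; molecules are sampled
  proportionally to molar fraction × effective length and starts are uniform,
  the regime in which TPM-normalized proxy counts equal molar fractions in
  expectation.

Reads are projected through the exon structure to genomic coordinates, with
junction-crossing reads emitted as multiple blocks (BED12). Fixtures come from
`make_fixture()`: `"thra-like"` (a configurable toy gene with the shared /
read-through / distinct-terminal-exon topology), `"thra"` (a synthetic
reconstruction of the human THRA locus whose 3'-end entries carry the
published chr17 coordinates; the upstream shared exons are synthetic), and
`"random"` for validator sweeps. `make_gorilla_fixture()` builds the
cross-species scenario: all of its *sequence* is random — only the coordinate
geometry follows the published locus — so alignment results on it validate the
locator's mechanics, not primate genomics.

The simulator deliberately omits sequencing errors, multimapping, barcode/UMI
collisions and PCR duplication. Passing its tests therefore shows that the
interval arithmetic, annotation rewrite, counting policy and normalization are
correct and self-consistent — not that a specific real library is free of
mapping artifacts. On real data those concerns are delegated to the upstream
aligner and UMI deduplication (the package assumes one record per molecule for
tag data, multimappers excluded via BAM flags).

Two quantitative behaviors are worth knowing:

* Under the 3' bias, a fraction `exp(-proxy_length / bias_scale)` of a
  group's molecules fall upstream of its proxy and are lost. With the default
  scale this loss is a few percent per group and nearly cancels between
  groups of comparable proxy length; the residual bias on the estimated
  fraction for the default fixture is ~0.003, well inside the ±0.01 recovery
  check at 100,000 reads. Groups with very different proxy lengths and short
  proxies would see a larger systematic offset.
* The consistency check over the 1k/10k/100k depth ladder uses the mean
  absolute error across 12 replicate simulations per depth (fixed seed
  schedule). A single draw per depth would fail to be monotone by chance with
  non-trivial probability even for a correct implementation; averaging makes
  the monotone decrease a sharp test at these problem sizes while keeping the
  whole ladder around a million simulated reads.

## Numerical and design choices

* **Counting policy**: ≥ 1 bp overlap, one count per read per region set,
  unstranded — featureCounts-style defaults, logged with the run. Fractional
  or multi-overlap counting is intentionally not offered.
* **Alignment scoring**: BLASTN-like defaults (match +2, mismatch −3, gap
  open −5, gap extend −2; a gap of length L costs `open + L·extend`);
  `min_score` defaults to 0.8 × the maximum attainable score, below which a
  "not found" result is returned rather than an error. Ties are broken
  deterministically: higher score, then lower start, then "+" before "−".
  Equivalence with a full-matrix Gotoh dynamic program is asserted in the
  tests.
* **Terminal-exon ties**: annotations in which several exons share the
  extreme 3' boundary contribute all such exons to the terminal region.
* **Graft geometry**: the 3'UTR record is emitted immediately 3' of the donor
  exon and non-overlapping with it, and the stop codon is an explicit option
  (`"none"`, `"inside"`, `"downstream"`), because published custom loci of
  this kind are ambiguous about whether the UTR shares the donor boundary
  base. `hit_to_donor(shift_start = 1)` covers the common off-by-one between
  a raw alignment hit and the curated exon start.
* **Pseudo-gene ids**: `<source_gene_id>-<GROUP>` by default, `gene_name` the
  bare group name; both configurable, and re-splitting an already split
  annotation is an error (or an explicit no-op), never a double split.
* **GTF dialect**: Ensembl attribute syntax, attribute strings preserved
  verbatim so untouched records round-trip byte-identically; the writer
  orders records deterministically (seqname, start, gene < transcript < exon
  < other, end) and a written file is a fixed point of read→write. GFF3 and
  chromosome aliasing are out of scope.

## Problem sizes used in the checks

The shipped checks run at desk scale: interval properties on 1,000 randomized
instances over a 10 kb universe; mixture recovery at 100,000 reads (±0.01);
the depth ladder at 1k/10k/100k × 12 replicates; proxy-vs-transcript agreement
on three mixtures × 100,000 uniform-coverage reads (mean |Δ| < 0.02);
alignment oracle comparisons on targets up to 2 kb. Applying the pipeline to
real datasets (reference-scale GTFs, Cell Ranger/STAR/StringTie outputs) uses
the same code paths but is not exercised by the test suite; running those
external tools is explicitly out of scope.

## Limitations

* Only 3'-end-distinguishable isoforms are addressed — no 5' or internal
  (cassette) exon discrimination, and no novel-isoform discovery.
* The TPM denominator is table-local; absolute proxy TPM values are not
  comparable with genome-wide TPM, only the within-gene fractions are.
* The locator is a full dynamic program intended for locus slices (it is
  quadratic); whole-genome homology search belongs to a seeded aligner.
* UMI deduplication, cell filtering and clustering are upstream concerns; the
  package consumes alignments/tables, not raw FASTQ.
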