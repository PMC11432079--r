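#' Transcript model
#'
#' A transcript as an ordered set of exons on one seqname and strand, with
#' optional CDS/UTR/stop-codon records. Exons must be non-overlapping within
#' the transcript; the spliced length is the sum of exon widths.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param seqname,strand Location; strand `"+"` or `"-"`.
#' @param exons `GRanges` of exons (any order; stored sorted by coordinate).
#' @param cds,utr5,utr3,stop_codon Optional `GRanges` of auxiliary records.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seqname, strand, exons,
                             cds = NULL, utr5 = NULL, utr3 = NULL,
                             stop_codon = NULL) {
  empty <- GenomicRanges::GRanges()
  if (is.null(cds)) cds <- empty
  if (is.null(utr5)) utr5 <- empty
  if (is.null(utr3)) utr3 <- empty
  if (is.null(stop_codon)) stop_codon <- empty
  if (length(exons) > 0L) {
    exons <- BiocGenerics::sort(strip_seqinfo(exons))
    if (!IRanges::isDisjoint(IRanges::ranges(exons)))
      stop("transcript ", transcript_id, " has overlapping exons")
    sq <- unique(as.character(GenomeInfoDb::seqnames(exons)))
    if (length(sq) != 1L || sq != seqname)
      stop("transcript ", transcript_id, " exons must all lie on ", seqname)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         seqname = seqname, strand = strand, exons = exons,
         cds = cds, utr5 = utr5, utr3 = utr3, stop_codon = stop_codon),
    class = "transcript_model"
  )
}

#' Gene model
#'
#' A gene as a named list of [transcript_model] objects sharing one seqname
#' and strand.
#'
#' @param gene_id,gene_name,biotype Identifiers (name/biotype may be `NA`).
#' @param seqname,strand Location.
#' @param transcripts Named list of `transcript_model` objects.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name, seqname, strand, transcripts,
                       biotype = NA_character_) {
  for (tx in transcripts) {
    if (tx$seqname != seqname || tx$strand != strand)
      stop("all transcripts of gene ", gene_id,
           " must share its seqname and strand")
  }
  structure(
    list(gene_id = gene_id, gene_name = gene_name, biotype = biotype,
         seqname = seqname, strand = strand, transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) on %s(%s), %d transcript(s)\n",
              x$gene_id, if (is.na(x$gene_name)) "-" else x$gene_name,
              x$seqname, x$strand, length(x$transcripts)))
  for (tx in x$transcripts) {
    cat(sprintf("  %s: %d exon(s), spliced length %d bp\n",
                tx$transcript_id, length(tx$exons), spliced_length(tx)))
  }
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) on %s(%s): %d exon(s), %d bp spliced\n",
              x$transcript_id, x$gene_id, x$seqname, x$strand,
              length(x$exons), spliced_length(x)))
  invisible(x)
}

#' Spliced length of a transcript
#'
#' @param tx A `transcript_model`.
#' @return Sum of exon widths in bp.
#' @export
spliced_length <- function(tx) {
  if (length(tx$exons) == 0L) return(0L)
  sum(BiocGenerics::width(tx$exons))
}

#' 3'-most exon(s) of a transcript
#'
#' Strand-aware: on `"+"` the exon(s) with the largest end coordinate, on
#' `"-"` those with the smallest start. Annotations with several exons sharing
#' the extreme 3' boundary (fragmented or trans-spliced entries) return all of
#' them.
#'
#' @param tx A `transcript_model`.
#' @return `GRanges` of terminal exon(s).
#' @export
terminal_exon <- function(tx) {
  if (length(tx$exons) == 0L)
    stop("transcript ", tx$transcript_id, " has no exons")
  if (tx$strand == "+") {
    boundary <- max(BiocGenerics::end(tx$exons))
    tx$exons[BiocGenerics::end(tx$exons) == boundary]
  } else if (tx$strand == "-") {
    boundary <- min(BiocGenerics::start(tx$exons))
    tx$exons[BiocGenerics::start(tx$exons) == boundary]
  } else {
    stop("terminal exon requires an explicit strand")
  }
}

#' Merged exonic bases of transcripts
#'
#' Union of exon, CDS, UTR and stop-codon intervals over the given
#' transcripts, merged into a disjoint set.
#'
#' @param transcripts A list of `transcript_model` objects (or a single one).
#' @return Merged `GRanges` (empty if no transcript has exons).
#' @export
exonic_bases <- function(transcripts) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  parts <- lapply(transcripts, function(tx) {
    strip_list <- lapply(list(tx$exons, tx$cds, tx$utr5, tx$utr3,
                              tx$stop_codon), strip_seqinfo)
    do.call(c, strip_list)
  })
  all <- do.call(c, unname(parts))
  if (is.null(all) || length(all) == 0L) return(GenomicRanges::GRanges())
  merge_intervals(all)
}

#' Genomic span of a gene model
#'
#' @param gene A `gene_model`.
#' @return Length-1 `GRanges` covering all exonic bases.
#' @export
gene_span <- function(gene) {
  bases <- exonic_bases(gene$transcripts)
  if (length(bases) == 0L)
    stop("gene ", gene$gene_id, " has no exonic bases")
  range(bases)
}
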