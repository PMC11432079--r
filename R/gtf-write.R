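#' Write an Ensembl-dialect GTF file
#'
#' Emits the record table of a [read_gtf()] annotation (or a compatible
#' data.frame) as a 9-column tab-separated GTF with LF line endings and a
#' deterministic record order: seqname, then start, then feature rank
#' (gene < transcript < exon < everything else), then end. Attribute strings
#' are written verbatim, so records that were not edited round-trip
#' byte-identically; a file written by this function and re-read is a fixed
#' point of the read/write cycle.
#'
#' @param x A `gtf_annotation` or a records data.frame (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  rec <- if (inherits(x, "gtf_annotation")) x$records else x
  lines <- character(0)
  if (nrow(rec) > 0L) {
    o <- order(rec$seqname, rec$start, feature_rank(rec$feature), rec$end,
               rec$feature, rec$attributes, method = "radix")
    rec <- rec[o, , drop = FALSE]
    lines <- paste(rec$seqname, rec$source, rec$feature,
                   format(rec$start, scientific = FALSE, trim = TRUE),
                   format(rec$end, scientific = FALSE, trim = TRUE),
                   rec$score, rec$strand, rec$frame, rec$attributes,
                   sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

feature_rank <- function(feature) {
  r <- match(feature, c("gene", "transcript", "exon"))
  r[is.na(r)] <- 4L
  r
}

# Build one GTF record row compatible with the read_gtf() record table.
# `attrs` is a named list written in the given order (Ensembl syntax).
make_gtf_record <- function(seqname, source, feature, start, end, strand,
                            attrs, score = ".", frame = ".") {
  data.frame(
    seqname = seqname, source = source, feature = feature,
    start = as.numeric(start), end = as.numeric(end), score = score,
    strand = strand, frame = frame,
    attributes = format_gtf_attrs(attrs),
    line = NA_integer_,
    gene_id = if ("gene_id" %in% names(attrs)) attrs$gene_id else NA_character_,
    transcript_id = if ("transcript_id" %in% names(attrs)) attrs$transcript_id else NA_character_,
    gene_name = if ("gene_name" %in% names(attrs)) attrs$gene_name else NA_character_,
    gene_biotype = if ("gene_biotype" %in% names(attrs)) attrs$gene_biotype else NA_character_,
    orphan = FALSE,
    stringsAsFactors = FALSE
  )
}

format_gtf_attrs <- function(attrs) {
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  paste(sprintf('%s "%s";', names(attrs), unlist(attrs)), collapse = " ")
}

#' Convert a gene model to GTF records
#'
#' Emits gene, transcript and exon records (plus CDS/UTR/stop-codon records
#' where present on the model) for one [gene_model()], e.g. a grafted gene
#' model that did not originate from a GTF file.
#'
#' @param gene A `gene_model`.
#' @param source Value for the GTF `source` column.
#' @return A records data.frame accepted by [write_gtf()].
#' @export
gene_model_records <- function(gene, source = "exonproxy") {
  span <- gene_span(gene)
  base_attrs <- list(gene_id = gene$gene_id)
  if (!is.na(gene$gene_name)) base_attrs$gene_name <- gene$gene_name
  if (!is.na(gene$biotype)) base_attrs$gene_biotype <- gene$biotype
  rows <- list(make_gtf_record(gene$seqname, source, "gene",
                               BiocGenerics::start(span), BiocGenerics::end(span),
                               gene$strand, base_attrs))
  for (tx in gene$transcripts) {
    tx_span <- range(strip_seqinfo(tx$exons))
    tattrs <- base_attrs
    tattrs$transcript_id <- tx$transcript_id
    # Ensembl order: gene_id, transcript_id, then names
    tattrs <- tattrs[c("gene_id", "transcript_id",
                       setdiff(names(tattrs), c("gene_id", "transcript_id")))]
    rows[[length(rows) + 1L]] <- make_gtf_record(
      gene$seqname, source, "transcript",
      BiocGenerics::start(tx_span), BiocGenerics::end(tx_span),
      gene$strand, tattrs)
    exons <- tx$exons
    ranks <- exon_rank(exons, gene$strand)
    for (i in seq_along(exons)) {
      eattrs <- tattrs
      eattrs$exon_number <- ranks[i]
      rows[[length(rows) + 1L]] <- make_gtf_record(
        gene$seqname, source, "exon",
        BiocGenerics::start(exons)[i], BiocGenerics::end(exons)[i],
        gene$strand, eattrs)
    }
    aux <- list(CDS = tx$cds, three_prime_utr = tx$utr3,
                five_prime_utr = tx$utr5, stop_codon = tx$stop_codon)
    for (ft in names(aux)) {
      gr <- aux[[ft]]
      for (i in seq_along(gr)) {
        rows[[length(rows) + 1L]] <- make_gtf_record(
          gene$seqname, source, ft,
          BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i],
          gene$strand, tattrs,
          frame = if (ft == "CDS") "0" else ".")
      }
    }
  }
  do.call(rbind, rows)
}

# 1-based exon rank in transcription order (5' -> 3', strand-aware).
exon_rank <- function(exons, strand) {
  if (strand == "-") {
    rank(-BiocGenerics::start(exons), ties.method = "first")
  } else {
    rank(BiocGenerics::start(exons), ties.method = "first")
  }
}

#' Write intervals as BED6
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open coordinates
#' at the boundary.
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @param names Feature names (BED column 4); defaults to `names(x)` or `"."`.
#' @param scores BED column 5 (default 0).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path, names = NULL, scores = 0L) {
  if (is.null(names)) {
    names <- if (!is.null(base::names(x))) base::names(x) else rep(".", length(x))
  }
  lines <- paste(as.character(GenomeInfoDb::seqnames(x)),
                 format(BiocGenerics::start(x) - 1L, scientific = FALSE, trim = TRUE),
                 format(BiocGenerics::end(x), scientific = FALSE, trim = TRUE),
                 names, scores, as.character(BiocGenerics::strand(x)),
                 sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write blocked read placements as BED12
#'
#' One BED12 line per read; spliced reads become multi-block lines
#' (`blockCount`/`blockSizes`/`blockStarts`), the standard exchange format for
#' split alignments.
#'
#' @param reads A `GRangesList` (one element per read, blocks in genomic
#'   order) such as the `reads` component of [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  nm <- base::names(reads)
  if (is.null(nm)) nm <- paste0("read", seq_along(reads))
  df <- as.data.frame(reads)
  o <- order(df$group, df$start)
  df <- df[o, , drop = FALSE]
  runs <- rle(df$group)
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1L
  cs <- df$start - 1L                      # 0-based block starts
  chrom_start <- cs[first]
  chrom_end <- df$end[last]
  strand <- as.character(df$strand)[first]
  strand[strand == "*"] <- "."
  g <- rep.int(seq_along(runs$lengths), runs$lengths)
  sizes <- split(df$end - df$start + 1L, g)
  rel_starts <- split(cs - rep.int(chrom_start, runs$lengths), g)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- paste(as.character(df$seqnames)[first],
                 fmt(chrom_start), fmt(chrom_end),
                 nm[runs$values], 0L, strand,
                 fmt(chrom_start), fmt(chrom_start), "0,0,0",
                 runs$lengths,
                 vapply(sizes, function(x)
                   paste0(paste(x, collapse = ","), ","), character(1)),
                 vapply(rel_starts, function(x)
                   paste0(paste(x, collapse = ","), ","), character(1)),
                 sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
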