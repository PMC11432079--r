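#' Read an Ensembl-dialect GTF file
#'
#' Parses a 9-column tab-separated GTF file (Ensembl attribute syntax:
#' `key "value";` pairs) into a flat record table plus hierarchical gene
#' models assembled by `gene_id`/`transcript_id`. Attribute strings are kept
#' verbatim so that untouched records round-trip byte-identically through
#' [write_gtf()]; the only normalizations applied on write are comment
#' removal and deterministic record ordering.
#'
#' Exon-level features lacking a `transcript_id` are reported as orphans via a
#' warning and excluded from the gene models, but retained in the record table
#' (they are not dropped silently).
#'
#' @param path Path to a GTF file.
#' @return An object of class `gtf_annotation`: a list with
#'   * `records`: data.frame of all feature rows (`seqname`, `source`,
#'     `feature`, `start`, `end`, `score`, `strand`, `frame`, `attributes`,
#'     plus extracted `gene_id`, `transcript_id`, `gene_name`, `gene_biotype`,
#'     the source `line` number and an `orphan` flag);
#'   * `genes`: named list of `gene_model` objects (see [gene_model()]).
#' @seealso [write_gtf()], [gene_model()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    rec <- empty_gtf_records()
    return(new_gtf_annotation(rec))
  }
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated columns, found %d",
                 line_no[bad], nf[bad]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 4]))
  end <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", line_no[bad]))
  }
  if (any(start < 1) || any(end < start)) {
    bad <- which(start < 1 | end < start)[1]
    stop(sprintf("malformed GTF line %d: invalid interval [%s, %s]",
                 line_no[bad], m[bad, 4], m[bad, 5]))
  }
  if (!all(m[, 7] %in% c("+", "-", "."))) {
    bad <- which(!(m[, 7] %in% c("+", "-", ".")))[1]
    stop(sprintf("malformed GTF line %d: invalid strand '%s'", line_no[bad], m[bad, 7]))
  }
  rec <- data.frame(
    seqname = m[, 1], source = m[, 2], feature = m[, 3],
    start = start, end = end, score = m[, 6], strand = m[, 7],
    frame = m[, 8], attributes = m[, 9],
    line = line_no, stringsAsFactors = FALSE
  )
  rec$gene_id <- gtf_attr(rec$attributes, "gene_id")
  rec$transcript_id <- gtf_attr(rec$attributes, "transcript_id")
  rec$gene_name <- gtf_attr(rec$attributes, "gene_name")
  rec$gene_biotype <- gtf_attr(rec$attributes, "gene_biotype")
  if (anyNA(rec$gene_id)) {
    bad <- which(is.na(rec$gene_id))[1]
    stop(sprintf("malformed GTF line %d: missing gene_id attribute", rec$line[bad]))
  }
  txlevel <- c("transcript", "exon", "CDS", "five_prime_utr",
               "three_prime_utr", "stop_codon", "start_codon")
  rec$orphan <- rec$feature %in% setdiff(txlevel, "transcript") &
    is.na(rec$transcript_id)
  if (any(rec$orphan)) {
    warning(sprintf("%d orphan feature record(s) without transcript_id (line %s); %s",
                    sum(rec$orphan),
                    paste(rec$line[rec$orphan], collapse = ", "),
                    "excluded from gene models but retained in the record table"))
  }
  new_gtf_annotation(rec)
}

empty_gtf_records <- function() {
  data.frame(
    seqname = character(), source = character(), feature = character(),
    start = numeric(), end = numeric(), score = character(),
    strand = character(), frame = character(), attributes = character(),
    line = integer(), gene_id = character(), transcript_id = character(),
    gene_name = character(), gene_biotype = character(), orphan = logical(),
    stringsAsFactors = FALSE
  )
}

new_gtf_annotation <- function(records) {
  structure(
    list(records = records, genes = assemble_gene_models(records)),
    class = "gtf_annotation"
  )
}

#' @export
print.gtf_annotation <- function(x, ...) {
  cat(sprintf("<gtf_annotation> %d records, %d genes\n",
              nrow(x$records), length(x$genes)))
  if (length(x$genes)) {
    nm <- vapply(x$genes, function(g) {
      sprintf("%s (%s): %d transcript(s)", g$gene_id,
              if (is.na(g$gene_name)) "-" else g$gene_name,
              length(g$transcripts))
    }, character(1))
    cat(paste0("  ", utils::head(nm, 10), collapse = "\n"), "\n")
    if (length(nm) > 10) cat(sprintf("  ... and %d more\n", length(nm) - 10))
  }
  invisible(x)
}

# Extract the value of `key "value"` from raw GTF attribute strings.
# Vectorized over `attrs`; returns NA where the key is absent.
gtf_attr <- function(attrs, key) {
  pat <- sprintf('(^|; ?|;)[ ]*%s +"([^"]*)"', key)
  mm <- regmatches(attrs, regexec(pat, attrs))
  vapply(mm, function(g) if (length(g) >= 3L) g[3] else NA_character_,
         character(1))
}

# Assemble hierarchical gene/transcript models from the flat record table.
assemble_gene_models <- function(rec) {
  rec <- rec[!rec$orphan, , drop = FALSE]
  if (nrow(rec) == 0L) return(structure(list(), names = character()))
  gene_ids <- unique(rec$gene_id)
  genes <- lapply(gene_ids, function(gid) {
    g <- rec[rec$gene_id == gid, , drop = FALSE]
    sq <- unique(g$seqname)
    if (length(sq) != 1L)
      stop("gene ", gid, " spans multiple sequences: ", paste(sq, collapse = ", "))
    st <- setdiff(unique(g$strand), ".")
    if (length(st) > 1L)
      stop("gene ", gid, " has features on both strands")
    if (length(st) == 0L) st <- "."
    gname <- stats::na.omit(g$gene_name)[1]
    if (is.null(gname) || length(gname) == 0L) gname <- NA_character_
    biotype <- stats::na.omit(g$gene_biotype)[1]
    if (is.null(biotype) || length(biotype) == 0L) biotype <- NA_character_
    tx_ids <- unique(stats::na.omit(g$transcript_id))
    transcripts <- lapply(tx_ids, function(tid) {
      t <- g[!is.na(g$transcript_id) & g$transcript_id == tid, , drop = FALSE]
      transcript_model(
        transcript_id = tid, gene_id = gid, seqname = sq, strand = st,
        exons = rows_to_granges(t[t$feature == "exon", ], sq, st),
        cds = rows_to_granges(t[t$feature == "CDS", ], sq, st),
        utr5 = rows_to_granges(t[t$feature == "five_prime_utr", ], sq, st),
        utr3 = rows_to_granges(t[t$feature == "three_prime_utr", ], sq, st),
        stop_codon = rows_to_granges(t[t$feature == "stop_codon", ], sq, st)
      )
    })
    names(transcripts) <- tx_ids
    gene_model(gene_id = gid, gene_name = gname, biotype = biotype,
               seqname = sq, strand = st, transcripts = transcripts)
  })
  names(genes) <- gene_ids
  genes
}

rows_to_granges <- function(rows, seqname, strand) {
  if (nrow(rows) == 0L) {
    return(GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  strand = character()))
  }
  gr <- genomic_intervals(seqname, rows$start, rows$end, strand)
  BiocGenerics::sort(gr)
}
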