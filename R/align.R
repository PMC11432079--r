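#' Locate a query sequence in a target by Smith-Waterman local alignment
#'
#' Searches both strands of each target sequence (the reverse strand by
#' aligning the reverse complement of the query against the forward target,
#' so coordinates are always reported on the forward coordinate system with a
#' strand flag). Intended for desk-scale searches such as finding the homolog
#' of a terminal exon in a syntenic locus slice of a related genome; it is a
#' full local alignment, not a seeded heuristic, so supply a locus slice, not
#' a whole genome.
#'
#' Target sequence names of the form `"chr5:41856001-41860000"` (the samtools
#' faidx region convention) are interpreted as 1-based slices and hits are
#' reported in the coordinates of the parent sequence.
#'
#' @param query A `DNAString`, character string, or path handled by
#'   `as_dna()`; length >= 50 nt for a meaningful search.
#' @param target A `DNAStringSet`, a named character vector, or a FASTA path.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (BLASTN-like defaults `+2/-3/-5/-2`; gap of length L scores
#'   `gap_open + L * gap_extend`).
#' @param min_score Minimum alignment score to call a hit; default 0.8 times
#'   the maximum attainable score (`match * query length`). A best score below
#'   this yields a "not found" result, not an error.
#' @return An object of class `exon_hit`: list with `found` (logical), `best`
#'   (1-row data.frame: `seqname`, `start`, `end`, `strand`, `score`,
#'   `identity`, `query_start`, `query_end`) and `hits` (per target x strand,
#'   sorted by score then position; the runner-up list).
#' @export
locate_exon <- function(query, target,
                        scoring = list(match = 2, mismatch = -3,
                                       gap_open = -5, gap_extend = -2),
                        min_score = NULL) {
  query <- as_dna(query)
  if (length(query) < 50L)
    warning("query is shorter than 50 nt; local hits may be spurious")
  targets <- as_dna_set(target)
  if (is.null(min_score)) min_score <- 0.8 * scoring$match * length(query)

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  qfwd <- query
  qrev <- Biostrings::reverseComplement(query)
  qlen <- length(query)

  rows <- list()
  for (i in seq_along(targets)) {
    nm <- base::names(targets)[i]
    reg <- parse_fasta_region(nm)
    for (st in c("+", "-")) {
      q <- if (st == "+") qfwd else qrev
      al <- Biostrings::pairwiseAlignment(
        pattern = q, subject = targets[[i]], type = "local",
        substitutionMatrix = submat,
        gapOpening = abs(scoring$gap_open),
        gapExtension = abs(scoring$gap_extend))
      s_start <- BiocGenerics::start(Biostrings::subject(al))
      s_end <- BiocGenerics::end(Biostrings::subject(al))
      p_start <- BiocGenerics::start(Biostrings::pattern(al))
      p_end <- BiocGenerics::end(Biostrings::pattern(al))
      if (st == "-") {   # convert query span out of revcomp space
        tmp <- p_start
        p_start <- qlen - p_end + 1L
        p_end <- qlen - tmp + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = reg$seqname,
        start = reg$offset + s_start,
        end = reg$offset + s_end,
        strand = st,
        score = Biostrings::score(al),
        identity = Biostrings::pid(al),
        query_start = p_start, query_end = p_end,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, rows)
  # deterministic tie-break: best score, then lowest start, then "+" first
  hits <- hits[order(-hits$score, hits$seqname, hits$start,
                     hits$strand, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  found <- nrow(hits) > 0L && hits$score[1] >= min_score
  structure(list(found = found,
                 best = if (found) hits[1, , drop = FALSE] else NULL,
                 hits = hits, min_score = min_score, scoring = scoring),
            class = "exon_hit")
}

#' @export
print.exon_hit <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<exon_hit> not found (best score %s < min_score %.1f)\n",
                if (nrow(x$hits)) format(x$hits$score[1]) else "NA", x$min_score))
    return(invisible(x))
  }
  b <- x$best
  cat(sprintf("<exon_hit> %s:%s-%s(%s) score %.0f, identity %.1f%%, query %d-%d\n",
              b$seqname, format(b$start, big.mark = ","),
              format(b$end, big.mark = ","), b$strand, b$score, b$identity,
              b$query_start, b$query_end))
  invisible(x)
}

#' Best hit as a GRanges donor interval
#'
#' Convenience bridge from [locate_exon()] to [graft_terminal_exon()].
#'
#' @param hit An `exon_hit`.
#' @param shift_start Bases to add to the hit start (e.g. `+1` to skip a
#'   stop-codon base kept out of the grafted exon); default 0.
#' @return Length-1 `GRanges`.
#' @export
hit_to_donor <- function(hit, shift_start = 0L) {
  if (!inherits(hit, "exon_hit") || !hit$found)
    stop("no hit to convert")
  b <- hit$best
  genomic_intervals(b$seqname, b$start + shift_start, b$end, b$strand)
}

as_dna <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single query sequence")
    return(x[[1]])
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) != 1L) stop("query FASTA must contain a single sequence")
    return(set[[1]])
  }
  Biostrings::DNAString(x)
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(list(x))
    base::names(out) <- "target"
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  out <- Biostrings::DNAStringSet(x)
  if (is.null(base::names(out)))
    base::names(out) <- paste0("target", seq_along(out))
  out
}

# "chr5:41856001-41860000" -> seqname chr5, offset 41856000; anything else ->
# the name itself with offset 0.
parse_fasta_region <- function(nm) {
  if (is.null(nm) || is.na(nm)) return(list(seqname = "target", offset = 0))
  nm <- sub("\\s.*$", "", nm)
  m <- regexec("^(.+):([0-9]+)-([0-9]+)$", nm)
  g <- regmatches(nm, m)[[1]]
  if (length(g) == 4L) {
    list(seqname = g[2], offset = as.numeric(g[3]) - 1)
  } else {
    list(seqname = nm, offset = 0)
  }
}
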