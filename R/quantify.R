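#' Count read placements over proxy regions
#'
#' featureCounts-style assignment: a read counts for a region set if at least
#' `min_overlap` bases of any of its aligned blocks fall inside any interval
#' of the region; each read is counted at most once per region set. Reads
#' whose blocks touch the regions of two different groups (impossible while
#' the regions are disjoint exon unions, but a spliced read can in principle
#' bridge them) are dropped and reported. Counting is unstranded by default,
#' matching featureCounts defaults.
#'
#' @param placements Read placements: a `GRangesList` (one element per read,
#'   one range per aligned block) or a `GRanges` (one unspliced read per
#'   range). An optional `sample` metadata column on the outer object assigns
#'   reads to samples/cells; otherwise a single sample `"sample1"` is assumed.
#' @param regions Named list of `proxy_region` objects (see [proxy_regions()])
#'   or a named `GRanges` (names identify groups; several intervals may share
#'   a name). Regions of different groups must be disjoint.
#' @param min_overlap Minimum overlapping bases (default 1).
#' @param ignore_strand Count regardless of strand (default `TRUE`).
#' @return Integer matrix of counts, regions x samples.
#' @export
count_reads <- function(placements, regions, min_overlap = 1L,
                        ignore_strand = TRUE) {
  region_gr <- proxies_to_granges(regions)
  grp <- base::names(region_gr)
  ugrp <- unique(grp)
  # disjointness across groups is a hard precondition
  self <- GenomicRanges::findOverlaps(region_gr, region_gr,
                                      ignore.strand = ignore_strand)
  off <- S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)
  if (any(off))
    stop("regions of different groups overlap; proxy regions must be disjoint")

  if (inherits(placements, "simulated_reads")) placements <- placements$reads
  single <- methods::is(placements, "GRanges")
  n_reads <- length(placements)
  samp <- S4Vectors::mcols(placements)$sample
  if (is.null(samp)) samp <- rep("sample1", n_reads)
  samp <- as.character(samp)
  usamp <- unique(samp)

  hits <- GenomicRanges::findOverlaps(placements, region_gr,
                                      minoverlap = min_overlap,
                                      ignore.strand = ignore_strand)
  q <- S4Vectors::queryHits(hits)
  g <- grp[S4Vectors::subjectHits(hits)]
  pair <- !duplicated(paste(q, g, sep = "\r"))
  q <- q[pair]; g <- g[pair]
  multi <- unique(q[duplicated(q)])
  if (length(multi) > 0L) {
    message(length(multi),
            " read(s) overlapped regions of more than one group and were dropped")
    keep <- !(q %in% multi)
    q <- q[keep]; g <- g[keep]
  }
  counts <- matrix(0L, nrow = length(ugrp), ncol = length(usamp),
                   dimnames = list(ugrp, usamp))
  if (length(q) > 0L) {
    tab <- table(factor(g, levels = ugrp), factor(samp[q], levels = usamp))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Transcripts per million (TPM)
#'
#' Per sample: `rate_i = count_i / length_i`, `TPM_i = 1e6 * rate_i / sum(rate)`.
#' The denominator is the set of features present in the supplied table, not
#' the whole transcriptome — proxy-only tables therefore give TPM on the scale
#' of the proxies alone (and shorter feature lengths inflate TPM for equal
#' counts). Columns with all-zero counts are returned as `NA`.
#'
#' @param counts Non-negative numeric matrix, features x samples.
#' @param lengths Named numeric vector of feature lengths in bp covering all
#'   rows of `counts`; all lengths must be positive.
#' @return Numeric matrix of TPM values with the shape of `counts`; each
#'   non-degenerate column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("'counts' must have feature rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L)
    stop("no length supplied for feature(s): ", paste(missing, collapse = ", "))
  len <- lengths[rownames(counts)]
  bad <- names(len)[is.na(len) | len <= 0]
  if (length(bad) > 0L)
    stop("feature length must be positive; offending feature(s): ",
         paste(bad, collapse = ", "))
  rate <- counts / len
  tot <- colSums(rate)
  out <- sweep(rate, 2L, tot, "/") * 1e6
  out[, tot == 0] <- NA_real_
  out
}

#' Sum transcript-level TPM over isoform groups
#'
#' The grouping step of transcript-level quantification: a group's abundance
#' is the sum of its member transcripts' TPM (e.g. summing the TPM of the
#' exon-9b-containing variants for THRA1). Members missing from the table are
#' treated as zero with a warning.
#'
#' @param transcript_tpm Numeric matrix, transcripts x samples, rownames are
#'   transcript ids.
#' @param groups List of `isoform_group` objects, an `isoform_partition`, or a
#'   named list of transcript-id vectors.
#' @return Numeric matrix, groups x samples.
#' @export
sum_group_tpm <- function(transcript_tpm, groups) {
  transcript_tpm <- as.matrix(transcript_tpm)
  if (inherits(groups, "isoform_partition")) groups <- groups$groups
  if (length(groups) && inherits(groups[[1]], "isoform_group")) {
    nm <- vapply(groups, `[[`, character(1), "name")
    groups <- lapply(groups, `[[`, "transcript_ids")
    names(groups) <- nm
  }
  membership <- matrix(0, nrow = length(groups), ncol = nrow(transcript_tpm),
                       dimnames = list(names(groups), rownames(transcript_tpm)))
  for (nm in names(groups)) {
    ids <- groups[[nm]]
    absent <- setdiff(ids, rownames(transcript_tpm))
    if (length(absent) > 0L)
      warning("group '", nm, "': transcript(s) absent from the table treated as 0: ",
              paste(absent, collapse = ", "))
    membership[nm, intersect(ids, rownames(transcript_tpm))] <- 1
  }
  membership %*% transcript_tpm
}

#' Isoform fractions from group-level abundances
#'
#' Per sample, each group's share of the summed abundance of all groups (for
#' two groups, the second row is the "isoform 2 share of the total" statistic).
#' Works on any abundance scale (TPM for length-normalized bulk data, UMI
#' counts for 3'-tag data) since the fraction is invariant to rescaling all
#' groups by a common factor. Samples with zero total are returned as `NA`
#' and flagged.
#'
#' @param group_abundance Numeric matrix, groups x samples (at least 2 groups).
#' @return Numeric matrix of fractions in `[0, 1]` whose columns sum to 1;
#'   all-`NA` columns where the total is 0, with the flagged samples in
#'   `attr(, "undefined_samples")`.
#' @export
isoform_fraction <- function(group_abundance) {
  m <- as.matrix(group_abundance)
  if (nrow(m) < 2L) stop("isoform fractions need at least 2 groups")
  tot <- colSums(m)
  out <- sweep(m, 2L, tot, "/")
  undef <- !is.na(tot) & tot == 0
  out[, undef] <- NA_real_
  attr(out, "undefined_samples") <- colnames(m)[undef]
  out
}

#' Agreement between two isoform-fraction tables
#'
#' Compares fractions estimated two ways on matched samples (e.g. from exon
#' proxies versus from transcript-level quantification) by absolute
#' difference, with a pass/fail verdict against a tolerance.
#'
#' @param frac_a,frac_b Fraction matrices (groups x samples) with matching
#'   group and sample names.
#' @param tolerance Maximum acceptable mean absolute difference (default
#'   0.02).
#' @return An object of class `proxy_agreement`: per-sample absolute
#'   differences, `mean_abs_diff`, `max_abs_diff`, `tolerance` and `pass`.
#' @export
proxy_agreement <- function(frac_a, frac_b, tolerance = 0.02) {
  a <- as.matrix(frac_a); b <- as.matrix(frac_b)
  if (is.null(colnames(a)) || is.null(colnames(b)) ||
      !setequal(colnames(a), colnames(b)))
    stop("sample mismatch between the two fraction tables")
  if (!setequal(rownames(a), rownames(b)))
    stop("group mismatch between the two fraction tables")
  b <- b[rownames(a), colnames(a), drop = FALSE]
  d <- abs(a - b)
  per_sample <- apply(d, 2L, max)
  structure(list(per_sample = per_sample,
                 abs_diff = d,
                 mean_abs_diff = mean(d, na.rm = TRUE),
                 max_abs_diff = max(d, na.rm = TRUE),
                 tolerance = tolerance,
                 pass = mean(d, na.rm = TRUE) <= tolerance),
            class = "proxy_agreement")
}

#' @export
print.proxy_agreement <- function(x, ...) {
  cat(sprintf("<proxy_agreement> mean |diff| = %.4f, max |diff| = %.4f, tolerance %.3f: %s\n",
              x$mean_abs_diff, x$max_abs_diff, x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Read placements from BED or BAM
#'
#' BED6/BED12 files are imported via rtracklayer (BED12 blocks become one
#' range per block); BAM files via GenomicAlignments with secondary
#' alignments (multimappers) excluded.
#'
#' @param path Path to a `.bed` or `.bam` file.
#' @return A `GRangesList`, one element per read.
#' @export
read_placements <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
        !requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the GenomicAlignments and Rsamtools packages")
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE))
    aln <- GenomicAlignments::readGAlignments(path, param = param)
    return(GenomicAlignments::grglist(aln))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(S4Vectors::mcols(gr)$blocks)) {
    out <- rtracklayer::blocks(gr)
  } else {
    out <- split(gr, seq_along(gr))
    base::names(out) <- S4Vectors::mcols(gr)$name
  }
  out
}

#' Read a transcript-level TPM table from TSV
#'
#' Accepts a wide table (one id column named `transcript_id`, `t_name` or
#' `ID` — otherwise the first column — plus one numeric column per sample,
#' the shape of a StringTie-style abundance export) or a long table with
#' columns `transcript_id`, `sample`, `TPM`. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, transcripts x samples.
#' @export
read_transcript_tpm <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  if (all(c("transcript_id", "sample", "tpm") %in% lc)) {
    tid <- df[[which(lc == "transcript_id")[1]]]
    smp <- df[[which(lc == "sample")[1]]]
    val <- df[[which(lc == "tpm")[1]]]
    tl <- unique(tid); sl <- unique(smp)
    m <- matrix(0, nrow = length(tl), ncol = length(sl),
                dimnames = list(tl, sl))
    m[cbind(match(tid, tl), match(smp, sl))] <- val
    return(m)
  }
  idc <- which(lc %in% c("transcript_id", "t_name", "id"))[1]
  if (is.na(idc)) idc <- 1L
  num <- vapply(df, is.numeric, logical(1))
  num[idc] <- FALSE
  if (!any(num)) stop("no numeric sample columns found in ", path)
  m <- as.matrix(df[, num, drop = FALSE])
  rownames(m) <- as.character(df[[idc]])
  m
}

#' Write a quantification table as TSV with a provenance header
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @param what Feature-column header (default `"feature"`).
#' @param comments Character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(x, path, what = "feature", comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# exonproxy %s", as.character(utils::packageVersion("exonproxy"))),
           if (length(comments)) paste0("# ", comments))
  writeLines(hdr, con, sep = "\n")
  writeLines(paste(c(what, colnames(x)), collapse = "\t"), con, sep = "\n")
  body <- apply(cbind(rownames(x), apply(x, 2L, as.character)), 1L,
                paste, collapse = "\t")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a quantification table written by [write_quant_tsv()]
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, features x samples.
#' @export
read_quant_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
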