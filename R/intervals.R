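#' Construct a set of stranded genomic intervals
#'
#' Coordinates are 1-based and inclusive on both ends (GTF convention), so an
#' interval of `start == end` has length 1. Intervals are represented as
#' [GenomicRanges::GRanges] throughout the package.
#'
#' @param seqname Sequence (chromosome) name; length 1 or `length(start)`.
#' @param start,end Integer vectors, 1-based inclusive; `end >= start`.
#' @param strand `"+"`, `"-"`, or `"."`/`"*"` (unstranded). Region arithmetic
#'   requires an explicit strand.
#' @return A `GRanges` object.
#' @examples
#' genomic_intervals("chr17", c(40093020, 40093137), c(40093613, 40093867), "+")
#' @export
genomic_intervals <- function(seqname, start, end, strand = "+") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(end) != length(start))
    stop("'start' and 'end' must have the same length")
  if (any(start < 1))
    stop("interval start coordinates must be >= 1 (1-based inclusive)")
  if (any(end < start))
    stop("interval end must be >= start")
  strand <- ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
}

# Contract check shared by the region operations: one seqname, one explicit
# strand. Returns the (unchanged) input invisibly.
check_region_set <- function(x, what = "intervals") {
  if (!methods::is(x, "GRanges"))
    stop("'", what, "' must be a GRanges object")
  if (length(x) == 0L) return(invisible(x))
  sq <- unique(as.character(GenomeInfoDb::seqnames(x)))
  if (length(sq) != 1L)
    stop("'", what, "' must lie on a single sequence, found: ",
         paste(sq, collapse = ", "))
  st <- unique(as.character(BiocGenerics::strand(x)))
  if (length(st) != 1L)
    stop("'", what, "' must share one strand, found: ",
         paste(st, collapse = ", "))
  if (st == "*")
    stop("region arithmetic requires an explicit strand ('+' or '-')")
  invisible(x)
}

# Rebuild a GRanges with seqinfo restricted to the levels in use, so that set
# operations between independently constructed objects do not warn about
# mismatched seqinfo.
strip_seqinfo <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(GenomeInfoDb::seqnames(x)),
    ranges = IRanges::ranges(x),
    strand = BiocGenerics::strand(x)
  )
}

#' Merge genomic intervals into a disjoint sorted union
#'
#' Returns the union of the input bases as a sorted, pairwise-disjoint set of
#' intervals. Overlapping and book-ended (gap of 0 bases) intervals are merged;
#' a 1-base gap is preserved (closed-interval union semantics).
#'
#' @param x A `GRanges` on a single seqname and explicit strand.
#' @return A sorted, disjoint `GRanges` covering exactly the union of `x`.
#' @examples
#' x <- genomic_intervals("chr17",
#'   c(40093020, 40093137, 40093020),
#'   c(40093613, 40093867, 40093867), "+")
#' merge_intervals(x)  # one interval: 40,093,020-40,093,867
#' @export
merge_intervals <- function(x) {
  check_region_set(x)
  if (length(x) == 0L) return(x)
  GenomicRanges::reduce(BiocGenerics::sort(strip_seqinfo(x)))
}

#' Subtract one interval set from another
#'
#' Returns the bases present in `a` and absent from `b`, merged and sorted.
#' Both sets must lie on the same seqname and strand.
#'
#' @param a,b `GRanges` on the same single seqname and explicit strand.
#' @return A sorted, disjoint `GRanges` with the bases of `a` not in `b`.
#' @examples
#' a <- genomic_intervals("chr1", 1, 100)
#' b <- genomic_intervals("chr1", 1, 40)
#' subtract_intervals(a, b)  # 41-100
#' @export
subtract_intervals <- function(a, b) {
  check_region_set(a, "a")
  check_region_set(b, "b")
  if (length(a) == 0L) return(a)
  if (length(b) == 0L) return(merge_intervals(a))
  if (as.character(GenomeInfoDb::seqnames(a)[1]) !=
      as.character(GenomeInfoDb::seqnames(b)[1]))
    stop("'a' and 'b' must lie on the same sequence")
  if (as.character(BiocGenerics::strand(a)[1]) !=
      as.character(BiocGenerics::strand(b)[1]))
    stop("'a' and 'b' must share the same strand")
  GenomicRanges::setdiff(merge_intervals(a), merge_intervals(b))
}

#' Total number of bases covered by an interval set
#'
#' @param x A `GRanges`.
#' @param merge Merge first so shared bases are counted once (default `TRUE`).
#' @return Integer number of bases.
#' @export
interval_bases <- function(x, merge = TRUE) {
  if (length(x) == 0L) return(0L)
  if (merge) x <- merge_intervals(x)
  sum(BiocGenerics::width(x))
}
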