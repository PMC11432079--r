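# Independent oracles used across the suite. These deliberately avoid the
# package's own interval/alignment code paths: interval operations are checked
# against per-base logical bitmaps, local alignment against a full-matrix
# Gotoh dynamic program, counting against a per-read brute-force scan.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# ---- per-base bitmap oracle --------------------------------------------------

bitmap_from_granges <- function(gr, universe) {
  v <- logical(universe)
  for (i in seq_along(gr)) v[start(gr)[i]:end(gr)[i]] <- TRUE
  v
}

bitmap_to_granges <- function(v, seqname = "chrX", strand = "+") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (!any(r$values)) return(GRanges())
  genomic_intervals(seqname, starts[r$values], ends[r$values], strand)
}

random_interval_set <- function(n, max_coord = 10000L, seqname = "chrX",
                                strand = "+") {
  s <- sample.int(max_coord, n, replace = TRUE)
  w <- sample.int(max(2L, max_coord %/% 20L), n, replace = TRUE)
  genomic_intervals(seqname, s, pmin(s + w - 1L, max_coord), strand)
}

# cheap boolean comparison for use inside large randomized loops (a single
# expectation on the failure count keeps the loops fast)
same_intervals <- function(got, want) {
  length(got) == length(want) &&
    all(start(got) == start(want)) &&
    all(end(got) == end(want))
}

expect_same_intervals <- function(got, want) {
  expect_equal(length(got), length(want))
  if (length(got) > 0) {
    expect_equal(start(got), start(want))
    expect_equal(end(got), end(want))
  }
}

# ---- full-matrix Smith-Waterman (Gotoh) oracle -------------------------------

# Affine-gap local alignment score; a gap of length L costs
# gap_open + L * gap_extend, the convention of the package's aligner.
sw_oracle_score <- function(query, target, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  q <- strsplit(as.character(query), "")[[1]]
  t <- strsplit(as.character(target), "")[[1]]
  n <- length(q); m <- length(t)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consume target)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in target (consume query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      sub <- if (q[i - 1] == t[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_string <- function(s, positions) {
  for (p in positions) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  s
}

# ---- brute-force overlap counting oracle -------------------------------------

# counts[group]: number of reads with >= 1 bp overlap between any block and
# any interval of the group; reads touching two groups dropped. Operates on
# plain numeric vectors per read so it shares no code with the implementation.
brute_force_counts <- function(reads, proxies) {
  df <- as.data.frame(reads)
  groups <- vapply(proxies, `[[`, character(1), "group_name")
  counts <- setNames(integer(length(groups)), groups)
  ivs <- lapply(proxies, function(p)
    cbind(start(p$intervals), end(p$intervals)))
  idx <- split(seq_len(nrow(df)), df$group)
  for (rid in idx) {
    hit <- character(0)
    for (k in seq_along(proxies)) {
      m <- ivs[[k]]
      ok <- FALSE
      for (q in seq_len(nrow(m))) {
        if (any(df$start[rid] <= m[q, 2] & df$end[rid] >= m[q, 1])) {
          ok <- TRUE
          break
        }
      }
      if (ok) hit <- c(hit, groups[k])
    }
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# ---- small annotated fixtures ------------------------------------------------

# Toy plus-strand gene with a shared exon, a read-through isoform P and a
# distinct-terminal-exon isoform Q (the worked proxy-subtraction geometry:
# shared exon 1001-1400, P reads through to 2000, Q ends in 2500-3000).
toy_pq_gene <- function() {
  txP <- transcript_model("P1", "TOY", "chr9", "+",
                          exons = genomic_intervals("chr9", 1001, 2000))
  txQ <- transcript_model("Q1", "TOY", "chr9", "+",
                          exons = genomic_intervals("chr9", c(1001, 2500),
                                                    c(1400, 3000)))
  gene_model("TOY", "TOY", "chr9", "+", list(P1 = txP, Q1 = txQ),
             biotype = "protein_coding")
}

# A bystander gene used to verify byte-preservation through split_gene.
make_gtf_lines_other_gene <- function() {
  c(
    'chr17\thavana\tgene\t39900000\t39901000\t.\t-\t.\tgene_id "NBR"; gene_name "NEIGHBOR"; gene_biotype "lincRNA";',
    'chr17\thavana\ttranscript\t39900000\t39901000\t.\t-\t.\tgene_id "NBR"; transcript_id "NBR.t1"; gene_name "NEIGHBOR";',
    'chr17\thavana\texon\t39900000\t39901000\t.\t-\t.\tgene_id "NBR"; transcript_id "NBR.t1"; exon_number "1";'
  )
}

write_toy_gtf <- function(path) {
  lines <- c(
    'chr1\ttest\tgene\t100\t900\t.\t+\t.\tgene_id "G1"; gene_name "GENE1"; gene_biotype "protein_coding";',
    'chr1\ttest\ttranscript\t100\t500\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; gene_name "GENE1";',
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; exon_number "1";',
    'chr1\ttest\texon\t400\t500\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1"; exon_number "2";',
    'chr1\ttest\ttranscript\t100\t900\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t2"; gene_name "GENE1";',
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t2"; exon_number "1";',
    'chr1\ttest\texon\t700\t900\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t2"; exon_number "2";'
  )
  writeLines(lines, path)
  path
}
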