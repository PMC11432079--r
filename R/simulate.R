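# Fixture construction and 3'-biased read simulation. The fixtures emulate the
# THRA-style 3'-end topology: isoforms share all exons up to a last common
# exon, after which one isoform reads through into an extended terminal exon
# while the other splices to a distinct downstream terminal exon.

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' simulations are reproducible without clobbering global randomness.
#'
#' @param seed Integer seed or `NULL` (no seeding).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = ""))
}

#' Build a THRA-like two-isoform gene fixture
#'
#' Constructs a synthetic annotated gene with the 3'-end topology that makes
#' exon-proxy quantification possible: isoform 1 reads through the last shared
#' exon into an extended terminal exon, isoform 2 splices from the last shared
#' exon to a distinct downstream terminal exon.
#'
#' Presets:
#' * `"thra-like"`: a small toy gene on `chrT` with configurable exon counts
#'   and widths (see parameters).
#' * `"thra"`: a synthetic reconstruction of the human THRA locus on chr17
#'   (plus strand) whose 3'-end coordinates equal the published exon 9b / exon
#'   10 annotation entries; shared upstream exons are synthetic. Parameters
#'   other than `transcript_ids` are ignored.
#' * `"random"`: topology parameters drawn from sane ranges under `seed`, for
#'   validator sweeps.
#'
#' @param preset `"thra-like"`, `"thra"` or `"random"`.
#' @param n_shared Number of shared upstream exons (toy preset).
#' @param exon_width,intron_width Widths of shared exons and of introns (bp).
#' @param anchor_width Width of the last shared exon (the "9a-like" exon).
#' @param readthrough Length of the read-through extension forming isoform 1's
#'   unique terminal stretch (bp).
#' @param terminal_width Width of isoform 2's distinct terminal exon (bp).
#' @param terminal_gap Intron between the read-through end and isoform 2's
#'   terminal exon (bp).
#' @param strand `"+"` or `"-"`; minus-strand fixtures are a mirrored layout.
#' @param seqname,gene_id,gene_name Identifiers for the toy gene.
#' @param transcript_ids Length-2 character vector of transcript ids
#'   (isoform 1 = read-through, isoform 2 = distinct terminal exon). For the
#'   `"thra"` preset a length-4 vector: two exon-9b transcripts then two
#'   exon-10 transcripts; defaults to the published variant ids.
#' @param with_sequence Also generate a random locus sequence (`DNAStringSet`)
#'   consistent with the annotation coordinates.
#' @param seed Seed for sequence generation / randomized topology.
#' @return An object of class `exonproxy_fixture`: list with `gene`
#'   ([gene_model()]), `annotation` (`gtf_annotation`), `groups` (named list
#'   of transcript-id vectors, in 5'-to-3' order of their terminal exon),
#'   `sequence` (or `NULL`), `preset` and `params`.
#' @examples
#' fx <- make_fixture("thra-like")
#' fx$gene
#' @export
make_fixture <- function(preset = c("thra-like", "thra", "random"),
                         n_shared = 3L, exon_width = 150L, intron_width = 300L,
                         anchor_width = 350L, readthrough = 800L,
                         terminal_width = 848L, terminal_gap = 400L,
                         strand = "+", seqname = "chrT", gene_id = "TLG1",
                         gene_name = "THRAL", transcript_ids = NULL,
                         with_sequence = FALSE, seed = NULL) {
  preset <- match.arg(preset)
  if (preset == "thra") {
    return(make_thra_fixture(transcript_ids = transcript_ids,
                             with_sequence = with_sequence, seed = seed))
  }
  if (preset == "random") {
    return(with_seed(seed, {
      make_fixture(
        "thra-like",
        n_shared = sample(1:5, 1),
        exon_width = sample(80:400, 1),
        intron_width = sample(50:2000, 1),
        anchor_width = sample(150:600, 1),
        readthrough = sample(150:4000, 1),
        terminal_width = sample(150:2000, 1),
        terminal_gap = sample(1:3000, 1),
        strand = sample(c("+", "-"), 1),
        with_sequence = with_sequence,
        seed = if (is.null(seed)) NULL else seed + 1L
      )
    }))
  }
  if (is.null(transcript_ids)) transcript_ids <- c("ISO1", "ISO2")
  if (length(transcript_ids) != 2L)
    stop("the thra-like preset has exactly 2 transcripts")
  stopifnot(n_shared >= 0, exon_width > 0, intron_width > 0, anchor_width > 0,
            readthrough > 0, terminal_width > 0, terminal_gap > 0)

  offset <- 1000L
  shared_starts <- offset + 1L + (seq_len(n_shared) - 1L) * (exon_width + intron_width)
  shared <- cbind(shared_starts, shared_starts + exon_width - 1L)
  s9a <- offset + 1L + n_shared * (exon_width + intron_width)
  anchor <- c(s9a, s9a + anchor_width - 1L)
  iso1_term <- c(s9a, s9a + anchor_width + readthrough - 1L)
  t_start <- iso1_term[2] + terminal_gap + 1L
  iso2_term <- c(t_start, t_start + terminal_width - 1L)

  all_iv <- rbind(shared, anchor, iso1_term, iso2_term)
  if (strand == "-") {
    m <- max(all_iv) + offset
    flip <- function(iv) cbind(m - iv[, 2, drop = FALSE], m - iv[, 1, drop = FALSE])
    shared <- flip(shared); anchor <- flip(rbind(anchor))[1, ]
    iso1_term <- flip(rbind(iso1_term))[1, ]
    iso2_term <- flip(rbind(iso2_term))[1, ]
  }
  mk <- function(iv) genomic_intervals(seqname, iv[, 1], iv[, 2], strand)
  exons1 <- mk(rbind(shared, iso1_term))
  exons2 <- mk(rbind(shared, anchor, iso2_term))
  # overlap feasibility (guards pathological parameter choices)
  if (!IRanges::isDisjoint(IRanges::ranges(exons1)) ||
      !IRanges::isDisjoint(IRanges::ranges(exons2)))
    stop("infeasible topology: requested exons overlap")

  tx1 <- transcript_model(transcript_ids[1], gene_id, seqname, strand, exons1)
  tx2 <- transcript_model(transcript_ids[2], gene_id, seqname, strand, exons2)
  transcripts <- stats::setNames(list(tx1, tx2), transcript_ids)
  gene <- gene_model(gene_id, gene_name, seqname, strand, transcripts,
                     biotype = "protein_coding")
  annotation <- new_gtf_annotation(gene_model_records(gene))
  sequence <- NULL
  if (with_sequence) {
    span_end <- max(BiocGenerics::end(exonic_bases(transcripts))) + 500L
    sequence <- with_seed(seed, {
      s <- Biostrings::DNAStringSet(list(random_dna(span_end)))
      base::names(s) <- seqname
      s
    })
  }
  structure(list(
    gene = gene, annotation = annotation,
    groups = stats::setNames(list(transcript_ids[1], transcript_ids[2]),
                             transcript_ids),
    sequence = sequence, preset = "thra-like",
    params = list(n_shared = n_shared, exon_width = exon_width,
                  intron_width = intron_width, anchor_width = anchor_width,
                  readthrough = readthrough, terminal_width = terminal_width,
                  terminal_gap = terminal_gap, strand = strand, seed = seed)
  ), class = "exonproxy_fixture")
}

# Synthetic reconstruction of the human THRA locus: the exon 9a boundary, the
# exon 9b and exon 10 entries (exon, CDS, UTR, stop codon) carry the published
# chr17 coordinates; the eight shared upstream exons are synthetic.
make_thra_fixture <- function(transcript_ids = NULL, with_sequence = FALSE,
                              seed = NULL) {
  if (is.null(transcript_ids))
    transcript_ids <- c("ENST00000450525", "ENST0000054624",
                        "ENST00000264637", "ENST00000584985")
  if (length(transcript_ids) != 4L)
    stop("the thra preset has exactly 4 transcripts (two per isoform)")
  sq <- "chr17"; st <- "+"
  gid <- "ENSG00000126351"
  shared_starts <- 40062201 + (0:7) * 3300
  shared <- cbind(shared_starts, shared_starts + 199)
  e9a <- c(40088983, 40089333)         # last shared exon; 9b starts at 40,089,334
  e9ab_long <- c(40088983, 40092627)   # read-through, full 9b
  e9ab_short <- c(40088983, 40089730)  # read-through, short 9b variant
  e10_long <- c(40093020, 40093867)
  e10_short <- c(40093137, 40093867)
  mk <- function(iv) genomic_intervals(sq, iv[, 1], iv[, 2], st)
  tx <- list(
    transcript_model(transcript_ids[1], gid, sq, st,
                     exons = mk(rbind(shared, e9ab_long)),
                     cds = genomic_intervals(sq, 40088983, 40089727, st),
                     stop_codon = genomic_intervals(sq, 40089728, 40089730, st),
                     utr3 = genomic_intervals(sq, 40089731, 40092627, st)),
    transcript_model(transcript_ids[2], gid, sq, st,
                     exons = mk(rbind(shared, e9ab_short))),
    transcript_model(transcript_ids[3], gid, sq, st,
                     exons = mk(rbind(shared, e9a, e10_long)),
                     cds = genomic_intervals(sq, 40093020, 40093613, st),
                     stop_codon = genomic_intervals(sq, 40093614, 40093616, st),
                     utr3 = genomic_intervals(sq, 40093617, 40093867, st)),
    transcript_model(transcript_ids[4], gid, sq, st,
                     exons = mk(rbind(shared, e9a, e10_short)))
  )
  names(tx) <- transcript_ids
  gene <- gene_model(gid, "THRA", sq, st, tx, biotype = "protein_coding")
  annotation <- new_gtf_annotation(gene_model_records(gene, source = "ensembl_havana"))
  structure(list(
    gene = gene, annotation = annotation,
    groups = list(THRA1 = transcript_ids[1:2], THRA2 = transcript_ids[3:4]),
    sequence = NULL, preset = "thra",
    params = list(transcript_ids = transcript_ids, seed = seed)
  ), class = "exonproxy_fixture")
}

#' @export
print.exonproxy_fixture <- function(x, ...) {
  cat(sprintf("<exonproxy_fixture> preset '%s'\n", x$preset))
  print(x$gene)
  invisible(x)
}

#' Build a gorilla-like THRA gene fixture for cross-species grafting
#'
#' A synthetic reconstruction of the gorilla THRA locus used to exercise the
#' exon-locating and grafting workflow: a minus-strand gene on chr5 whose
#' transcript carries the published gorilla THRA1 accession, a 4 kb random
#' locus slice (named in `chr:start-end` convention), and a synthetic 363 nt
#' "human exon 10" query whose mutated reverse complement is embedded at the
#' published BLAST-hit coordinates chr5:41,857,943-41,858,305(-). All sequence
#' content is random (synthetic); only the coordinate geometry follows the
#' published locus.
#'
#' @param seed Seed for the random sequences.
#' @param n_subs Substitutions introduced into the embedded homolog
#'   (default 7, about 2% divergence).
#' @return A list with `gene` ([gene_model()]), `sequence` (`DNAStringSet`
#'   slice `chr5:41856001-41860000`), `exon10_query` (`DNAString`),
#'   `hit_truth` and `donor` (`GRanges`).
#' @export
make_gorilla_fixture <- function(seed = 1L, n_subs = 7L) {
  sq <- "chr5"; st <- "-"
  ex_ends <- c(41888473, 41888473 - (2:8) * 3000)
  exons <- genomic_intervals(sq, c(ex_ends[1] - 473, ex_ends[-1] - 149),
                             ex_ends, st)
  exon9 <- genomic_intervals(sq, 41858400, 41859100, st)  # read-through 9a+9b
  tx <- transcript_model("XM_019026893.2", "GGO_THRA", sq, st,
                         exons = c(strip_seqinfo(exons), strip_seqinfo(exon9)))
  gene <- gene_model("GGO_THRA", "THRA", sq, st,
                     transcripts = list("XM_019026893.2" = tx),
                     biotype = "protein_coding")
  hit_truth <- genomic_intervals(sq, 41857943, 41858305, st)
  donor <- genomic_intervals(sq, 41857944, 41858305, st)
  slice_start <- 41856001; slice_end <- 41860000
  out <- with_seed(seed, {
    query <- random_dna(363L)
    slice <- random_dna(slice_end - slice_start + 1L)
    hom <- as.character(query)
    pos <- sample(10:354, n_subs)
    for (p in pos) {
      cur <- substr(hom, p, p)
      substr(hom, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    hom_rc <- Biostrings::reverseComplement(Biostrings::DNAString(hom))
    at <- 41857943 - slice_start + 1L
    slice <- Biostrings::replaceLetterAt(slice, at:(at + 362L), hom_rc)
    seqs <- Biostrings::DNAStringSet(list(slice))
    base::names(seqs) <- sprintf("%s:%d-%d", sq, slice_start, slice_end)
    list(query = query, seqs = seqs)
  })
  list(gene = gene, sequence = out$seqs, exon10_query = out$query,
       hit_truth = hit_truth, donor = donor)
}

#' Simulate 3'-biased single-end read placements from an isoform mixture
#'
#' Emulates UMI-collapsed 10X-style data: one read per molecule, the molecule's
#' isoform drawn from the molar mixture, and the read's 3' end placed at a
#' distance from the transcript 3' end drawn from an exponential distribution
#' of scale `bias_scale` truncated to the transcript (mode `"threeprime"`).
#' Mode `"uniform"` emulates a bulk full-length library: molecules are sampled
#' proportionally to molar fraction times effective length
#' (`spliced length - read_length + 1`) and read starts are uniform — the
#' regime where length-normalized (TPM) proxy counts recover molar fractions.
#' Reads crossing exon junctions are emitted as multiple blocks at genomic
#' coordinates.
#'
#' @param x An `exonproxy_fixture` or a [gene_model()].
#' @param fractions Molar fractions, one per transcript (named by transcript
#'   id, or unnamed in the gene's transcript order); must sum to 1.
#' @param n_reads Number of reads (>= 1).
#' @param read_length Read length in bp (default 91, the 10X cDNA read).
#' @param bias `"threeprime"` (default) or `"uniform"`.
#' @param bias_scale Mean distance (bp) of the read 3' end from the transcript
#'   3' end under the truncated exponential (default 400).
#' @param seed Integer seed; the simulation is deterministic given a seed.
#' @param sample Sample label attached to all reads.
#' @return An object of class `simulated_reads`: list with `reads`
#'   (`GRangesList`, one element per read, `isoform` and `sample` metadata on
#'   the outer object), `isoform` (character vector of source transcript ids)
#'   and `spec` (the simulation parameters).
#' @examples
#' fx <- make_fixture("thra-like")
#' sim <- simulate_reads(fx, c(0.2, 0.8), n_reads = 1000, seed = 7)
#' table(sim$isoform)
#' @export
simulate_reads <- function(x, fractions, n_reads, read_length = 91L,
                           bias = c("threeprime", "uniform"),
                           bias_scale = 400, seed = NULL, sample = "sample1") {
  bias <- match.arg(bias)
  gene <- if (inherits(x, "exonproxy_fixture")) x$gene else x
  if (!inherits(gene, "gene_model")) stop("'x' must be a fixture or gene_model")
  txs <- gene$transcripts
  k <- length(txs)
  if (is.null(names(fractions))) {
    if (length(fractions) != k)
      stop("need one fraction per transcript (", k, ")")
    names(fractions) <- names(txs)
  }
  if (!setequal(names(fractions), names(txs)))
    stop("fraction names do not match the gene's transcript ids")
  fractions <- fractions[names(txs)]
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (bias_scale <= 0) stop("bias_scale must be > 0")
  L <- vapply(txs, spliced_length, integer(1))
  active <- fractions > 0
  if (any(read_length > L[active]))
    stop("read_length (", read_length, ") exceeds the spliced length of: ",
         paste(names(txs)[active & read_length > L], collapse = ", "))

  out <- with_seed(seed, {
    w <- if (bias == "uniform") fractions * (L - read_length + 1) else fractions
    iso <- sample.int(k, n_reads, replace = TRUE, prob = w)
    Ls <- L[iso]
    if (bias == "threeprime") {
      Tr <- Ls - read_length
      u <- stats::runif(n_reads)
      d <- -bias_scale * log(1 - u * (1 - exp(-Tr / bias_scale)))
      o <- pmin(floor(d), Tr)
      s <- Ls - o - read_length + 1
    } else {
      s <- floor(stats::runif(n_reads) * (Ls - read_length + 1)) + 1
    }
    e <- s + read_length - 1
    blocks <- map_transcript_blocks(txs, iso, s, e)
    list(iso = iso, blocks = blocks)
  })
  reads <- out$blocks
  iso_ids <- names(txs)[out$iso]
  base::names(reads) <- sprintf("read%06d", seq_len(n_reads))
  S4Vectors::mcols(reads)$isoform <- iso_ids
  S4Vectors::mcols(reads)$sample <- sample
  structure(list(reads = reads, isoform = iso_ids,
                 spec = list(fractions = fractions, n_reads = n_reads,
                             read_length = read_length, bias = bias,
                             bias_scale = bias_scale, seed = seed,
                             sample = sample)),
            class = "simulated_reads")
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("<simulated_reads> %d reads (%s bias), isoform mix: %s\n",
              x$spec$n_reads, x$spec$bias,
              paste(sprintf("%s=%.3g", names(x$spec$fractions),
                            x$spec$fractions), collapse = ", ")))
  invisible(x)
}

# Project transcript-coordinate intervals [s, e] (1 = 5' end) onto genomic
# blocks through each transcript's exon structure. Vectorized over reads;
# returns a GRangesList parallel to `iso`.
map_transcript_blocks <- function(txs, iso, s, e) {
  n <- length(iso)
  res_seq <- character(0); res_start <- numeric(0); res_end <- numeric(0)
  res_strand <- character(0); res_read <- integer(0)
  for (t in unique(iso)) {
    idx <- which(iso == t)
    tx <- txs[[t]]
    ex <- tx$exons
    if (tx$strand == "-") {
      ord <- order(-BiocGenerics::start(ex))
    } else {
      ord <- order(BiocGenerics::start(ex))
    }
    ex <- ex[ord]
    w <- BiocGenerics::width(ex)
    txe <- cumsum(w); txs0 <- txe - w + 1
    gs <- BiocGenerics::start(ex); ge <- BiocGenerics::end(ex)
    for (j in seq_along(w)) {
      os <- pmax(s[idx], txs0[j]); oe <- pmin(e[idx], txe[j])
      sel <- os <= oe
      if (!any(sel)) next
      if (tx$strand == "+") {
        bs <- gs[j] + (os[sel] - txs0[j])
        be <- gs[j] + (oe[sel] - txs0[j])
      } else {
        be <- ge[j] - (os[sel] - txs0[j])
        bs <- ge[j] - (oe[sel] - txs0[j])
      }
      res_seq <- c(res_seq, rep(tx$seqname, sum(sel)))
      res_start <- c(res_start, bs)
      res_end <- c(res_end, be)
      res_strand <- c(res_strand, rep(tx$strand, sum(sel)))
      res_read <- c(res_read, idx[sel])
    }
  }
  gr <- GenomicRanges::GRanges(res_seq, IRanges::IRanges(res_start, res_end),
                               strand = res_strand)
  o <- order(res_read, res_start)
  split(gr[o], factor(res_read[o], levels = seq_len(n)))
}
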