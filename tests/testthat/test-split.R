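thra_split <- function() {
  fx <- make_fixture("thra")
  part <- partition_transcripts(fx$gene, groups = fx$groups)
  px <- proxy_regions(fx$gene, part)
  list(fx = fx, px = px,
       res = split_gene(fx$annotation, fx$gene$gene_id, px))
}

test_that("splitting THRA yields THRA, THRA1 and THRA2 with the published exon-10 proxy", {
  s <- thra_split()
  ann <- s$res$annotation
  expect_setequal(unique(stats::na.omit(ann$records$gene_name)),
                  c("THRA", "THRA1", "THRA2"))
  e2 <- ann$records[!is.na(ann$records$gene_name) &
                      ann$records$gene_name == "THRA2" &
                      ann$records$feature == "exon", ]
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$start, 40093020)
  expect_equal(e2$end, 40093867)
  # every pseudo-gene carries the fields a 10X-style reference builder needs
  new_rows <- ann$records[ann$records$gene_name %in% c("THRA1", "THRA2") &
                            !is.na(ann$records$gene_name), ]
  expect_true(all(!is.na(new_rows$gene_id)))
  expect_true(all(!is.na(new_rows$gene_biotype)))
  expect_true(all(!is.na(new_rows$transcript_id[new_rows$feature != "gene"])))
  # the retained gene keeps its identity and the shared exons end at exon 9a
  thra_ex <- ann$records[!is.na(ann$records$gene_name) &
                           ann$records$gene_name == "THRA" &
                           ann$records$feature == "exon", ]
  expect_equal(max(thra_ex$end), 40089333)
  # the split annotation is itself valid GTF
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  expect_no_error(reread <- read_gtf(path))
  expect_setequal(names(reread$genes),
                  c("ENSG00000126351", "ENSG00000126351-THRA1",
                    "ENSG00000126351-THRA2"))
})

test_that("records of other genes are preserved verbatim through a split", {
  path <- withr::local_tempfile(fileext = ".gtf")
  fx <- make_fixture("thra")
  other <- make_gtf_lines_other_gene()
  write_gtf(fx$annotation, path)
  lines <- c(other, readLines(path))
  writeLines(lines, path)
  ann <- read_gtf(path)
  part <- partition_transcripts(ann$genes[["ENSG00000126351"]],
                                groups = fx$groups)
  px <- proxy_regions(ann$genes[["ENSG00000126351"]], part)
  res <- split_gene(ann, "ENSG00000126351", px)
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(res$annotation, out)
  got <- readLines(out)
  expect_true(all(other %in% got))
})

test_that("exonic bases are conserved between the original gene and retained + pseudo-genes", {
  s <- thra_split()
  orig <- exonic_bases(s$fx$gene$transcripts)
  ann <- s$res$annotation
  rec <- ann$records
  ex <- rec[rec$feature == "exon" &
              rec$gene_id %in% c("ENSG00000126351", "ENSG00000126351-THRA1",
                                 "ENSG00000126351-THRA2"), ]
  after <- merge_intervals(genomic_intervals("chr17", ex$start, ex$end, "+"))
  off <- 40060000L; n <- 40100000L - off
  v_orig <- bitmap_from_granges(GenomicRanges::shift(orig, -off), n)
  v_after <- bitmap_from_granges(GenomicRanges::shift(after, -off), n)
  expect_identical(v_orig, v_after)
  # disjointness of retained vs pseudo bases
  ret <- rec[rec$feature == "exon" & rec$gene_id == "ENSG00000126351", ]
  pse <- rec[rec$feature == "exon" & rec$gene_id != "ENSG00000126351", ]
  v_ret <- bitmap_from_granges(GenomicRanges::shift(
    genomic_intervals("chr17", ret$start, ret$end, "+"), -off), n)
  v_pse <- bitmap_from_granges(GenomicRanges::shift(
    genomic_intervals("chr17", pse$start, pse$end, "+"), -off), n)
  expect_false(any(v_ret & v_pse))
})

test_that("re-splitting an already split annotation is an error or an explicit no-op, never a double split", {
  s <- thra_split()
  expect_error(split_gene(s$res$annotation, "ENSG00000126351", s$px),
               "already present")
  expect_message(
    again <- split_gene(s$res$annotation, "ENSG00000126351", s$px,
                        on_existing = "skip"),
    "unchanged")
  expect_identical(again$annotation$records, s$res$annotation$records)
})

test_that("split counts are conserved: THRA + THRA1 + THRA2 reads equal unsplit THRA reads", {
  fx <- make_fixture("thra")
  part <- partition_transcripts(fx$gene, groups = fx$groups)
  px <- proxy_regions(fx$gene, part)
  res <- split_gene(fx$annotation, fx$gene$gene_id, px)
  sim <- simulate_reads(fx, c(0.1, 0.1, 0.4, 0.4), n_reads = 5000, seed = 31)

  count_over_gene_exons <- function(rec, gids) {
    ex <- rec[rec$feature == "exon" & rec$gene_id %in% gids, ]
    gr <- genomic_intervals("chr17", ex$start, ex$end, "+")
    regions <- merge_intervals(gr)
    names(regions) <- rep("g", length(regions))
    sum(count_reads(sim$reads, regions))
  }
  unsplit <- count_over_gene_exons(fx$annotation$records, "ENSG00000126351")
  split_total <- count_over_gene_exons(
    res$annotation$records,
    c("ENSG00000126351", "ENSG00000126351-THRA1", "ENSG00000126351-THRA2"))
  expect_equal(unsplit, 5000L)  # all simulated reads fall in exons
  expect_equal(split_total, unsplit)
})

test_that("grafting reproduces the published gorilla transcript geometry", {
  g <- make_gorilla_fixture(seed = 5)
  grafted <- graft_terminal_exon(g$gene, g$donor, transcript_id = "THRA2-custom",
                                 utr_length = 487L, stop_codon = "downstream")
  tx <- grafted$transcripts[["THRA2-custom"]]
  span <- transcript_span(tx)
  expect_equal(GenomicRanges::start(span), 41857944)
  expect_equal(GenomicRanges::end(span), 41888473)
  expect_equal(length(tx$exons), 10L)  # exons 1-9 plus the grafted exon 10
  # 3'UTR appended strand-aware immediately downstream of the donor
  expect_equal(GenomicRanges::start(tx$utr3), 41857944 - 487)
  expect_equal(GenomicRanges::end(tx$utr3), 41857943)
  expect_equal(GenomicRanges::start(tx$stop_codon), 41857941)
  expect_equal(GenomicRanges::end(tx$stop_codon), 41857943)
  # emitted records pass GTF validation
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gene_model_records(grafted), path)
  expect_no_error(read_gtf(path))
})

test_that("grafting on the plus strand and its error contracts behave", {
  tx <- transcript_model("t1", "G", "chr8", "+",
                         exons = genomic_intervals("chr8", c(100, 300), c(200, 400)))
  g <- gene_model("G", "G", "chr8", "+", list(t1 = tx))
  grafted <- graft_terminal_exon(g, genomic_intervals("chr8", 500, 600, "+"),
                                 transcript_id = "t2")
  tx2 <- grafted$transcripts[["t2"]]
  expect_equal(length(tx2$exons), 3L)
  span <- transcript_span(tx2)
  expect_equal(c(GenomicRanges::start(span), GenomicRanges::end(span)),
               c(100, 600))
  # overlapping donor -> error
  expect_error(graft_terminal_exon(g, genomic_intervals("chr8", 350, 450, "+")),
               "overlaps")
  # wrong strand -> error
  expect_error(graft_terminal_exon(g, genomic_intervals("chr8", 500, 600, "-")),
               "strand")
  # donor 5' of everything -> error
  expect_error(graft_terminal_exon(g, genomic_intervals("chr8", 10, 50, "+")),
               "not 3'")
})
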