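test_that("explicit partitions validate membership and cover the THRA variant lists", {
  fx <- make_fixture("thra")
  part <- partition_transcripts(fx$gene, groups = fx$groups)
  expect_equal(length(part$groups), 2L)
  expect_equal(part$groups[[1]]$name, "THRA1")
  expect_setequal(part$groups[[2]]$transcript_ids,
                  c("ENST00000264637", "ENST00000584985"))
  expect_equal(length(part$unassigned), 0L)

  expect_error(partition_transcripts(fx$gene, groups = list(A = "NOPE")),
               "unknown transcript_id")
  expect_error(partition_transcripts(
    fx$gene, groups = list(A = "ENST00000264637", B = "ENST00000264637")),
    "more than one group")
  # transcripts left out are reported as unassigned
  p2 <- partition_transcripts(fx$gene, groups = list(T2 = fx$groups$THRA2))
  expect_setequal(p2$unassigned, fx$groups$THRA1)
})

test_that("automatic grouping by identical terminal exon matches exhaustive enumeration", {
  # single-transcript gene: one group
  tx <- transcript_model("solo", "G", "chr2", "+",
                         exons = genomic_intervals("chr2", 1, 100))
  g1 <- gene_model("G", "G", "chr2", "+", list(solo = tx))
  p1 <- partition_transcripts(g1, auto = TRUE)
  expect_equal(length(p1$groups), 1L)
  expect_equal(p1$groups[[1]]$transcript_ids, "solo")

  # 3 transcripts, two sharing a terminal exon -> 2 groups
  mk <- function(id, starts, ends)
    transcript_model(id, "G3", "chr2", "+",
                     exons = genomic_intervals("chr2", starts, ends))
  txs <- list(a = mk("a", c(1, 201), c(100, 300)),
              b = mk("b", c(51, 201), c(100, 300)),
              c = mk("c", c(1, 401), c(100, 500)))
  g3 <- gene_model("G3", "G3", "chr2", "+", txs)
  p3 <- partition_transcripts(g3, auto = TRUE)
  expect_equal(length(p3$groups), 2L)
  # oracle: enumerate terminal exons directly
  keys <- vapply(txs, function(t) {
    e <- t$exons[which.max(GenomicRanges::end(t$exons))]
    paste(GenomicRanges::start(e), GenomicRanges::end(e))
  }, character(1))
  expect_equal(length(unique(keys)), length(p3$groups))
  members <- lapply(p3$groups, `[[`, "transcript_ids")
  expect_true(any(vapply(members, setequal, logical(1), c("a", "b"))))
  expect_true(any(vapply(members, setequal, logical(1), "c")))
})

test_that("the terminal region follows the strand-aware 3' rule", {
  mk <- function(strand) {
    tx <- transcript_model("t", "G", "chr3", strand,
                           exons = genomic_intervals("chr3", c(1, 201),
                                                     c(100, 300), strand))
    gene_model("G", "G", "chr3", strand, list(t = tx))
  }
  plus <- terminal_region("t", mk("+"))
  expect_same_intervals(plus, genomic_intervals("chr3", 201, 300))
  minus <- terminal_region("t", mk("-"))
  expect_same_intervals(minus, genomic_intervals("chr3", 1, 100, "-"))
  expect_error(terminal_exon(transcript_model("e", "G", "chr3", "+",
                                              exons = GenomicRanges::GRanges())),
               "no exons")
})

test_that("the THRA2 terminal region is the union of the three published exon-10 entries", {
  fx <- make_fixture("thra")
  part <- partition_transcripts(fx$gene, groups = fx$groups)
  reg <- terminal_region(part$groups[[2]], fx$gene)
  expect_equal(length(reg), 1L)
  expect_equal(GenomicRanges::start(reg), 40093020)
  expect_equal(GenomicRanges::end(reg), 40093867)
})

test_that("distinguishing regions match the bitmap oracle on the worked toy geometry", {
  gene <- toy_pq_gene()
  part <- partition_transcripts(gene, groups = list(P = "P1", Q = "Q1"))
  suppressWarnings(px <- proxy_regions(gene, part))
  universe <- 4000L
  # oracle: terminal exon bases of P minus all exonic bases of Q
  vP <- bitmap_from_granges(genomic_intervals("chr9", 1001, 2000), universe) &
    !bitmap_from_granges(genomic_intervals("chr9", c(1001, 2500), c(1400, 3000)),
                         universe)
  expect_same_intervals(px$P$intervals, bitmap_to_granges(vP, "chr9"))
  expect_same_intervals(px$P$intervals, genomic_intervals("chr9", 1401, 2000))
  expect_same_intervals(px$Q$intervals, genomic_intervals("chr9", 2500, 3000))
  expect_equal(px$P$proxy_length, 600L)
})

test_that("indistinguishable groups raise an error naming the collision", {
  tx1 <- transcript_model("x", "G", "chr4", "+",
                          exons = genomic_intervals("chr4", c(1, 201), c(100, 300)))
  tx2 <- transcript_model("y", "G", "chr4", "+",
                          exons = genomic_intervals("chr4", c(1, 201), c(100, 300)))
  g <- gene_model("G", "G", "chr4", "+", list(x = tx1, y = tx2))
  part <- partition_transcripts(g, groups = list(A = "x", B = "y"))
  expect_error(distinguishing_region(part$groups[[1]], g, part),
               "not 3'-distinguishable.*B")
})

test_that("the THRA1 proxy starts immediately after exon 9a and proxies avoid shared bases", {
  fx <- make_fixture("thra")
  part <- partition_transcripts(fx$gene, groups = fx$groups)
  px <- proxy_regions(fx$gene, part)
  expect_equal(GenomicRanges::start(px$THRA1$intervals), 40089334)
  expect_equal(GenomicRanges::end(px$THRA1$intervals), 40092627)
  expect_equal(px$THRA1$proxy_length, 3294L)
  expect_equal(px$THRA2$proxy_length, 848L)

  # invariant: proxies never intersect bases shared with other transcripts
  universe_off <- 40060000L
  all_ex <- exonic_bases(fx$gene$transcripts)
  shift0 <- function(gr) GenomicRanges::shift(gr, -universe_off)
  n <- 40100000L - universe_off
  vprox <- bitmap_from_granges(shift0(px$THRA1$intervals), n) |
    bitmap_from_granges(shift0(px$THRA2$intervals), n)
  vshared <- bitmap_from_granges(
    shift0(subtract_intervals(all_ex,
                              merge_intervals(c(px$THRA1$intervals,
                                                px$THRA2$intervals)))), n)
  expect_false(any(vprox & vshared))
})

test_that("proxy regions are invariant under transcript and group listing order", {
  fx <- make_fixture("thra")
  part1 <- partition_transcripts(fx$gene, groups = fx$groups)
  gene_rev <- fx$gene
  gene_rev$transcripts <- rev(gene_rev$transcripts)
  part2 <- partition_transcripts(gene_rev, groups = rev(fx$groups))
  px1 <- proxy_regions(fx$gene, part1)
  px2 <- proxy_regions(gene_rev, part2)
  for (nm in names(px1)) {
    expect_same_intervals(px1[[nm]]$intervals, px2[[nm]]$intervals)
  }
})

test_that("short proxies trigger the configured warning and error thresholds", {
  gene <- toy_pq_gene()
  part <- partition_transcripts(gene, groups = list(P = "P1", Q = "Q1"))
  expect_warning(distinguishing_region(part$groups[[1]], gene, part,
                                       warn_below = 1000L), "short")
  expect_error(distinguishing_region(part$groups[[1]], gene, part,
                                     min_length = 601L), "min_length")
})

test_that("grouping specs round-trip through YAML and JSON", {
  spec <- list(gene_id = "ENSG00000126351",
               groups = list(THRA1 = c("ENST00000450525", "ENST0000054624"),
                             THRA2 = c("ENST00000264637", "ENST00000584985")),
               min_length = 150)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(spec, yml)
  got <- read_grouping_spec(yml)
  expect_equal(got$gene_id, spec$gene_id)
  expect_equal(got$groups$THRA2, spec$groups$THRA2)
  expect_equal(got$min_length, 150L)
  expect_false(got$auto)

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(spec, jsn, auto_unbox = TRUE)
  got2 <- read_grouping_spec(jsn)
  expect_equal(got2$groups, lapply(spec$groups, as.character))
})
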