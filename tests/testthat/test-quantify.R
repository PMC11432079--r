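toy_proxies <- function() {
  list(
    THRA1 = structure(list(group_name = "THRA1",
                           intervals = genomic_intervals("chr17", 40089334, 40092627),
                           proxy_length = 3294L), class = "proxy_region"),
    THRA2 = structure(list(group_name = "THRA2",
                           intervals = genomic_intervals("chr17", 40093020, 40093867),
                           proxy_length = 848L), class = "proxy_region")
  )
}

test_that("reads are assigned by the >= 1 bp overlap policy, once per region set", {
  px <- toy_proxies()
  reads <- GenomicRanges::GRangesList(
    contained = genomic_intervals("chr17", 40093100, 40093190),   # inside exon 10
    one_bp = genomic_intervals("chr17", 40092930, 40093020),      # 1 bp overlap
    outside = genomic_intervals("chr17", 40092930, 40093019),     # 0 bp overlap
    two_blocks = genomic_intervals("chr17", c(40093030, 40093200),
                                   c(40093080, 40093250))          # spliced, same region
  )
  counts <- count_reads(reads, px)
  expect_equal(counts["THRA2", "sample1"], 3L)
  expect_equal(counts["THRA1", "sample1"], 0L)
})

test_that("reads bridging two groups' regions are dropped and reported", {
  px <- toy_proxies()
  bridging <- GenomicRanges::GRangesList(
    r1 = genomic_intervals("chr17", c(40092600, 40093020),
                           c(40092627, 40093060)))
  expect_message(counts <- count_reads(bridging, px), "dropped")
  expect_equal(sum(counts), 0L)
})

test_that("overlapping region sets are rejected", {
  bad <- genomic_intervals("chr17", c(100, 150), c(200, 250))
  names(bad) <- c("A", "B")
  reads <- GenomicRanges::GRangesList(r = genomic_intervals("chr17", 100, 190))
  expect_error(count_reads(reads, bad), "disjoint")
})

test_that("counting agrees with a brute-force per-read scan on random placements", {
  set.seed(7)
  # 5 disjoint regions
  starts <- c(1000, 3000, 5000, 7000, 9000)
  px <- lapply(seq_along(starts), function(i) {
    structure(list(group_name = paste0("R", i),
                   intervals = genomic_intervals("chrZ", starts[i],
                                                 starts[i] + 499),
                   proxy_length = 500L), class = "proxy_region")
  })
  n <- 10000L
  s <- sample.int(11000L, n, replace = TRUE)
  w <- sample(30:120, n, replace = TRUE)
  reads_gr <- genomic_intervals("chrZ", s, s + w - 1L)
  reads <- split(reads_gr, seq_len(n))
  got <- count_reads(reads, px)
  want <- brute_force_counts(reads, px)
  expect_equal(got[names(want), "sample1"], want)
})

test_that("TPM follows the closed form and columns sum to one million", {
  counts <- matrix(c(10, 0), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(tpm(counts, c(a = 100, b = 50))["a", "s1"], 1e6)

  counts2 <- matrix(c(5, 5), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  got <- tpm(counts2, c(a = 100, b = 200))
  expect_equal(got["a", "s1"], 2e6 / 3, tolerance = 1e-9)
  expect_equal(got["b", "s1"], 1e6 / 3, tolerance = 1e-9)

  set.seed(12)
  cm <- matrix(rpois(60, 40), nrow = 6,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  lens <- setNames(sample(100:5000, 6), rownames(cm))
  tt <- tpm(cm, lens)
  expect_true(all(abs(colSums(tt) - 1e6) < 1e-6 * 1e6))

  # all-zero sample is NA, zero-length feature is an error
  cz <- cbind(cm, s0 = 0)
  expect_true(all(is.na(tpm(cz, lens)[, "s0"])))
  expect_error(tpm(cm, replace(lens, 1, 0)), "positive")
})

test_that("proxy-length TPM exceeds transcript-length TPM for the same counts", {
  # same THRA counts against a fixed background of other genes: normalizing by
  # the short proxy instead of the full transcript inflates the TPM value
  counts <- matrix(c(50, 200, 500, 800), nrow = 4,
                   dimnames = list(c("iso1", "iso2", "bg1", "bg2"), "s1"))
  len_tx <- c(iso1 = 5245, iso2 = 2799, bg1 = 2000, bg2 = 3500)
  len_proxy <- c(iso1 = 3294, iso2 = 848, bg1 = 2000, bg2 = 3500)
  t_tx <- tpm(counts, len_tx)
  t_px <- tpm(counts, len_proxy)
  expect_gt(t_px["iso1", "s1"], t_tx["iso1", "s1"])
  expect_gt(t_px["iso2", "s1"], t_tx["iso2", "s1"])
})

test_that("group TPM sums equal the 0/1 membership-matrix product", {
  expect_equal(
    sum_group_tpm(matrix(c(10, 5), nrow = 2,
                         dimnames = list(c("t1", "t2"), "s1")),
                  list(G = c("t1", "t2")))["G", "s1"],
    15)
  expect_warning(
    got <- sum_group_tpm(matrix(10, 1, 1, dimnames = list("t1", "s1")),
                         list(G = c("t1", "missing"))),
    "absent")
  expect_equal(got["G", "s1"], 10)

  set.seed(5)
  m <- matrix(runif(40, 0, 100), nrow = 8,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  groups <- list(A = c("t1", "t3", "t8"), B = c("t2", "t4"), C = "t5")
  got <- sum_group_tpm(m, groups)
  mem <- matrix(0, 3, 8, dimnames = list(names(groups), rownames(m)))
  for (g in names(groups)) mem[g, groups[[g]]] <- 1
  expect_equal(got, mem %*% m)
})

test_that("isoform fractions form a simplex, flag zero totals and ignore common rescaling", {
  m <- matrix(c(50, 50, 20, 80, 0, 0), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  fr <- isoform_fraction(m)
  expect_equal(fr[, "s1"], c(g1 = 0.5, g2 = 0.5))
  expect_equal(fr[, "s2"], c(g1 = 0.2, g2 = 0.8))
  expect_true(all(is.na(fr[, "s3"])))
  expect_equal(attr(fr, "undefined_samples"), "s3")
  fr2 <- isoform_fraction(m * 37.5)
  expect_equal(fr[, 1:2], fr2[, 1:2])
})

test_that("proxy agreement reports absolute differences with a verdict", {
  a <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  same <- proxy_agreement(a, a)
  expect_equal(same$mean_abs_diff, 0)
  expect_true(same$pass)

  b <- matrix(c(0.3, 0.7), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  rep <- proxy_agreement(a, b, tolerance = 0.02)
  expect_equal(rep$max_abs_diff, 0.1, tolerance = 1e-12)
  expect_false(rep$pass)

  colnames(b) <- "other"
  expect_error(proxy_agreement(a, b), "mismatch")
})

test_that("quantification tables round-trip through TSV", {
  m <- matrix(c(1.5, 2, 0, 4), 2, 2,
              dimnames = list(c("THRA1", "THRA2"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_tsv(m, path, comments = "unit test")
  got <- read_quant_tsv(path)
  expect_equal(got, m)
})

test_that("transcript TPM tables are read in wide and long form", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\ts1\ts2",
               "ENST00000264637\t10.5\t3",
               "ENST00000584985\t2\t0"), wide)
  m <- read_transcript_tpm(wide)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["ENST00000264637", "s1"], 10.5)

  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tsample\tTPM",
               "t1\ts1\t5", "t2\ts1\t10", "t1\ts2\t1"), long)
  m2 <- read_transcript_tpm(long)
  expect_equal(m2["t2", "s1"], 10)
  expect_equal(m2["t1", "s2"], 1)
  expect_equal(m2["t2", "s2"], 0)
})
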