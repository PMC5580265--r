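test_that("poly-A/poly-T clipping removes whole artifact runs and enforces min length", {
  # 5-A tail exceeds the genomic maximum of 4: the entire run goes
  expect_equal(clip_read("ACGTACGTACGTACGTACGTAAAAA", 4, 4, min_len = 10),
               "ACGTACGTACGTACGTACGT")
  # a run not exceeding the maximum is genomic signal and stays
  expect_equal(clip_read("ACGTACGTACGTACGTACGTAAAA", 4, 4, min_len = 10),
               "ACGTACGTACGTACGTACGTAAAA")
  # leading poly-T clipped symmetrically
  expect_equal(clip_read("TTTTTGACGTACGTACGTACGT", 4, 4, min_len = 10),
               "GACGTACGTACGTACGT")
  # a read falling under 20 nt after clipping is dropped
  r25 <- paste0(strrep("ACGT", 4), "AC", strrep("A", 7))  # 18 nt + 7 A
  expect_true(is.na(clip_read(r25, 4, 4, min_len = 20)))
  expect_true(is.na(clip_read("", 4, 4)))
})

test_that("clipping is idempotent and never lengthens a read", {
  set.seed(5)
  reads <- vapply(1:200, function(i) {
    core <- paste(sample(c("A", "C", "G", "T"), sample(15:40, 1), TRUE),
                  collapse = "")
    paste0(strrep("T", sample(0:8, 1)), core, strrep("A", sample(0:8, 1)))
  }, character(1))
  once <- clip_read(reads, 4, 4, min_len = 1)
  twice <- clip_read(once[!is.na(once)], 4, 4, min_len = 1)
  expect_equal(twice, once[!is.na(once)])
  expect_true(all(nchar(once[!is.na(once)]) <= nchar(reads[!is.na(once)])))
})

test_that("longest genomic homopolymer run is detected", {
  g <- Biostrings::DNAString("ACGTAAAACGTTTTTTG")
  expect_equal(max_homopolymer_run(g, "A"), 4L)
  expect_equal(max_homopolymer_run(g, "T"), 6L)
  expect_equal(max_homopolymer_run(Biostrings::DNAString("CCGG"), "A"), 0L)
})

test_that("alignment filter applies span, mismatch, gap and multi-mapper rules", {
  rec <- rbind(
    make_records("r1", 101, 140, mismatches = 4),        # 40/50 = 0.8, kept
    make_records("r2", 101, 139),                        # 39/50 < 0.8
    make_records("r3", 101, 150, mismatches = 5),        # too many mismatches
    make_records("r4", 101, 150, gaps = 1L),             # gapped
    make_records("r5", 101, 150, evalue = 1e-3),         # e-value above 1e-4
    make_records(c("r6", "r6"), c(101, 501), c(150, 550), score = 100),  # tie
    make_records(c("r7", "r7"), c(101, 501), c(150, 550),
                 score = c(100, 90))                     # unique best
  )
  kept <- filter_alignments(rec)
  expect_setequal(kept$read_id, c("r1", "r7"))
  expect_equal(kept$start[kept$read_id == "r7"], 101)
})

test_that("alignment filtering is idempotent, order-independent, and honours rDNA masking", {
  set.seed(8)
  rec <- make_records(sprintf("r%03d", 1:60),
                      start = sample(1:900, 60, TRUE),
                      end = 0, mismatches = sample(0:6, 60, TRUE),
                      score = sample(80:100, 60, TRUE))
  rec$end <- rec$start + sample(c(39L, 49L), 60, TRUE)
  kept <- filter_alignments(rec)
  expect_equal(filter_alignments(kept), kept)
  perm <- rec[sample(nrow(rec)), ]
  kept_perm <- filter_alignments(perm)
  expect_equal(kept_perm[order(kept_perm$read_id), ],
               kept[order(kept$read_id), ], ignore_attr = TRUE)

  rdna <- data.frame(replicon = "chr", start = 1, end = 2000)
  expect_equal(nrow(filter_alignments(rec, rdna_regions = rdna)), 0L)
})

test_that("5'-end coverage uses strand-aware read ends and smallest-library normalization", {
  recs <- list(
    A = make_records(sprintf("a%d", 1:10), start = 200, end = 249),
    B = make_records("b1", start = 100, end = 140, strand = "-")
  )
  tracks <- coverage_from_alignments(recs, c(chr = 500),
                                     library_sizes = c(A = 1000, B = 500))
  # raw 10 in the larger library scales by 500/1000
  expect_equal(tracks$A$cov[["chr|+"]][200], 5)
  # the smallest library is left unscaled
  expect_equal(tracks$B$norm_factor, 1)
  # minus-strand 5' end is the alignment end
  expect_equal(tracks$B$cov[["chr|-"]][140], 1)
  expect_equal(tracks$B$cov[["chr|-"]][100], 0)
  expect_error(coverage_from_alignments(recs, c(chr = 500),
                                        library_sizes = c(A = 0, B = 500)),
               "zero-size")
})

test_that("normalized genome-wide totals all equal the smallest library's raw total", {
  set.seed(21)
  recs <- lapply(c(400, 1000, 650), function(n) {
    p <- sample(1:950, n, TRUE)
    make_records(sprintf("r%d", seq_len(n)), start = p, end = p + 49)
  })
  names(recs) <- c("s", "m", "l")
  tracks <- coverage_from_alignments(recs, c(chr = 1000))
  totals <- vapply(tracks, function(t) sum(unlist(t$cov)), numeric(1))
  expect_true(all(abs(totals - 400) < 1e-9))
})

test_that("tabular and SAM alignment readers reconstruct the record fields", {
  tab <- tempfile(fileext = ".tsv")
  writeLines(c(
    "read1\tchr\t98.0\t50\t1\t0\t1\t50\t101\t150\t1e-20\t95\t50",
    "read2\tchr\t100.0\t40\t0\t0\t1\t40\t240\t201\t1e-18\t80\t50"
  ), tab)
  rec <- read_alignments_tabular(tab)
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$start, c(101, 201))
  expect_equal(rec$end, c(150, 240))
  expect_equal(rec$read_length, c(50, 50))
  expect_equal(rec$mismatches, c(1, 0))

  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr\tLN:1000",
    paste("read1\t0\tchr\t101\t60\t50M\t*\t0\t0", strrep("A", 50), "*",
          "NM:i:2\tAS:i:96", sep = "\t"),
    paste("read2\t16\tchr\t201\t60\t40M\t*\t0\t0", strrep("C", 40), "*",
          "NM:i:0", sep = "\t"),
    paste("read3\t4\t*\t0\t0\t*\t*\t0\t0", strrep("G", 30), "*", sep = "\t")
  ), sam)
  srec <- read_alignments_sam(sam)
  expect_equal(nrow(srec), 2L)  # unmapped read excluded
  expect_equal(srec$strand, c("+", "-"))
  expect_equal(srec$end, c(150, 240))
  expect_equal(srec$mismatches, c(2, 0))
  expect_equal(srec$score, c(96, 40))
})
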