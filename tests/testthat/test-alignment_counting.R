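rg_fixture <- function() build_repeat_genome(fixture_genome(), fixture_catalog())

test_that("exact substrings map with zero mismatches; threshold is respected", {
  rg <- rg_fixture()
  read <- substr(rg$sequence, 3, 14)
  aln <- naive_align(read, rg, max_mismatches = 0)
  expect_true(aln$mapped)
  expect_equal(aln$offset, 2L)
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$strand, "+")
  # one substitution: mapped at max_mismatches 1, unmapped at 0
  sub <- read
  substr(sub, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(read, 5, 5))[1]
  expect_true(naive_align(sub, rg, max_mismatches = 1)$mapped)
  expect_false(naive_align(sub, rg, max_mismatches = 0)$mapped)
})

test_that("reverse-complement reads map on the minus strand", {
  set.seed(14)
  ref <- random_dna(120)
  read <- oracle_revcomp(substr(ref, 41, 60))
  stopifnot(read != substr(ref, 41, 60))  # not rc-palindromic
  aln <- naive_align(read, ref, max_mismatches = 0)
  expect_true(aln$mapped)
  expect_equal(aln$strand, "-")
  expect_equal(aln$offset, 40L)
})

test_that("spacer Ns always count as mismatches", {
  rg <- rg_fixture()
  # read straddling the spacer: positions 17..28 of the repeat genome
  read <- paste0(substr(rg$sequence, 17, 20), "AAAAA",
                 substr(rg$sequence, 26, 28))
  # even if the non-N bases agree perfectly, the 5 Ns give >= 5 mismatches
  expect_false(naive_align(read, rg, max_mismatches = 4)$mapped)
  expect_true(naive_align(read, rg, max_mismatches = 5)$mapped)
})

test_that("scan and seed methods agree with the brute-force oracle", {
  set.seed(21)
  for (i in 1:60) {
    ref <- random_dna(sample(100:400, 1))
    mm_max <- sample(0:3, 1)
    if (i %% 2 == 0) {
      off <- sample(nchar(ref) - 36, 1)
      read <- substr(ref, off, off + 35)
      nmut <- sample(0:4, 1)
      for (p in sample(36, nmut)) substr(read, p, p) <-
          sample(c("A", "C", "G", "T"), 1)
      if (runif(1) < 0.5) read <- oracle_revcomp(read)
    } else {
      read <- random_dna(36)
    }
    want <- oracle_align(read, ref, mm_max)
    got_scan <- naive_align(read, ref, mm_max, method = "scan")
    got_seed <- naive_align(read, ref, mm_max, method = "seed")
    expect_equal(got_scan$mapped, want$mapped)
    expect_equal(got_seed$mapped, want$mapped)
    if (want$mapped) {
      expect_equal(got_scan$mismatches, want$mismatches)
      expect_equal(got_seed$mismatches, want$mismatches)
      expect_equal(got_seed$offset, got_scan$offset)
      expect_equal(got_seed$strand, got_scan$strand)
    }
  }
})

test_that("tie-breaking picks the smallest offset, forward first", {
  ref <- paste0("ACGTACGT", "TTTT", "ACGTACGT")  # exact match at 0 and 12
  aln <- naive_align("ACGTACGT", ref, 0)
  expect_equal(aln$offset, 0L)
  # palindromic read maps forward and reverse at the same offset: forward wins
  aln2 <- naive_align("ACGT", "GGACGTGG", 0)
  expect_equal(aln2$strand, "+")
  expect_equal(aln2$offset, 2L)
})

test_that("input validation on reads", {
  rg <- rg_fixture()
  expect_error(naive_align("", rg), "empty read")
  expect_error(naive_align("ACGU", rg), "outside")
  expect_error(naive_align(strrep("A", 100), rg), "exceeds")
  expect_error(naive_align("ACGT", rg, max_mismatches = -1), ">= 0")
})

test_that("count_hits_reads counts distinct mapped reads over the library", {
  rg <- rg_fixture()
  reads <- c(substr(rg$sequence, 1, 12), substr(rg$sequence, 27, 38),
             "GGGGGGGGGGGG", "TTTTTTTTTTTT")
  hc <- count_hits_reads(reads, rg, max_mismatches = 0)
  expect_s3_class(hc, "hit_counts")
  expect_equal(hc$hits, 2L)
  expect_equal(hc$total_reads, 4L)
  expect_equal(hc$family, "satA")
})

test_that("SAM counting matches the naive path and honours flags", {
  rg <- rg_fixture()
  set.seed(5)
  reads <- c(vapply(1:6, function(i) {
    o <- sample(nchar(rg$sequence) - 12, 1)
    substr(rg$sequence, o, o + 11)
  }, character(1)), replicate(4, random_dna(12)))
  reads <- reads[!grepl("N", reads)]
  aln <- naive_align(reads, rg, max_mismatches = 1)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, reads, rg, sam)
  via_sam <- count_hits_sam(sam, "satA")
  via_reads <- count_hits_reads(reads, rg, max_mismatches = 1)
  expect_equal(via_sam$hits, via_reads$hits)
  expect_equal(via_sam$total_reads, via_reads$total_reads)
})

test_that("secondary records never double-count a read", {
  sam <- withr::local_tempfile(fileext = ".sam")
  recs <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:satA\tLN:45",
    # 4 reads mapped once
    sprintf("m%d\t0\tsatA\t1\t255\t8M\t*\t0\t0\tACGTACGT\t*", 1:4),
    # 1 read with a primary and 3 secondary records
    "multi\t0\tsatA\t1\t255\t8M\t*\t0\t0\tACGTACGT\t*",
    sprintf("multi\t256\tsatA\t%d\t255\t8M\t*\t0\t0\tACGTACGT\t*", c(5, 9, 13)),
    # 5 unmapped
    sprintf("u%d\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGT\t*", 1:5))
  writeLines(recs, sam)
  hc <- count_hits_sam(sam, "satA")
  expect_equal(hc$hits, 5L)
  expect_equal(hc$total_reads, 10L)
})

test_that("SAM stream without unmapped records demands an explicit total", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:satA\tLN:45",
               "r1\t0\tsatA\t1\t255\t8M\t*\t0\t0\tACGTACGT\t*"), sam)
  expect_error(count_hits_sam(sam, "satA"), "total_reads")
  hc <- count_hits_sam(sam, "satA", total_reads = 1000L)
  expect_equal(hc$hits, 1L)
  expect_equal(hc$total_reads, 1000L)
  expect_error(count_hits_sam(sam, "other_family", total_reads = 10L),
               "do not match")
})

test_that("enrichment implements the normalised ratio and its CI", {
  hc <- function(h, t, f = "sat") structure(
    list(family = f, hits = as.integer(h), total_reads = as.integer(t)),
    class = "hit_counts")
  er <- enrichment(hc(120, 10000), hc(100, 10000))
  expect_equal(er$fold, 1.2)
  se <- sqrt(1 / 120 - 1 / 10000 + 1 / 100 - 1 / 10000)
  expect_equal(er$ci_low, exp(log(1.2) - qnorm(0.975) * se))
  expect_equal(er$ci_high, exp(log(1.2) + qnorm(0.975) * se))
  expect_true(er$ci_low <= er$fold && er$fold <= er$ci_high)
  # identity and degenerate cases
  expect_equal(enrichment(hc(50, 1000), hc(50, 1000))$fold, 1)
  und <- enrichment(hc(50, 1000), hc(0, 1000))
  expect_true(und$undefined)
  expect_true(is.na(und$fold))
  expect_error(enrichment(hc(1, 10, "a"), hc(1, 10, "b")), "mismatched")
  # library-size normalisation matters; raw mode ignores totals
  er2 <- enrichment(hc(120, 20000), hc(100, 10000))
  expect_equal(er2$fold, 0.6)
  expect_equal(enrichment(hc(120, 20000), hc(100, 10000),
                          normalize = "raw")$fold, 1.2)
})

test_that("enrichment is symmetric under swapping chip and input", {
  hc <- function(h, t) structure(
    list(family = "s", hits = as.integer(h), total_reads = as.integer(t)),
    class = "hit_counts")
  set.seed(9)
  for (i in 1:20) {
    h1 <- sample(1:500, 1); h2 <- sample(1:500, 1)
    t1 <- sample(1000:5000, 1); t2 <- sample(1000:5000, 1)
    f1 <- enrichment(hc(h1, t1), hc(h2, t2))$fold
    f2 <- enrichment(hc(h2, t2), hc(h1, t1))$fold
    expect_equal(f1, 1 / f2, tolerance = 1e-12)
  }
})
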