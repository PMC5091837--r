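test_that("concatenation puts exactly one spacer between instance segments", {
  rg <- build_repeat_genome(fixture_genome(), fixture_catalog())
  expect_equal(nchar(rg$sequence), 20L + 5L + 20L)
  expect_equal(substr(rg$sequence, 21, 25), "NNNNN")
  expect_equal(substr(rg$sequence, 1, 20), "ACGTACGTACGTACGTACGT")
  expect_equal(substr(rg$sequence, 26, 45), "ACGTTGCAACGTTGCAACGT")
  # lengths 120 + 80 with a 5-nt spacer give 205
  g <- c(c1 = random_dna(300))
  cat2 <- repeat_catalog(c("c1", "c1"), c(0L, 150L), c(120L, 230L),
                         c("+", "+"), c("f", "f"))
  expect_equal(nchar(build_repeat_genome(g, cat2)$sequence), 205L)
})

test_that("a single instance yields its subsequence with no spacer", {
  g <- fixture_genome()
  cat1 <- fixture_catalog()[1, ]
  rg <- build_repeat_genome(g, cat1)
  expect_equal(rg$sequence, substr(g[[1]], 11, 30))
  expect_false(grepl("N", rg$sequence))
})

test_that("minus-strand instances are reverse complemented under the default policy", {
  set.seed(3)
  g <- c(c1 = random_dna(200))
  cat1 <- repeat_catalog("c1", 50L, 90L, "-", "f")
  rg <- build_repeat_genome(g, cat1)
  expect_equal(rg$sequence, oracle_revcomp(substr(g[[1]], 51, 90)))
  rg_plus <- build_repeat_genome(g, cat1, strand_policy = "as_plus")
  expect_equal(rg_plus$sequence, substr(g[[1]], 51, 90))
})

test_that("bounds violations, empty families and multi-family input error", {
  g <- fixture_genome()
  expect_error(build_repeat_genome(g, repeat_catalog("chr1", 60L, 100L, "+", "f")),
               "bounds")
  expect_error(build_repeat_genome(g, fixture_catalog()[0, ]), "empty family")
  two <- repeat_catalog(c("chr1", "chr1"), c(0L, 10L), c(5L, 20L),
                        c("+", "+"), c("f", "g"))
  expect_error(build_repeat_genome(g, two), "multiple families")
  expect_error(build_repeat_genome(g, fixture_catalog(), spacer = "NANNA"),
               "spacer")
  expect_warning(build_repeat_genome(g, fixture_catalog(),
                                     expected_read_length = 36L),
                 "shorter than the expected")
})

test_that("add_consensus appends the printed minor satellite consensus after one spacer", {
  g <- c(c1 = random_dna(150))
  rg <- build_repeat_genome(g, repeat_catalog("c1", 0L, 100L, "+", "minor_sat"))
  expect_equal(nchar(minor_satellite_consensus), 120L)
  rg2 <- add_consensus(rg, "minor_sat_consensus", minor_satellite_consensus)
  expect_equal(nchar(rg2$sequence), 100L + 5L + 120L)
  expect_equal(substr(rg2$sequence, 106, 225), minor_satellite_consensus)
  expect_equal(rg2$segments$source, c("instance", "consensus"))
  expect_error(add_consensus(rg, "bad", "ACGU"), "outside")
  expect_error(add_consensus(rg, "bad", ""), "empty")
})

test_that("map_offset inverts the construction and labels spacers", {
  g <- c(c1 = random_dna(300))
  cat2 <- repeat_catalog(c("c1", "c1"), c(0L, 150L), c(120L, 230L),
                         c("+", "-"), c("f", "f"))
  rg <- build_repeat_genome(g, cat2)
  m0 <- map_offset(rg, 0L)
  expect_equal(m0$source, "instance")
  expect_equal(m0$genomic_pos, 0L)
  expect_equal(map_offset(rg, 122L)$source, "spacer")
  m125 <- map_offset(rg, 125L)
  expect_equal(m125$within, 0L)
  # minus-strand segment: rg position 125 is the instance's LAST genomic base
  expect_equal(m125$genomic_pos, 229L)
  expect_error(map_offset(rg, 205L), "out of range")
  expect_error(map_offset(rg, -1L), "out of range")
  # every non-spacer offset maps to the genomic base that generated it
  gchars <- strsplit(g[[1]], "")[[1]]
  rgchars <- strsplit(rg$sequence, "")[[1]]
  mo <- map_offset(rg, 0:(nchar(rg$sequence) - 1L))
  for (i in seq_len(nrow(mo))) {
    if (mo$source[i] == "spacer") {
      expect_equal(rgchars[i], "N")
    } else {
      seg <- rg$segments[rg$segments$name == mo$name[i], ]
      base <- gchars[mo$genomic_pos[i] + 1L]
      if (seg$strand == "-") base <- oracle_revcomp(base)
      expect_equal(rgchars[i], base)
    }
  }
})

test_that("FASTA writing wraps at 60 columns and round-trips exactly", {
  g <- c(c1 = random_dna(400))
  cat2 <- repeat_catalog(c("c1", "c1"), c(0L, 150L), c(120L, 230L),
                         c("+", "-"), c("fam", "fam"))
  rg <- build_repeat_genome(g, cat2)  # 205 nt
  fa <- withr::local_tempfile(fileext = ".fa")
  write_repeat_genome_fasta(rg, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], ">fam")
  expect_equal(nchar(lines[-1]), c(60L, 60L, 60L, 25L))
  rt <- read_repeat_genome_fasta(fa)
  expect_equal(rt$sequence, rg$sequence)
  expect_equal(rt$segments$offset_start, rg$segments$offset_start)
  expect_equal(rt$family, rg$family)
  # empty repeat genomes are refused
  rg$sequence <- ""
  rg$segments <- rg$segments[0, ]
  expect_error(write_repeat_genome_fasta(rg, fa), "empty family")
})

test_that("spacer-run invariant: N runs of spacer length = segments - 1", {
  set.seed(8)
  for (rep in 1:5) {
    n_inst <- sample(2:5, 1)
    lens <- sample(30:80, n_inst, TRUE)
    starts <- cumsum(c(10L, lens[-n_inst] + 10L))
    g <- c(c1 = random_dna(sum(lens) + 11L * n_inst + 50L))
    cat_n <- repeat_catalog(rep("c1", n_inst), starts, starts + lens,
                            sample(c("+", "-"), n_inst, TRUE),
                            rep("f", n_inst))
    rg <- build_repeat_genome(g, cat_n)
    runs <- gregexpr("N+", rg$sequence)[[1]]
    expect_equal(length(runs), n_inst - 1L)
    expect_true(all(attr(runs, "match.length") == 5L))
    # concatenation invariant: dropping spacers reproduces the segment seqs
    parts <- strsplit(rg$sequence, "NNNNN", fixed = TRUE)[[1]]
    extract <- vapply(seq_len(n_inst), function(i) {
      s <- substr(g[[1]], cat_n$start[i] + 1L, cat_n$end[i])
      if (cat_n$strand[i] == "-") oracle_revcomp(s) else s
    }, character(1))
    expect_equal(parts, extract)
  }
})
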