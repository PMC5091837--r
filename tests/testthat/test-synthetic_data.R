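test_that("toy genomes are deterministic and annotated exactly", {
  t1 <- make_toy_genome(seed = 12, families = "sat", n_instances = 3,
                        instance_length = 200, background_length = 10000)
  t2 <- make_toy_genome(seed = 12, families = "sat", n_instances = 3,
                        instance_length = 200, background_length = 10000)
  expect_identical(t1$genome, t2$genome)
  expect_identical(as.data.frame(t1$catalog), as.data.frame(t2$catalog))
  expect_equal(nrow(t1$catalog), 3L)
  # embedded instances are >= 90% identical to the consensus (5% divergence)
  cons <- strsplit(t1$consensus[["sat"]], "")[[1]]
  for (i in seq_len(3)) {
    s <- substr(t1$genome[[1]], t1$catalog$start[i] + 1, t1$catalog$end[i])
    if (t1$catalog$strand[i] == "-") s <- oracle_revcomp(s)
    ident <- mean(strsplit(s, "")[[1]] == cons)
    expect_gte(ident, 0.9)
  }
})

test_that("zero instances give a pure background genome", {
  t0 <- make_toy_genome(seed = 2, families = character(0),
                        background_length = 5000)
  expect_equal(nrow(t0$catalog), 0L)
  expect_equal(nchar(t0$genome[[1]]), 5000L)
})

test_that("read simulation is byte-deterministic given the seed", {
  toy <- make_toy_genome(seed = 5, families = "sat", n_instances = 2,
                         instance_length = 150, background_length = 20000)
  s1 <- simulate_reads(toy$genome, toy$catalog, seed = 8, n_reads = 500)
  s2 <- simulate_reads(toy$genome, toy$catalog, seed = 8, n_reads = 500)
  expect_identical(s1$chip, s2$chip)
  expect_identical(s1$input, s2$input)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$chip, f1)
  write_fastq(s2$chip, f2)
  expect_identical(readLines(f1), readLines(f2))
  # FASTQ is readable by a standard parser and matches the in-memory reads
  back <- Biostrings::readDNAStringSet(f1, format = "fastq")
  expect_equal(as.character(back), s1$chip)
})

test_that("null enrichment gives matching chip/input family fractions", {
  toy <- make_toy_genome(seed = 31, families = "sat", n_instances = 3,
                         instance_length = 250, background_length = 50000)
  sim <- simulate_reads(toy$genome, toy$catalog, seed = 1, n_reads = 20000)
  frac <- function(lib) mean(sim$truth$family[sim$truth$library == lib] == "sat")
  p <- sum(toy$catalog$end - toy$catalog$start) / nchar(toy$genome[[1]])
  bound <- 3 * sqrt(p * (1 - p) / 20000)
  expect_lt(abs(frac("chip") - frac("input")), 2 * bound)
})

test_that("enriched family read share follows the closed-form expectation", {
  toy <- make_toy_genome(seed = 77, families = "sat", n_instances = 4,
                         instance_length = 250, background_length = 50000)
  sim <- simulate_reads(toy$genome, toy$catalog, seed = 2, n_reads = 50000,
                        enrichment = c(sat = 3))
  n_starts <- nchar(toy$genome[[1]]) - 36 + 1
  f <- sum(pmin(toy$catalog$end, n_starts) - toy$catalog$start) / n_starts
  expected <- 3 * f / (3 * f + (1 - f))
  obs <- mean(sim$truth$family[sim$truth$library == "chip"] == "sat")
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 50000))
})

test_that("truth table matches the reads it describes", {
  toy <- make_toy_genome(seed = 9, families = "sat", n_instances = 2,
                         instance_length = 100, background_length = 8000)
  sim <- simulate_reads(toy$genome, toy$catalog, seed = 3, n_reads = 200,
                        error_rate = 0)
  tr <- sim$truth[sim$truth$library == "input", ]
  for (i in sample(nrow(tr), 25)) {
    src <- substr(toy$genome[[1]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") src <- oracle_revcomp(src)
    expect_equal(unname(sim$input[tr$read_id[i]]), src)
  }
})

test_that("read simulation validates its inputs", {
  toy <- make_toy_genome(seed = 9, families = "sat", n_instances = 2,
                         instance_length = 100, background_length = 8000)
  expect_error(simulate_reads(toy$genome, toy$catalog, 1, read_length = 150),
               "shortest repeat instance")
  expect_error(simulate_reads(toy$genome, toy$catalog, 1, error_rate = 1),
               "error_rate")
  expect_error(simulate_reads(toy$genome, toy$catalog, 1,
                              enrichment = c(sat = -1)), "> 0")
  expect_error(simulate_reads(toy$genome, toy$catalog, 1,
                              enrichment = c(nope = 2)), "not in catalog")
})

test_that("nucleus images carry exact spot truth and are deterministic", {
  s1 <- simulate_nucleus_image(seed = 21, n_spots = 12, radii = 4)
  s2 <- simulate_nucleus_image(seed = 21, n_spots = 12, radii = 4)
  expect_identical(s1$image, s2$image)
  expect_equal(nrow(s1$truth), 12L)
  expect_equal(count_chromocentres(detect_spots(s1$image, s1$mask)), 12L)
  # 0 spots -> count 0; sub-threshold radii -> count 0 after the 2.75 filter
  s0 <- simulate_nucleus_image(seed = 1, n_spots = 0)
  expect_equal(count_chromocentres(detect_spots(s0$image, s0$mask)), 0L)
  s2px <- simulate_nucleus_image(seed = 2, n_spots = 8, radii = 2)
  expect_equal(count_chromocentres(detect_spots(s2px$image, s2px$mask)), 0L)
  expect_equal(nrow(detect_spots(s2px$image, s2px$mask)), 8L)
})

test_that("infeasible packing errors out after bounded retries", {
  expect_error(simulate_nucleus_image(seed = 1, n_spots = 60, radii = 10,
                                      image_size = c(80, 80), max_tries = 50),
               "infeasible")
})

test_that("Ct table simulation is deterministic and encodes the folds", {
  s1 <- simulate_ct_table(seed = 6, folds = c(MG132 = 10, ActD = 0.5))
  s2 <- simulate_ct_table(seed = 6, folds = c(MG132 = 10, ActD = 0.5))
  expect_identical(s1$table, s2$table)
  expect_setequal(unique(s1$table$condition), c("DMSO", "MG132", "ActD"))
  expect_error(simulate_ct_table(seed = 1, folds = c(MG132 = -2)), "> 0")
  expect_error(simulate_ct_table(seed = 1, folds = 3), "named")
  # fold-1 tables estimate close to 1
  s3 <- simulate_ct_table(seed = 7, folds = c(MG132 = 1))
  est <- relative_expression(s3$table, "major_sat", "spike", "MG132", "DMSO")
  expect_lt(abs(est$fold - 1), 0.3)
})
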