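# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# reverse complement, hand-rolled
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# exhaustive brute-force ungapped mismatch scan; N always mismatches.
# Returns the minimal mismatch count over all offsets and orientations and
# whether any offset is within budget.
oracle_align <- function(read, ref, max_mismatches) {
  code <- function(s) {
    v <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L  # N and anything else: code 0, never matches
    v
  }
  p <- code(read)
  prc <- code(oracle_revcomp(read))
  r <- code(ref)
  l <- length(p)
  noff <- length(r) - l + 1L
  if (noff < 1L) return(list(mapped = FALSE, mismatches = NA_integer_))
  # window matrix: row i = ref codes at offset+i-1
  win <- vapply(seq_len(l), function(i) r[i:(i + noff - 1L)],
                integer(noff))
  if (noff == 1L) win <- matrix(win, nrow = 1L)
  mm_of <- function(pat) {
    bad <- t(win) != pat | t(win) == 0L | pat == 0L
    colSums(bad)
  }
  best <- min(c(mm_of(p), mm_of(prc)))
  list(mapped = best <= max_mismatches, mismatches = as.integer(best))
}

# textbook Pearson chi-squared on a contingency table
oracle_chi2 <- function(tab) {
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic))
}

# coarse grid search minimising SSE of y = A exp(-k t)
oracle_decay_grid <- function(times, values,
                              a_grid = seq(0.5, 1.5, length.out = 60) *
                                max(values),
                              k_grid = seq(0, 2, length.out = 200)) {
  best <- list(sse = Inf)
  for (a in a_grid) for (k in k_grid) {
    sse <- sum((values - a * exp(-k * times))^2)
    if (sse < best$sse) best <- list(A = a, k = k, sse = sse)
  }
  best
}
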