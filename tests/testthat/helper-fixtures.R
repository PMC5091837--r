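# Small fixtures built in code at test time.

# a tiny genome with two exactly-known repeat instances on chr1
fixture_genome <- function() {
  c(chr1 = paste0(
    "TTTTTTTTTT",                     # 0-9 background
    "ACGTACGTACGTACGTACGT",           # 10-29 instance A1 (+)
    "GGGGGGGGGG",                     # 30-39 background
    "ACGTTGCAACGTTGCAACGT",           # 40-59 instance A2 (+)
    "CCCCCCCCCC"                      # 60-69 background
  ))
}

fixture_catalog <- function() {
  repeat_catalog(chrom = c("chr1", "chr1"), start = c(10L, 40L),
                 end = c(30L, 60L), strand = c("+", "+"),
                 family = c("satA", "satA"), repclass = c("Satellite", "Satellite"))
}

# rmsk_table dialect text for given instances (UCSC full 17-column layout)
fixture_rmsk_lines <- function(catalog) {
  vapply(seq_len(nrow(catalog)), function(i) {
    paste(c("0", "1000", "10", "0", "0", catalog$chrom[i], catalog$start[i],
            catalog$end[i], "-100", catalog$strand[i], catalog$family[i],
            catalog$repclass[i], catalog$repclass[i], "1",
            catalog$end[i] - catalog$start[i], "0", as.character(i)),
          collapse = "\t")
  }, character(1))
}

# RepeatMasker .out dialect text (1-based inclusive, strand C = minus)
fixture_rm_out_lines <- function(catalog) {
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  body <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c("1000", "5.0", "0.0", "0.0", catalog$chrom[i],
            catalog$start[i] + 1L, catalog$end[i],
            "(100)", if (catalog$strand[i] == "-") "C" else "+",
            catalog$family[i], catalog$repclass[i], "1",
            catalog$end[i] - catalog$start[i], "(0)", as.character(i)),
          collapse = "  ")
  }, character(1))
  c(header, body)
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
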