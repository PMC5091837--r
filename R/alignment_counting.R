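#' Align reads to a repeat genome with a naive ungapped aligner
#'
#' A deliberately simple internal aligner used to close the test loop without
#' an external aligner: a read maps iff some ungapped offset, in forward or
#' reverse-complement orientation, carries at most `max_mismatches`
#' mismatches. Every `N` in read or reference counts as a mismatch, so the
#' `NNNNN` spacers of a repeat genome guarantee that boundary-spanning reads
#' do not map when the spacer is longer than the mismatch budget. The best
#' hit has minimal mismatch count; ties are broken by smallest offset, then
#' forward orientation. The production route for real data remains any
#' SAM-emitting aligner (see [count_hits_sam()]).
#'
#' `method = "scan"` checks every offset exhaustively; `"seed"` uses a
#' pigeonhole seed index (`max_mismatches + 1` non-overlapping seeds, so every
#' alignment within the mismatch budget is still guaranteed to be found) and
#' gives identical results much faster on large read sets. `"auto"` (default)
#' uses seeds whenever the seed length is at least 8 nt and the read is
#' N-free, and falls back to the scan otherwise.
#'
#' @param reads Character vector of read sequences over `A,C,G,T,N`.
#' @param rg A `repeat_genome` (or a single reference sequence as a string).
#' @param max_mismatches Maximum tolerated mismatches (default 3).
#' @param method `"auto"`, `"seed"` or `"scan"`.
#'
#' @return Data frame with one row per read: `mapped` (logical), `offset`
#'   (0-based best offset or NA), `strand` (`"+"`/`"-"` or NA), `mismatches`.
#' @examples
#' rg <- list(sequence = "ACGTACGTACGTACGTACGT")
#' naive_align("ACGTACGT", rg$sequence, max_mismatches = 0)
#' @export
naive_align <- function(reads, rg, max_mismatches = 3L,
                        method = c("auto", "seed", "scan")) {
  method <- match.arg(method)
  ref <- if (inherits(rg, "repeat_genome")) rg$sequence else as.character(rg)
  reads <- toupper(as.character(reads))
  if (!length(reads)) stop("no reads supplied", call. = FALSE)
  if (any(!nzchar(reads))) stop("empty read sequence", call. = FALSE)
  if (any(grepl("[^ACGTN]", reads)))
    stop("reads contain characters outside {A,C,G,T,N}", call. = FALSE)
  if (max(nchar(reads)) > nchar(ref))
    stop("read length exceeds repeat genome length", call. = FALSE)
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  use_seed <- method %in% c("auto", "seed")
  min_seed <- if (method == "seed") 1L else 8L
  .cpp_align_reads(reads, ref, as.integer(max_mismatches), use_seed,
                   as.integer(min_seed))
}

#' Count reads hitting a repeat family
#'
#' A "hit" is a distinct read with at least one reported alignment to the
#' family's repeat genome; multi-mapping reads count once per family and
#' secondary/supplementary records never double-count a read.
#' `count_hits_reads()` runs the internal [naive_align()] path;
#' [count_hits_sam()] consumes alignments from any external aligner.
#'
#' @param reads Character vector of read sequences.
#' @param rg The family's `repeat_genome`.
#' @param max_mismatches,method Passed to [naive_align()].
#' @param family Family name; defaults to `rg$family`.
#'
#' @return A `hit_counts` object: list with `family`, `hits`, `total_reads`.
#' @export
count_hits_reads <- function(reads, rg, max_mismatches = 3L,
                             method = c("auto", "seed", "scan"),
                             family = NULL) {
  if (is.null(family))
    family <- if (inherits(rg, "repeat_genome")) rg$family else
      stop("supply 'family' when 'rg' is a bare sequence", call. = FALSE)
  aln <- naive_align(reads, rg, max_mismatches, method)
  hit_counts(family, sum(aln$mapped), length(reads))
}

#' @rdname count_hits_reads
#' @param x For the generic `count_hits()`: a SAM/BAM file path or a character
#'   vector of read sequences.
#' @param ... Passed on to the path-specific counter.
#' @export
count_hits <- function(x, ...) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(sam|bam)$", x, ignore.case = TRUE))
    count_hits_sam(x, ...)
  else count_hits_reads(x, ...)
}

#' Count hits from a SAM/BAM alignment stream
#'
#' @param path SAM or BAM file. Reference names must correspond to repeat
#'   genome families.
#' @param family Family to count; must match the reference name of the mapped
#'   records.
#' @param total_reads Library size. Required when the stream contains no
#'   unmapped records (the stream then cannot reveal how many reads were
#'   attempted); otherwise inferred as the number of distinct read ids.
#' @return A `hit_counts` object.
#' @export
count_hits_sam <- function(path, family, total_reads = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname"))
  )[[1L]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  primary <- bitwAnd(flag, bitwOr(0x100L, 0x800L)) == 0L
  mapped_rname <- unique(as.character(res$rname[!unmapped]))
  if (length(mapped_rname) && any(mapped_rname != family))
    stop("alignment reference name(s) ",
         paste(setdiff(mapped_rname, family), collapse = ", "),
         " do not match requested family '", family, "'", call. = FALSE)
  hits <- length(unique(res$qname[!unmapped]))
  n_ids <- length(unique(res$qname))
  if (is.null(total_reads)) {
    if (!any(unmapped & primary))
      stop("stream contains no unmapped records; supply 'total_reads' ",
           "explicitly", call. = FALSE)
    total_reads <- n_ids
  }
  hit_counts(family, hits, total_reads)
}

hit_counts <- function(family, hits, total_reads) {
  hits <- as.integer(hits); total_reads <- as.integer(total_reads)
  if (is.na(hits) || is.na(total_reads) || hits < 0L || hits > total_reads)
    stop("invalid hit counts: need 0 <= hits <= total_reads", call. = FALSE)
  structure(list(family = family, hits = hits, total_reads = total_reads),
            class = "hit_counts")
}

#' @export
print.hit_counts <- function(x, ...) {
  cat(sprintf("hit_counts '%s': %d / %d reads (%.3f%%)\n", x$family, x$hits,
              x$total_reads, 100 * x$hits / x$total_reads))
  invisible(x)
}

#' Write alignments produced by [naive_align()] as a SAM file
#'
#' Minimal single-reference SAM emitter, mainly for cross-checking the naive
#' alignment path against the SAM counting path.
#'
#' @param aln Data frame returned by [naive_align()].
#' @param reads The read sequences that were aligned.
#' @param rg The `repeat_genome` the reads were aligned to.
#' @param path Output SAM path.
#' @param read_ids Read names; default `read1..readN`.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, reads, rg, path,
                      read_ids = sprintf("read%d", seq_along(reads))) {
  stopifnot(inherits(rg, "repeat_genome"),
            nrow(aln) == length(reads), length(read_ids) == length(reads))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", rg$family, nchar(rg$sequence)))
  flag <- ifelse(!aln$mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
  pos <- ifelse(aln$mapped, aln$offset + 1L, 0L)
  rname <- ifelse(aln$mapped, rg$family, "*")
  cigar <- ifelse(aln$mapped, paste0(nchar(reads), "M"), "*")
  mapq <- ifelse(aln$mapped, 255L, 0L)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*", read_ids, flag,
                  rname, pos, mapq, cigar, reads)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' ChIP-vs-input fold enrichment for one repeat family
#'
#' Computes fold enrichment of a ChIP library over its input library for one
#' repeat family: `fold = (hits_chip / total_chip) / (hits_input /
#' total_input)` (library-size normalised, the default), or the raw hit ratio
#' `hits_chip / hits_input` with `normalize = "raw"` for pipelines that assume
#' equal library sizes. A 95% confidence interval comes from the normal
#' approximation on the log ratio of two binomial proportions:
#' `exp(log(fold) +/- 1.96 * sqrt(1/h_c - 1/T_c + 1/h_i - 1/T_i))`.
#'
#' @param chip,input `hit_counts` for the same family.
#' @param normalize `"library_size"` (default) or `"raw"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An `enrichment_result`: one-row data frame with `family`, `fold`,
#'   `ci_low`, `ci_high`, `hits_chip`, `total_chip`, `hits_input`,
#'   `total_input`, `undefined` (TRUE when `input$hits == 0`, in which case no
#'   numeric fold is reported).
#' @examples
#' enrichment(hc <- structure(list(family = "sat", hits = 120L,
#'                                 total_reads = 10000L), class = "hit_counts"),
#'            structure(list(family = "sat", hits = 100L,
#'                           total_reads = 10000L), class = "hit_counts"))
#' @export
enrichment <- function(chip, input, normalize = c("library_size", "raw"),
                       conf_level = 0.95) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(chip, "hit_counts"), inherits(input, "hit_counts"))
  if (!identical(chip$family, input$family))
    stop("mismatched families: '", chip$family, "' vs '", input$family, "'",
         call. = FALSE)
  if (chip$total_reads <= 0L || input$total_reads <= 0L)
    stop("zero total reads", call. = FALSE)
  res <- data.frame(family = chip$family, fold = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, hits_chip = chip$hits,
                    total_chip = chip$total_reads, hits_input = input$hits,
                    total_input = input$total_reads, undefined = FALSE,
                    stringsAsFactors = FALSE)
  if (input$hits == 0L) {
    res$undefined <- TRUE
  } else {
    res$fold <- if (normalize == "library_size")
      (chip$hits / chip$total_reads) / (input$hits / input$total_reads)
    else chip$hits / input$hits
    if (chip$hits > 0L) {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      se <- sqrt(1 / chip$hits - 1 / chip$total_reads +
                   1 / input$hits - 1 / input$total_reads)
      res$ci_low <- exp(log(res$fold) - z * se)
      res$ci_high <- exp(log(res$fold) + z * se)
    } else {
      res$fold <- 0
    }
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write per-family enrichment results as TSV
#'
#' @param results An `enrichment_result` (possibly several rows, e.g. from
#'   `rbind`ing per-family results).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(results, path) {
  cols <- c("family", "hits_chip", "total_chip", "hits_input", "total_input",
            "fold", "ci_low", "ci_high")
  utils::write.table(as.data.frame(results)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
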