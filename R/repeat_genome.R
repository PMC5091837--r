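#' Build a concatenated repeat genome for one repeat family
#'
#' Concatenates the genomic sequence of every annotated instance of one repeat
#' family into a single artificial reference ("repeat genome"), with
#' consecutive instances separated by an N spacer (default `"NNNNN"`) so that
#' reads cannot align across instance boundaries. Minus-strand instances are
#' reverse-complemented by default so that every segment reads in the repeat
#' consensus orientation.
#'
#' @param genome Genome sequence source: a named character vector, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param instances A [repeat_catalog()] (or data frame with the same columns)
#'   holding the instances of a single family.
#' @param spacer Spacer string inserted between segments; must be one or more
#'   `N`s. Default `"NNNNN"`.
#' @param strand_policy `"reverse_complement_minus"` (default): minus-strand
#'   instances are reverse complemented; `"as_plus"`: all instances are taken
#'   literally from the plus strand.
#' @param expected_read_length Optional read length of the sequencing data the
#'   reference is intended for; a warning is emitted when the spacer is
#'   shorter, since reads could then cross instance boundaries.
#'
#' @return A `repeat_genome` object: list with elements `family`, `sequence`
#'   (single character string over `A,C,G,T,N`), `spacer`, `strand_policy`
#'   and `segments`, a data frame with one row per segment
#'   (`offset_start`/`offset_end`, 0-based half-open positions in the repeat
#'   genome; `source` either `"instance"` or `"consensus"`; original
#'   `chrom`/`start`/`end`/`strand`; `name`).
#' @examples
#' g <- c(chr1 = "ACGTACGTACGTACGTACGT")
#' inst <- repeat_catalog(c("chr1", "chr1"), c(0, 10), c(4, 16),
#'                        c("+", "-"), c("sat", "sat"))
#' rg <- build_repeat_genome(g, inst)
#' rg$sequence
#' @export
build_repeat_genome <- function(genome, instances, spacer = "NNNNN",
                                strand_policy = c("reverse_complement_minus",
                                                  "as_plus"),
                                expected_read_length = NULL) {
  strand_policy <- match.arg(strand_policy)
  if (!grepl("^N+$", spacer))
    stop("spacer must consist only of N characters", call. = FALSE)
  validate_repeat_catalog(instances)
  if (nrow(instances) == 0L)
    stop("empty family: no instances to concatenate", call. = FALSE)
  fam <- unique(instances$family)
  if (length(fam) != 1L)
    stop("instances span multiple families: ", paste(fam, collapse = ", "),
         call. = FALSE)
  if (!is.null(expected_read_length) && nchar(spacer) < expected_read_length)
    warning("spacer (", nchar(spacer), " nt) is shorter than the expected ",
            "read length (", expected_read_length, " nt); reads could map ",
            "across instance boundaries", call. = FALSE)

  seqs <- as_genome_seqs(genome)
  segs <- character(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    chrom <- instances$chrom[i]
    if (!chrom %in% names(seqs))
      stop("chromosome not found in genome: ", chrom, call. = FALSE)
    chrom_len <- Biostrings::width(seqs[chrom])
    if (instances$end[i] > chrom_len)
      stop("instance exceeds chromosome bounds: ", chrom, ":",
           instances$start[i], "-", instances$end[i], " (length ",
           chrom_len, ")", call. = FALSE)
    s <- Biostrings::subseq(seqs[[chrom]], start = instances$start[i] + 1L,
                            end = instances$end[i])
    if (strand_policy == "reverse_complement_minus" &&
        instances$strand[i] == "-")
      s <- Biostrings::reverseComplement(s)
    segs[i] <- as.character(s)
  }

  seg_len <- nchar(segs)
  offset_start <- cumsum(c(0L, seg_len[-length(seg_len)] + nchar(spacer)))
  segments <- data.frame(
    offset_start = offset_start,
    offset_end = offset_start + seg_len,
    source = "instance",
    chrom = instances$chrom, start = instances$start, end = instances$end,
    strand = instances$strand,
    name = paste0(instances$chrom, ":", instances$start, "-", instances$end),
    stringsAsFactors = FALSE
  )
  rg <- structure(
    list(family = fam, sequence = paste(segs, collapse = spacer),
         spacer = spacer, strand_policy = strand_policy, segments = segments),
    class = "repeat_genome"
  )
  validate_repeat_genome(rg)
  rg
}

validate_repeat_genome <- function(rg) {
  stopifnot(inherits(rg, "repeat_genome"))
  segs <- rg$segments
  if (nrow(segs)) {
    stopifnot(all(segs$offset_start < segs$offset_end))
    if (nrow(segs) > 1L) {
      gaps <- segs$offset_start[-1L] - segs$offset_end[-nrow(segs)]
      stopifnot(all(gaps == nchar(rg$spacer)))
    }
    total <- sum(segs$offset_end - segs$offset_start) +
      nchar(rg$spacer) * (nrow(segs) - 1L)
    stopifnot(nchar(rg$sequence) == total)
  }
  if (nchar(rg$sequence) && grepl("[^ACGTN]", rg$sequence))
    stop("repeat genome contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  invisible(rg)
}

#' @export
print.repeat_genome <- function(x, ...) {
  cat(sprintf(
    "repeat_genome '%s': %d nt, %d segment(s) (%d instance, %d consensus), spacer '%s', strand policy %s\n",
    x$family, nchar(x$sequence), nrow(x$segments),
    sum(x$segments$source == "instance"),
    sum(x$segments$source == "consensus"), x$spacer, x$strand_policy))
  invisible(x)
}

#' Append a consensus sequence to a repeat genome
#'
#' Adds one extra segment holding a consensus sequence (e.g. the 120-nt minor
#' satellite consensus, [minor_satellite_consensus]), separated from the last
#' instance by one spacer.
#'
#' @param rg A `repeat_genome`.
#' @param name Label recorded for the new segment.
#' @param seq Consensus sequence, non-empty, over `A,C,G,T,N`.
#' @return The extended `repeat_genome`.
#' @export
add_consensus <- function(rg, name, seq) {
  stopifnot(inherits(rg, "repeat_genome"))
  seq <- toupper(as.character(seq))
  if (!nchar(seq)) stop("consensus sequence is empty", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("consensus contains characters outside {A,C,G,T,N}", call. = FALSE)
  empty <- nchar(rg$sequence) == 0L
  offset_start <- if (empty) 0L else nchar(rg$sequence) + nchar(rg$spacer)
  rg$sequence <- if (empty) seq else paste0(rg$sequence, rg$spacer, seq)
  rg$segments <- rbind(rg$segments, data.frame(
    offset_start = offset_start, offset_end = offset_start + nchar(seq),
    source = "consensus", chrom = NA_character_, start = NA_integer_,
    end = NA_integer_, strand = NA_character_, name = name,
    stringsAsFactors = FALSE
  ))
  validate_repeat_genome(rg)
  rg
}

#' Map a repeat-genome offset back to its source
#'
#' Inverts the concatenation: a 0-based offset in the repeat genome is mapped
#' either to the segment it falls in (with the within-segment position and,
#' for instance segments, the original genomic coordinate) or labelled
#' `"spacer"`.
#'
#' @param rg A `repeat_genome`.
#' @param offset Integer vector of 0-based offsets, each in
#'   `[0, nchar(rg$sequence))`.
#' @return Data frame with one row per offset: `offset`, `source` (`"instance"`,
#'   `"consensus"` or `"spacer"`), `name`, `within` (0-based position inside
#'   the segment, NA for spacers), `chrom`, `genomic_pos` (0-based genomic
#'   coordinate of the base, strand-aware; NA for spacers/consensus).
#' @export
map_offset <- function(rg, offset) {
  stopifnot(inherits(rg, "repeat_genome"))
  offset <- as.integer(offset)
  if (any(is.na(offset) | offset < 0L | offset >= nchar(rg$sequence)))
    stop("offset out of range [0, ", nchar(rg$sequence), ")", call. = FALSE)
  segs <- rg$segments
  # index of the last segment starting at or before the offset
  idx <- findInterval(offset, segs$offset_start)
  res <- data.frame(offset = offset, source = "spacer", name = NA_character_,
                    within = NA_integer_, chrom = NA_character_,
                    genomic_pos = NA_integer_, stringsAsFactors = FALSE)
  in_seg <- idx >= 1L & offset < segs$offset_end[pmax(idx, 1L)]
  if (any(in_seg)) {
    i <- idx[in_seg]
    res$source[in_seg] <- segs$source[i]
    res$name[in_seg] <- segs$name[i]
    within <- offset[in_seg] - segs$offset_start[i]
    res$within[in_seg] <- within
    inst <- segs$source[i] == "instance"
    if (any(inst)) {
      j <- i[inst]
      rc <- rg$strand_policy == "reverse_complement_minus" &
        segs$strand[j] == "-"
      gp <- ifelse(rc, segs$end[j] - 1L - within[inst],
                   segs$start[j] + within[inst])
      res$chrom[in_seg][inst] <- segs$chrom[j]
      res$genomic_pos[in_seg][inst] <- gp
    }
  }
  res
}

#' Write a repeat genome as FASTA plus a segments sidecar table
#'
#' Writes one FASTA record (id = family name, 60-column wrapping) and a
#' tab-separated sidecar table of segment offsets, so the construction can be
#' reloaded losslessly with [read_repeat_genome_fasta()].
#'
#' @param rg A `repeat_genome` with non-empty sequence.
#' @param path FASTA output path.
#' @param segments_path Sidecar TSV path; default `paste0(path, ".segments.tsv")`.
#' @return Invisibly, a list with both paths.
#' @export
write_repeat_genome_fasta <- function(rg, path,
                                      segments_path = paste0(path, ".segments.tsv")) {
  validate_repeat_genome(rg)
  if (!nchar(rg$sequence))
    stop("empty family: refusing to write an empty repeat genome",
         call. = FALSE)
  dss <- Biostrings::DNAStringSet(stats::setNames(rg$sequence, rg$family))
  Biostrings::writeXStringSet(dss, filepath = path, width = 60L)
  meta <- rg$segments
  meta$family <- rg$family
  meta$spacer <- rg$spacer
  meta$strand_policy <- rg$strand_policy
  utils::write.table(meta, segments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(list(fasta = path, segments = segments_path))
}

#' Read back a repeat genome written by [write_repeat_genome_fasta()]
#'
#' @param path FASTA path.
#' @param segments_path Sidecar TSV path.
#' @return A `repeat_genome`.
#' @export
read_repeat_genome_fasta <- function(path,
                                     segments_path = paste0(path, ".segments.tsv")) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) != 1L)
    stop("expected exactly one FASTA record (one repeat genome per family)",
         call. = FALSE)
  meta <- utils::read.delim(segments_path, stringsAsFactors = FALSE)
  rg <- structure(
    list(family = names(dss)[1L], sequence = as.character(dss[[1L]]),
         spacer = meta$spacer[1L], strand_policy = meta$strand_policy[1L],
         segments = meta[, c("offset_start", "offset_end", "source", "chrom",
                             "start", "end", "strand", "name")]),
    class = "repeat_genome"
  )
  validate_repeat_genome(rg)
  rg
}

# Normalize a genome argument to a DNAStringSet.
as_genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("character genome must be a named vector of sequences",
           call. = FALSE)
    return(Biostrings::DNAStringSet(genome))
  }
  stop("unsupported genome type: supply a DNAStringSet, a named character ",
       "vector, or a FASTA path", call. = FALSE)
}
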