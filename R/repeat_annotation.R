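#' Create a repeat catalog
#'
#' A repeat catalog is an ordered table of annotated repeat instances, one row
#' per genomic copy of a repeat element. Coordinates are 0-based half-open
#' throughout the package; conversion from 1-based dialects happens only at
#' parse/write boundaries.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions (`end > start`).
#' @param strand Character vector, each element `"+"` or `"-"`.
#' @param family Character vector of repeat names (UCSC `repName`), non-empty.
#' @param repclass Character vector of repeat class labels (UCSC `repClass`);
#'   defaults to `"Unknown"`.
#' @param genome_build Free-text label for the assembly the coordinates refer
#'   to.
#'
#' @return A `repeat_catalog`: a data frame with columns `chrom`, `start`,
#'   `end`, `strand`, `family`, `repclass` and a `genome_build` attribute.
#' @examples
#' repeat_catalog("chr1", 100, 220, "+", "minor_sat")
#' @export
repeat_catalog <- function(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           family = character(),
                           repclass = rep("Unknown", length(chrom)),
                           genome_build = "unknown") {
  cat_df <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    family = as.character(family), repclass = as.character(repclass),
    stringsAsFactors = FALSE
  )
  attr(cat_df, "genome_build") <- genome_build
  class(cat_df) <- c("repeat_catalog", "data.frame")
  validate_repeat_catalog(cat_df)
  cat_df
}

validate_repeat_catalog <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "strand", "family", "repclass")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("repeat catalog lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!(x$start >= 0L & x$start < x$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1L], call. = FALSE)
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand at row ", bad[1L], " (must be '+' or '-')", call. = FALSE)
  bad <- which(is.na(x$family) | x$family == "")
  if (length(bad))
    stop("empty repeat family name at row ", bad[1L], call. = FALSE)
  invisible(x)
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("repeat_catalog: %d instance(s), %d famil%s [build: %s]\n",
              nrow(x), length(unique(x$family)),
              if (length(unique(x$family)) == 1L) "y" else "ies",
              attr(x, "genome_build") %||% "unknown"))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Parse a repeat annotation file into a repeat catalog
#'
#' Two dialects are supported. `rmsk_table` is the UCSC Genome Browser
#' RepeatMasker track dump: tab-separated, `genoStart` 0-based half-open,
#' either the full 17-column `rmsk` layout (no header) or any tab table with a
#' header line naming at least `genoName`, `genoStart`, `genoEnd`, `strand`
#' and `repName`. `rm_out` is native RepeatMasker `.out` output:
#' whitespace-separated with 3 header lines, 1-based inclusive `begin`/`end`
#' and strand `C` meaning minus.
#'
#' @param path Path to the annotation file.
#' @param dialect `"rmsk_table"` or `"rm_out"`.
#' @param genome_build Label stored on the catalog.
#'
#' @return A [repeat_catalog()] in 0-based half-open coordinates, rows in file
#'   order.
#' @seealso [write_rmsk_table()], [group_by_family()]
#' @export
parse_repeat_annotation <- function(path,
                                    dialect = c("rmsk_table", "rm_out"),
                                    genome_build = "unknown") {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ",
                                               dialect[1L], call. = FALSE))
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  switch(dialect,
         rmsk_table = parse_rmsk_table(path, genome_build),
         rm_out = parse_rm_out(path, genome_build))
}

# UCSC rmsk full table layout (no header): positional columns.
.rmsk_cols <- c(bin = 1L, genoName = 6L, genoStart = 7L, genoEnd = 8L,
                strand = 10L, repName = 11L, repClass = 12L)

parse_rmsk_table <- function(path, genome_build) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines) || all(!nzchar(lines)))
    return(repeat_catalog(genome_build = genome_build))
  header_idx <- NULL
  first_fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- "genoStart" %in% first_fields
  if (has_header) {
    header <- first_fields
    body <- lines[-1L]
  } else {
    body <- lines
  }
  body <- body[nzchar(body)]
  if (!length(body)) return(repeat_catalog(genome_build = genome_build))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  line_no <- seq_along(body) + if (has_header) 1L else 0L

  get_col <- function(name) {
    if (has_header) {
      j <- match(name, header)
      if (is.na(j)) stop("rmsk_table header lacks column '", name, "'",
                         call. = FALSE)
    } else {
      if (any(nf < 12L))
        stop("malformed rmsk_table row at line ",
             line_no[which(nf < 12L)[1L]],
             " (expected >= 12 tab-separated fields)", call. = FALSE)
      j <- .rmsk_cols[[name]]
    }
    vapply(fields, function(f) if (j <= length(f)) f[[j]] else NA_character_,
           character(1))
  }

  chrom <- get_col("genoName")
  start_chr <- get_col("genoStart")
  end_chr <- get_col("genoEnd")
  strand <- get_col("strand")
  family <- get_col("repName")
  repclass <- tryCatch(get_col("repClass"), error = function(e) NULL)

  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | is.na(chrom) | is.na(family) |
                 !strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed rmsk_table row at line ", line_no[bad[1L]], call. = FALSE)
  repeat_catalog(chrom, start, end, strand, family,
                 repclass %||% rep("Unknown", length(chrom)),
                 genome_build = genome_build)
}

parse_rm_out <- function(path, genome_build) {
  lines <- readLines(path)
  # .out files carry 2 column-header lines plus a blank line; skip any leading
  # lines whose first token is not a numeric Smith-Waterman score.
  body <- lines[nzchar(trimws(lines))]
  is_data <- vapply(body, function(l) {
    tok <- strsplit(trimws(l), "[ \t]+")[[1L]][1L]
    !is.na(suppressWarnings(as.numeric(tok)))
  }, logical(1))
  first_data <- which(is_data)[1L]
  if (is.na(first_data)) return(repeat_catalog(genome_build = genome_build))
  body <- body[seq(first_data, length(body))]
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop("malformed rm_out row at line ", match(body[bad[1L]], lines),
         " (expected >= 11 whitespace-separated fields)", call. = FALSE)
  # fields: score div del ins query begin end (left) strand repName class/family ...
  chrom <- vapply(fields, `[[`, character(1), 5L)
  begin <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 6L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 7L)))
  strand_raw <- vapply(fields, `[[`, character(1), 9L)
  family <- vapply(fields, `[[`, character(1), 10L)
  repclass <- vapply(fields, `[[`, character(1), 11L)
  bad <- which(is.na(begin) | is.na(end) | !strand_raw %in% c("+", "C"))
  if (length(bad))
    stop("malformed rm_out row at line ", match(body[bad[1L]], lines),
         call. = FALSE)
  # 1-based inclusive -> 0-based half-open; strand 'C' (complement) -> '-'
  repeat_catalog(chrom, begin - 1L, end, ifelse(strand_raw == "C", "-", "+"),
                 family, repclass, genome_build = genome_build)
}

#' Write a repeat catalog in the UCSC rmsk table dialect
#'
#' Writes a tab-separated table with a header line (`genoName`, `genoStart`,
#' `genoEnd`, `strand`, `repName`, `repClass`), `genoStart` 0-based half-open
#' as in the UCSC dump. Re-parsing with
#' `parse_repeat_annotation(dialect = "rmsk_table")` reproduces the catalog
#' exactly.
#'
#' @param catalog A [repeat_catalog()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rmsk_table <- function(catalog, path) {
  validate_repeat_catalog(catalog)
  out <- data.frame(genoName = catalog$chrom, genoStart = catalog$start,
                    genoEnd = catalog$end, strand = catalog$strand,
                    repName = catalog$family, repClass = catalog$repclass)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Group catalog instances by repeat family
#'
#' Partitions a catalog into per-family instance tables. Family identity is
#' the repeat name (`repName`) by default; grouping at the repeat-class level
#' (`repClass`, e.g. to pool all LINE L1 copies) is available via `level`.
#'
#' @param catalog A [repeat_catalog()].
#' @param families Optional character vector restricting (and ordering) the
#'   returned groups. A requested family absent from the catalog is an error,
#'   not a silent empty group.
#' @param level `"family"` (repName, default) or `"repclass"`.
#'
#' @return Named list of `repeat_catalog` subsets, one per family, instances
#'   sorted by (`chrom`, `start`).
#' @examples
#' cat <- repeat_catalog(rep("chr1", 3), c(0, 50, 10), c(5, 60, 20),
#'                       rep("+", 3), c("A", "B", "A"))
#' lengths(group_by_family(cat))
#' @export
group_by_family <- function(catalog, families = NULL,
                            level = c("family", "repclass")) {
  validate_repeat_catalog(catalog)
  level <- match.arg(level)
  key <- catalog[[level]]
  observed <- unique(key)
  if (is.null(families)) {
    families <- observed
  } else {
    missing_fams <- setdiff(families, observed)
    if (length(missing_fams))
      stop("family not found in catalog: ",
           paste(missing_fams, collapse = ", "), call. = FALSE)
  }
  groups <- lapply(families, function(f) {
    g <- catalog[key == f, , drop = FALSE]
    g <- g[order(g$chrom, g$start), , drop = FALSE]
    rownames(g) <- NULL
    attr(g, "genome_build") <- attr(catalog, "genome_build")
    class(g) <- class(catalog)
    g
  })
  names(groups) <- families
  groups
}
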