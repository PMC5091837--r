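#' Generate a toy genome with embedded repeat-family instances
#'
#' Builds a random background chromosome and embeds, for each family, copies
#' of a random family consensus diverged by point substitutions, at recorded
#' non-overlapping positions and random strands (minus-strand instances are
#' embedded reverse-complemented). The matching annotation is returned as a
#' [repeat_catalog()], so every downstream stage can be checked against known
#' ground truth. The same seed reproduces the genome byte for byte.
#'
#' Defaults emulate the study conditions at desk scale: satellite-like
#' families each occupying a fraction of a percent of the toy genome, so the
#' fold-vs-input estimand of [enrichment()] is essentially the generative
#' enrichment factor (see the methods vignette).
#'
#' @param seed Integer seed; fixes every output byte.
#' @param families Character vector of family names.
#' @param n_instances Instances per family (recycled).
#' @param instance_length Consensus length range (single value or c(min, max));
#'   one length is drawn per family.
#' @param background_length Background genome length (nt).
#' @param divergence Per-base substitution probability applied to each
#'   instance copy (default 0.05).
#' @param chrom Chromosome name.
#'
#' @return List with `genome` (named character vector of length 1), `catalog`
#'   (a [repeat_catalog()]), `consensus` (named character vector per family)
#'   and `seed`.
#' @examples
#' toy <- make_toy_genome(seed = 1, families = "sat", n_instances = 3,
#'                        instance_length = 200, background_length = 10000)
#' nrow(toy$catalog)
#' @export
make_toy_genome <- function(seed, families = c("major_sat", "minor_sat"),
                            n_instances = 3L, instance_length = c(200L, 300L),
                            background_length = 240000L, divergence = 0.05,
                            chrom = "chrT") {
  stopifnot(length(families) >= 0, divergence >= 0, divergence < 1)
  n_instances <- rep_len(as.integer(n_instances), length(families))
  if (length(instance_length) == 1L)
    instance_length <- rep(instance_length, 2L)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    genome_chars <- sample(bases, background_length, replace = TRUE)
    consensus <- stats::setNames(vapply(seq_along(families), function(i) {
      lens <- seq(instance_length[1L], instance_length[2L])
      len <- lens[sample.int(length(lens), 1L)]
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }, character(1)), families)

    rows <- list()
    occupied <- integer(0)
    for (i in seq_along(families)) {
      cons <- strsplit(consensus[[i]], "")[[1L]]
      len <- length(cons)
      for (j in seq_len(n_instances[i])) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          s <- sample.int(background_length - len + 1L, 1L) - 1L  # 0-based
          span <- seq(s + 1L, s + len)
          if (!any(span %in% occupied)) {
            occupied <- c(occupied, span)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place instance without overlap; reduce instance ",
               "count/length or enlarge the background", call. = FALSE)
        inst <- cons
        mut <- which(stats::runif(len) < divergence)
        if (length(mut))
          inst[mut] <- vapply(inst[mut], function(b)
            sample(setdiff(bases, b), 1L), character(1))
        strand <- sample(c("+", "-"), 1L)
        embedded <- if (strand == "-") rev(chartr("ACGT", "TGCA", inst)) else inst
        genome_chars[span] <- embedded
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s + len, strand = strand,
          family = families[i], stringsAsFactors = FALSE)
      }
    }
    catalog <- if (length(rows)) {
      rows <- do.call(rbind, rows)
      repeat_catalog(rows$chrom, rows$start, rows$end, rows$strand,
                     rows$family, rep("Satellite", nrow(rows)),
                     genome_build = sprintf("toy(seed=%d)", seed))
    } else repeat_catalog(genome_build = sprintf("toy(seed=%d)", seed))
    list(genome = stats::setNames(paste(genome_chars, collapse = ""), chrom),
         catalog = catalog, consensus = consensus, seed = seed)
  })
}

#' Simulate ChIP and input read libraries with known enrichment
#'
#' Input reads start uniformly across the genome; ChIP reads start with the
#' weight of positions inside family-`f` instances multiplied by the
#' enrichment factor `e_f` and renormalised. Reads are drawn from either
#' strand, and i.i.d. per-base substitution errors are applied at
#' `error_rate`. The truth table records each read's source interval, strand
#' and originating family, which suffices to compute every downstream stage's
#' expected output in the noiseless limit.
#'
#' @param genome Named character vector with exactly one sequence (as produced
#'   by [make_toy_genome()]).
#' @param catalog The matching [repeat_catalog()].
#' @param seed Integer seed; same seed reproduces identical reads.
#' @param n_reads Reads per library (default 100000).
#' @param read_length Read length in nt (default 36).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param enrichment Named numeric vector of per-family ChIP enrichment
#'   factors `e_f` (> 0); families absent from the vector get 1.
#'
#' @return A list of class `read_simulation`: `chip` and `input` (named
#'   character vectors of read sequences, names = read ids), `truth` (data
#'   frame: `read_id`, `library`, `start` 0-based, `strand`, `family` of the
#'   start position or `"background"`), and the simulation parameters.
#' @export
simulate_reads <- function(genome, catalog, seed, n_reads = 100000L,
                           read_length = 36L, error_rate = 0.005,
                           enrichment = NULL) {
  stopifnot(length(genome) == 1L, !is.null(names(genome)))
  validate_repeat_catalog(catalog)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  L <- nchar(genome[[1L]])
  if (read_length > L) stop("read length exceeds genome length", call. = FALSE)
  if (nrow(catalog) && min(catalog$end - catalog$start) < read_length)
    stop("read length exceeds the shortest repeat instance", call. = FALSE)
  fams <- unique(catalog$family)
  e <- stats::setNames(rep(1, length(fams)), fams)
  if (!is.null(enrichment)) {
    if (any(enrichment <= 0)) stop("enrichment factors must be > 0", call. = FALSE)
    unknown <- setdiff(names(enrichment), fams)
    if (length(unknown))
      stop("enrichment names not in catalog: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    e[names(enrichment)] <- enrichment
  }

  # class of each valid 0-based start position: 0 = background, i = family i
  n_starts <- L - read_length + 1L
  class_of <- integer(n_starts)  # indices 1..n_starts represent starts 0..n_starts-1
  for (i in seq_along(fams)) {
    inst <- catalog[catalog$family == fams[i], , drop = FALSE]
    for (r in seq_len(nrow(inst))) {
      lo <- inst$start[r] + 1L
      hi <- min(inst$end[r], n_starts)
      if (lo <= hi) class_of[lo:hi] <- i
    }
  }
  starts_by_class <- split(0:(n_starts - 1L), class_of)

  with_seed(seed, {
    gen_lib <- function(weights, lib) {
      cls <- names(starts_by_class)
      w <- vapply(cls, function(cl) {
        length(starts_by_class[[cl]]) *
          (if (cl == "0") 1 else weights[fams[as.integer(cl)]])
      }, numeric(1))
      counts <- as.vector(stats::rmultinom(1L, n_reads, w / sum(w)))
      starts <- integer(0)
      for (ci in seq_along(cls)) {
        if (counts[ci] > 0L)
          starts <- c(starts, sample(starts_by_class[[cls[ci]]], counts[ci],
                                     replace = TRUE))
      }
      starts <- sample(starts)  # shuffle so read order carries no signal
      minus <- stats::runif(n_reads) < 0.5
      err <- which(stats::runif(n_reads * read_length) < error_rate)
      reads <- .cpp_make_reads(genome[[1L]], starts, minus, read_length,
                               (err - 1L) %/% read_length,
                               (err - 1L) %% read_length,
                               if (length(err))
                                 sample.int(3L, length(err), replace = TRUE)
                               else integer(0))
      ids <- sprintf("%s_%07d", lib, seq_len(n_reads))
      fam_of <- ifelse(class_of[starts + 1L] == 0L, "background",
                       fams[class_of[starts + 1L]])
      list(reads = stats::setNames(reads, ids),
           truth = data.frame(read_id = ids, library = lib, start = starts,
                              end = starts + read_length,
                              strand = ifelse(minus, "-", "+"),
                              family = fam_of, stringsAsFactors = FALSE))
    }
    input <- gen_lib(stats::setNames(rep(1, length(fams)), fams), "input")
    chip <- gen_lib(e, "chip")
    structure(list(chip = chip$reads, input = input$reads,
                   truth = rbind(chip$truth, input$truth),
                   params = list(seed = seed, n_reads = n_reads,
                                 read_length = read_length,
                                 error_rate = error_rate, enrichment = e)),
              class = "read_simulation")
  })
}

#' Write reads as FASTQ
#'
#' Plain four-line FASTQ with constant qualities; a sidecar
#' `<path>.spec.txt` records the generator parameters so files are
#' self-describing.
#'
#' @param reads Named character vector (names = read ids).
#' @param path Output path.
#' @param qual Quality character applied to every base.
#' @param spec Optional list of parameters recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, qual = "I", spec = NULL) {
  ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           strrep(qual, nchar(reads))))
  writeLines(lines, path)
  if (!is.null(spec))
    writeLines(paste(names(spec), vapply(spec, function(x)
      paste(format(x), collapse = ","), character(1)), sep = "\t"),
      paste0(path, ".spec.txt"))
  invisible(path)
}

#' Simulate a single-nucleus image with known bright spots
#'
#' Generates an elliptical nuclear mask over a dark field, a uniform nuclear
#' background with optional Gaussian noise, and bright spots at recorded
#' centres and radii (uniform-intensity disks by default, optionally
#' Gaussian-profiled). Spots are placed fully inside the mask with pairwise
#' centre distance at least `r_i + r_j + min_gap`; placement failure after
#' bounded retries is an error.
#'
#' @param seed Integer seed.
#' @param n_spots Number of spots.
#' @param radii Spot radii in pixels (scalar or length `n_spots`).
#' @param image_size `c(rows, cols)` (default 220 x 220).
#' @param nucleus_axes Ellipse semi-axes in pixels; default 42%/36% of size.
#' @param background Nuclear background intensity (default 50).
#' @param spot_intensity Spot plateau intensity (default 200).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param min_gap Minimum clearance between spot rims in pixels (default 8).
#' @param profile `"disk"` (uniform) or `"gaussian"`.
#' @param max_tries Placement retries per spot before failing.
#'
#' @return List with `image` (matrix), `mask` (logical matrix), `truth` (data
#'   frame `row`, `col`, `radius`) and `seed`.
#' @examples
#' sim <- simulate_nucleus_image(seed = 1, n_spots = 5, radii = 4)
#' count_chromocentres(detect_spots(sim$image, sim$mask))
#' @export
simulate_nucleus_image <- function(seed, n_spots, radii = 4,
                                   image_size = c(220L, 220L),
                                   nucleus_axes = NULL, background = 50,
                                   spot_intensity = 200, noise_sd = 0,
                                   min_gap = 8, profile = c("disk", "gaussian"),
                                   max_tries = 5000L) {
  profile <- match.arg(profile)
  stopifnot(n_spots >= 0, all(radii > 0), background >= 0, noise_sd >= 0)
  radii <- rep_len(radii, max(n_spots, 1L))[seq_len(n_spots)]
  nr <- image_size[1L]; nc <- image_size[2L]
  ax <- nucleus_axes %||% c(0.42 * nr, 0.36 * nc)
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((rr - r0) / ax[1L])^2 + ((cc - c0) / ax[2L])^2 <= 1

  with_seed(seed, {
    centres <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(n_spots)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # integer-pixel centres so each generated radius has a well-defined
        # discrete disk area (truth would otherwise wobble with subpixel phase)
        cand <- c(sample.int(nr, 1L), sample.int(nc, 1L))
        # spot (plus a 2 px halo for smoothing) must sit inside the nucleus
        margin <- radii[i] + 2
        inside <- ((cand[1L] - r0) / (ax[1L] - margin))^2 +
          ((cand[2L] - c0) / (ax[2L] - margin))^2 <= 1
        if (!inside) next
        if (nrow(centres)) {
          d <- sqrt((centres[, 1L] - cand[1L])^2 + (centres[, 2L] - cand[2L])^2)
          if (any(d < radii[i] + radii[seq_len(nrow(centres))] + min_gap)) next
        }
        centres <- rbind(centres, cand)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("infeasible spot packing: could not place spot ", i, " after ",
             max_tries, " tries", call. = FALSE)
    }

    img <- matrix(0, nr, nc)
    img[mask] <- background
    for (i in seq_len(n_spots)) {
      d2 <- (rr - centres[i, 1L])^2 + (cc - centres[i, 2L])^2
      if (profile == "disk") {
        img[d2 <= radii[i]^2] <- spot_intensity
      } else {
        amp <- (spot_intensity - background) * exp(-d2 / (2 * (radii[i] / 2)^2))
        sel <- d2 <= (3 * radii[i])^2
        img[sel] <- pmax(img[sel], background + amp[sel])
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)

    truth <- if (n_spots > 0L)
      data.frame(row = centres[, 1L], col = centres[, 2L], radius = radii)
    else data.frame(row = numeric(), col = numeric(), radius = numeric())
    list(image = img, mask = mask, truth = truth, seed = seed)
  })
}

#' Simulate a long-format qPCR Ct table with known fold changes
#'
#' Reference Ct values are Normal(`reference_ct`, `ct_sd`) in every condition;
#' target Ct values in the vehicle are Normal(`target_vehicle_ct`, `ct_sd`),
#' and in each treatment condition the target Ct is shifted down by
#' `log_efficiency(fold)` cycles plus noise, so [relative_expression()]
#' recovers the folds exactly in the noiseless limit.
#'
#' @param seed Integer seed.
#' @param folds Named numeric vector of true fold changes (> 0), one per
#'   treatment condition (e.g. `c(MG132 = 10)`).
#' @param target,reference Target and reference (spike/housekeeping) names.
#' @param vehicle Vehicle condition label.
#' @param n_replicates Replicates per condition/target (default 6).
#' @param ct_sd Gaussian Ct noise SD in cycles (default 0.1).
#' @param reference_ct,target_vehicle_ct Mean Ct levels.
#' @param efficiency Amplification efficiency base (default 2).
#'
#' @return List with `table` (a Ct table, see [read_ct_table()]) and `truth`
#'   (the fold vector).
#' @export
simulate_ct_table <- function(seed, folds = c(MG132 = 10),
                              target = "major_sat", reference = "spike",
                              vehicle = "DMSO", n_replicates = 6L,
                              ct_sd = 0.1, reference_ct = 20,
                              target_vehicle_ct = 25, efficiency = 2) {
  if (any(folds <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (is.null(names(folds)) || any(!nzchar(names(folds))))
    stop("'folds' must be named by condition", call. = FALSE)
  conditions <- c(vehicle, names(folds))
  shift <- c(0, log(folds, base = efficiency))
  with_seed(seed, {
    rows <- lapply(seq_along(conditions), function(i) {
      reps <- seq_len(n_replicates)
      data.frame(
        sample = paste(conditions[i], reps, sep = "_"),
        condition = conditions[i],
        target = rep(c(target, reference), each = n_replicates),
        replicate = rep(reps, 2L),
        ct = c(target_vehicle_ct - shift[i] + stats::rnorm(n_replicates, 0, ct_sd),
               reference_ct + stats::rnorm(n_replicates, 0, ct_sd)),
        stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = validate_ct_table(tab), truth = folds, seed = seed)
  })
}
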