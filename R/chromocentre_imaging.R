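#' Spot detection parameters
#'
#' Parameters of the deterministic chromocentre spot-detection pipeline. The
#' only value fixed by the assay convention is the 2.75-pixel equivalent-radius
#' cutoff applied downstream by [count_chromocentres()]; smoothing, background
#' statistic and threshold factor are configurable design choices.
#'
#' @param smooth_sigma Gaussian blur width in pixels (>= 0; 0 disables).
#' @param background_factor Multiplicative threshold over the per-nucleus
#'   background (> 1).
#' @param min_radius Equivalent-radius cutoff in pixels (> 0).
#' @param background_stat Background statistic within the nuclear mask.
#' @param size_from How spot area is measured: `"half_max"` (default) takes,
#'   within each thresholded component, the pixels above half way between
#'   background and the component's peak (FWHM convention, nearly unbiased for
#'   disk radius after smoothing); `"threshold"` uses the raw component.
#' @return A `spot_detection_params` list.
#' @export
spot_detection_params <- function(smooth_sigma = 1.0, background_factor = 1.3,
                                  min_radius = 2.75,
                                  background_stat = c("median", "mean"),
                                  size_from = c("half_max", "threshold")) {
  background_stat <- match.arg(background_stat)
  size_from <- match.arg(size_from)
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0", call. = FALSE)
  if (background_factor <= 1) stop("background_factor must be > 1", call. = FALSE)
  if (min_radius <= 0) stop("min_radius must be > 0", call. = FALSE)
  structure(list(smooth_sigma = smooth_sigma,
                 background_factor = background_factor,
                 min_radius = min_radius, background_stat = background_stat,
                 size_from = size_from),
            class = "spot_detection_params")
}

#' Detect bright spots in a single-nucleus image
#'
#' Deterministic pipeline for DRAQ5/DAPI-dense chromocentre spots: Gaussian
#' smoothing, per-nucleus background estimation (median or mean inside the
#' nuclear mask), thresholding at `background * background_factor` restricted
#' to the mask, 8-connected component labeling, and one spot per component.
#' Spot size is measured on the half-maximum contour within each component by
#' default (see [spot_detection_params()]); the equivalent radius is
#' `sqrt(area / pi)`.
#'
#' @param image 2-D numeric matrix (grayscale intensities).
#' @param mask Binary/logical matrix of the same shape marking nuclear pixels;
#'   when NULL, an Otsu threshold on the whole image is used.
#' @param params A [spot_detection_params()].
#' @return Data frame with one row per spot: `row`, `col` (centroid, pixels),
#'   `area` (px^2), `equiv_radius` (px), `mean_intensity`.
#' @examples
#' img <- matrix(50, 40, 40)
#' img[15:19, 15:19] <- 200
#' detect_spots(img, mask = matrix(TRUE, 40, 40))
#' @export
detect_spots <- function(image, mask = NULL,
                         params = spot_detection_params()) {
  image <- as.matrix(image)
  if (!is.numeric(image) || length(dim(image)) != 2L)
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  if (is.null(mask)) {
    rng <- range(image)
    if (rng[2] > rng[1]) {
      norm <- (image - rng[1]) / (rng[2] - rng[1])
      mask <- norm > EBImage::otsu(EBImage::Image(norm))
    } else {
      mask <- matrix(TRUE, nrow(image), ncol(image))
    }
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(image)))
    stop("image and mask must have the same shape", call. = FALSE)
  if (!any(mask)) stop("empty nuclear mask", call. = FALSE)

  smoothed <- if (params$smooth_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(image),
                             sigma = params$smooth_sigma))
  else image

  bg <- switch(params$background_stat,
               median = stats::median(smoothed[mask]),
               mean = mean(smoothed[mask]))
  binary <- (smoothed > bg * params$background_factor) & mask
  labels <- .cpp_label8(binary)
  n <- max(labels)
  if (n == 0L)
    return(data.frame(row = numeric(), col = numeric(), area = numeric(),
                      equiv_radius = numeric(), mean_intensity = numeric()))

  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(image) + 1L
  cols <- (idx - 1L) %/% nrow(image) + 1L
  sm <- smoothed[idx]
  keep <- rep(TRUE, length(idx))
  if (params$size_from == "half_max") {
    peak <- vapply(split(sm, lab), max, numeric(1))
    level <- bg + 0.5 * (peak[as.character(lab)] - bg)
    keep <- sm >= level
  }
  lab_k <- lab[keep]
  area <- as.numeric(table(lab_k))
  spots <- data.frame(
    row = as.numeric(tapply(rows[keep], lab_k, mean)),
    col = as.numeric(tapply(cols[keep], lab_k, mean)),
    area = area,
    equiv_radius = sqrt(area / pi),
    mean_intensity = as.numeric(tapply(image[idx][keep], lab_k, mean))
  )
  rownames(spots) <- NULL
  spots
}

#' Count chromocentres from detected spots
#'
#' A spot counts as a chromocentre when its equivalent radius is strictly
#' greater than `min_radius` (2.75 pixels by convention).
#'
#' @param spots Data frame from [detect_spots()].
#' @param min_radius Radius cutoff in pixels (>= 0).
#' @return Integer count.
#' @examples
#' count_chromocentres(data.frame(equiv_radius = c(5, 3, 2)))
#' @export
count_chromocentres <- function(spots, min_radius = 2.75) {
  if (!is.numeric(min_radius) || length(min_radius) != 1L ||
      is.na(min_radius) || min_radius < 0)
    stop("min_radius must be a single non-negative number", call. = FALSE)
  if (!nrow(spots)) return(0L)
  sum(spots$equiv_radius > min_radius)
}

#' Pearson chi-squared statistic for a contingency table
#'
#' Plain Pearson statistic (no continuity correction) with
#' `df = (nrow - 1) * (ncol - 1)`.
#'
#' @param tab Numeric matrix of counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chi2(rbind(A = c(70, 30), B = c(30, 70)))$statistic  # 32
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Compare two per-cell chromocentre count distributions
#'
#' Bins the per-cell counts of two conditions by chromocentre number, pools
#' bins from the tail until every expected cell of the 2 x k contingency table
#' is at least `pool_min_expected` (Cochran's rule), and applies the Pearson
#' chi-squared test with `df = k - 1`.
#'
#' @param a,b Non-negative integer vectors of per-cell chromocentre counts
#'   (one element per cell), or `count_distribution` objects.
#' @param pool_min_expected Minimum expected cell count after pooling.
#' @return List with `statistic`, `df`, `p_value`, `table` (the pooled 2 x k
#'   table) and the condition labels.
#' @examples
#' compare_distributions(rpois(200, 12), rpois(200, 15))$p_value
#' @export
compare_distributions <- function(a, b, pool_min_expected = 5) {
  lab_a <- attr(a, "condition") %||% "A"
  lab_b <- attr(b, "condition") %||% "B"
  a <- as.integer(a); b <- as.integer(b)
  if (!length(a) || !length(b))
    stop("both count distributions must be non-empty", call. = FALSE)
  if (any(a < 0) || any(b < 0))
    stop("chromocentre counts must be >= 0", call. = FALSE)
  kmax <- max(a, b)
  tab <- rbind(tabulate(a + 1L, nbins = kmax + 1L),
               tabulate(b + 1L, nbins = kmax + 1L))
  rownames(tab) <- c(lab_a, lab_b)
  colnames(tab) <- as.character(0:kmax)
  # drop all-zero bins, then pool sparse bins inward from both extremes of
  # the count histogram until Cochran's rule holds (per-cell chromocentre
  # histograms are sparse at both ends, so tail-only pooling would degenerate)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  expected_tab <- function(x) outer(rowSums(x), colSums(x)) / sum(x)
  while (ncol(tab) > 2L && any(expected_tab(tab) < pool_min_expected)) {
    k <- ncol(tab)
    exp_now <- expected_tab(tab)
    merge_head <- min(exp_now[, 1L]) <= min(exp_now[, k])
    if (merge_head) {
      tab[, 2L] <- tab[, 1L] + tab[, 2L]
      colnames(tab)[2L] <- paste0("<=", sub("^<=", "", colnames(tab)[2L]))
      tab <- tab[, -1L, drop = FALSE]
    } else {
      tab[, k - 1L] <- tab[, k - 1L] + tab[, k]
      colnames(tab)[k - 1L] <- paste0(">=", sub("^>=", "", colnames(tab)[k - 1L]))
      tab <- tab[, -k, drop = FALSE]
    }
  }
  if (ncol(tab) < 2L)
    stop("degenerate table: fewer than 2 bins after pooling", call. = FALSE)
  res <- pearson_chi2(tab)
  list(statistic = res$statistic, df = res$df, p_value = res$p_value,
       table = tab, conditions = c(lab_a, lab_b))
}

#' Label a vector of per-cell counts with its condition
#'
#' @param condition Condition label.
#' @param counts Non-negative integer per-cell chromocentre counts.
#' @return The counts with a `condition` attribute (class
#'   `count_distribution`).
#' @export
count_distribution <- function(condition, counts) {
  counts <- as.integer(counts)
  if (any(is.na(counts) | counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(counts, condition = condition, class = "count_distribution")
}

#' Read a grayscale nucleus image (TIFF/PNG)
#'
#' @param path Image path; multi-channel images are averaged to grayscale.
#' @return Numeric matrix of intensities.
#' @export
read_nucleus_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- if (length(d) == 2L) EBImage::imageData(img)
  else apply(EBImage::imageData(img), c(1L, 2L), mean)
  as.matrix(m)
}

#' Per-cell chromocentre counts for a set of nucleus images
#'
#' Convenience wrapper running [detect_spots()] and [count_chromocentres()]
#' over a list of images (and optional matching masks).
#'
#' @param images List of image matrices, or character vector of image paths.
#' @param masks Optional list of mask matrices (or mask image paths), matched
#'   by position.
#' @param params A [spot_detection_params()].
#' @return Data frame with `cell_id`, `n_spots`, `n_chromocentres`.
#' @export
chromocentre_counts <- function(images, masks = NULL,
                                params = spot_detection_params()) {
  if (is.character(images)) {
    ids <- basename(images)
    images <- lapply(images, read_nucleus_image)
  } else {
    ids <- names(images) %||% sprintf("cell%d", seq_along(images))
  }
  if (is.character(masks))
    masks <- lapply(masks, function(p) read_nucleus_image(p) > 0)
  res <- lapply(seq_along(images), function(i) {
    m <- if (is.null(masks)) NULL else masks[[i]]
    spots <- detect_spots(images[[i]], m, params)
    data.frame(cell_id = ids[i], n_spots = nrow(spots),
               n_chromocentres = count_chromocentres(spots, params$min_radius))
  })
  do.call(rbind, res)
}
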