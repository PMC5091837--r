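#' Read and write long-format qPCR Ct tables
#'
#' A Ct table is a long-format data frame with columns `sample`, `condition`,
#' `target`, `replicate` and `ct` (threshold cycles, finite and positive).
#'
#' @param path CSV path.
#' @return `read_ct_table()`: a validated data frame; `write_ct_table()`:
#'   invisibly, `path`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

#' @rdname read_ct_table
#' @param ct A Ct table data frame.
#' @export
write_ct_table <- function(ct, path) {
  validate_ct_table(ct)
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_ct_table <- function(ct) {
  need <- c("sample", "condition", "target", "replicate", "ct")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols))
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  ct
}

ct_series <- function(ct, condition, target) {
  rows <- ct$condition == condition & ct$target == target
  if (!any(rows))
    stop("Ct table has no rows for condition '", condition, "', target '",
         target, "'", call. = FALSE)
  ct[rows, , drop = FALSE]
}

#' Relative expression by the ddCt method
#'
#' Classic comparative-Ct quantification: per replicate,
#' `dCt = Ct_target - Ct_reference` (replicates paired by replicate index);
#' the fold change of `condition` over `vehicle` is
#' `efficiency^-(mean dCt_condition - mean dCt_vehicle)`, i.e. the geometric
#' mean of the per-replicate folds, so that vehicle-vs-vehicle is exactly 1.
#' Spike-in normalisation is the same computation with the spiked RNA as the
#' reference target. Per-replicate folds (each normalised to the mean vehicle
#' dCt) and their SEM are reported alongside, matching the mean +/- SEM of
#' biological replicates convention.
#'
#' @param ct A Ct table (see [read_ct_table()]).
#' @param target Target gene/repeat name (e.g. `"major_sat"`).
#' @param reference Reference target (housekeeping gene or spiked RNA).
#' @param condition Treatment condition label (e.g. `"MG132"`).
#' @param vehicle Vehicle condition label (e.g. `"DMSO"`).
#' @param efficiency Amplification efficiency base; 2.0 = perfect doubling.
#'
#' @return List with `fold` (point estimate), `sem` (SEM of per-replicate
#'   folds), `n` (replicates in the condition), `per_replicate` folds.
#' @examples
#' ct <- simulate_ct_table(seed = 1, folds = c(MG132 = 10))
#' relative_expression(ct$table, "major_sat", "spike", "MG132", "DMSO")$fold
#' @export
relative_expression <- function(ct, target, reference, condition, vehicle,
                                efficiency = 2.0) {
  validate_ct_table(ct)
  if (efficiency <= 1) stop("efficiency must be > 1", call. = FALSE)
  dct <- function(cond) {
    tg <- ct_series(ct, cond, target)
    rf <- ct_series(ct, cond, reference)
    m <- merge(tg[, c("replicate", "ct")], rf[, c("replicate", "ct")],
               by = "replicate", suffixes = c("_target", "_ref"))
    if (!nrow(m))
      stop("no replicate indices shared between target and reference in ",
           "condition '", cond, "'", call. = FALSE)
    stats::setNames(m$ct_target - m$ct_ref, m$replicate)
  }
  dct_cond <- dct(condition)
  dct_veh <- dct(vehicle)
  ddct <- dct_cond - mean(dct_veh)
  per_rep <- efficiency^(-ddct)
  fold <- efficiency^(-(mean(dct_cond) - mean(dct_veh)))
  list(fold = fold,
       sem = if (length(per_rep) > 1L)
         stats::sd(per_rep) / sqrt(length(per_rep)) else NA_real_,
       n = length(per_rep), per_replicate = per_rep)
}

#' Percent-of-input ChIP-qPCR enrichment
#'
#' Converts ChIP and input Ct values to the percent-input scale: the input Ct
#' is first adjusted for the input dilution
#' (`Ct' = ct_input - log_efficiency(1 / input_fraction)`), then
#' `percent = 100 * efficiency^(Ct' - ct_chip)`. When a background Ct (e.g. a
#' no-antibody control) is given, its percent-input value is subtracted on the
#' percent scale and the result is floored at 0.
#'
#' @param ct_chip,ct_input Numeric Ct values (vectors recycle).
#' @param input_fraction Fraction of chromatin used as input, in `(0, 1]`.
#' @param ct_background Optional background (no-antibody) Ct values.
#' @param efficiency Amplification efficiency base (default 2.0).
#' @return Numeric vector of percent-input values.
#' @examples
#' percent_input(ct_chip = 26, ct_input = 25, input_fraction = 0.5)
#' @export
percent_input <- function(ct_chip, ct_input, input_fraction,
                          ct_background = NULL, efficiency = 2.0) {
  if (!is.numeric(input_fraction) || length(input_fraction) != 1L ||
      is.na(input_fraction) || input_fraction <= 0 || input_fraction > 1)
    stop("input_fraction must be a single value in (0, 1]", call. = FALSE)
  if (efficiency <= 1) stop("efficiency must be > 1", call. = FALSE)
  ct_adj <- ct_input - log(1 / input_fraction, base = efficiency)
  pct <- 100 * efficiency^(ct_adj - ct_chip)
  if (!is.null(ct_background)) {
    pct_bg <- 100 * efficiency^(ct_adj - ct_background)
    pct <- pmax(pct - pct_bg, 0)
  }
  pct
}

#' Histone-mark enrichment relative to H3
#'
#' Ratio of a mark's percent-input enrichment to total-H3 percent-input
#' enrichment (both typically already background-subtracted).
#'
#' @param percent_mark,percent_h3 Percent-input values (vectors recycle).
#' @return Data frame with `ratio` and `undefined` (TRUE where
#'   `percent_h3 == 0`; the ratio is then NA).
#' @export
relative_to_h3 <- function(percent_mark, percent_h3) {
  if (any(percent_h3 < 0, na.rm = TRUE))
    stop("percent_h3 must be >= 0", call. = FALSE)
  undefined <- percent_h3 == 0
  ratio <- ifelse(undefined, NA_real_, percent_mark / percent_h3)
  data.frame(ratio = ratio, undefined = undefined)
}

#' Fit an exponential decay to expression time courses
#'
#' Nonlinear least-squares fit of `y = A * exp(-k * t)` (plus a plateau `C`
#' when `with_plateau = TRUE`) to relative-expression values over time, as
#' used for transcript decay after transcription inhibition. Starting values
#' are `A = y` at the earliest time, `k` from a log-linear regression, and
#' `C = min(y)`; the fit is by Levenberg-Marquardt with 1e-8 parameter
#' tolerance, with `k` constrained to be non-negative.
#'
#' @param times Numeric vector of times (hours).
#' @param values Positive expression values, same length.
#' @param with_plateau Fit the 3-parameter variant with plateau `C`.
#' @return A `decay_fit`: list with `A`, `k` (per hour), `C` (NA unless
#'   fitted), `half_life` (`log(2)/k`, hours), `rss`, `no_decay` (TRUE when
#'   `k` is pinned at 0), `fitted`.
#' @examples
#' t <- c(0, 1, 2, 4, 8)
#' fit_exponential_decay(t, 100 * exp(-0.5 * t))$half_life
#' @export
fit_exponential_decay <- function(times, values, with_plateau = FALSE) {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 3L)
    stop("need at least 3 distinct time points", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be finite and > 0", call. = FALSE)
  df <- data.frame(t = as.numeric(times), y = as.numeric(values))

  slope <- unname(stats::coef(stats::lm(log(y) ~ t, data = df))[2L])
  k0 <- max(-slope, 1e-6)
  a0 <- mean(df$y[df$t == min(df$t)])
  ctrl <- minpack.lm::nls.lm.control(ptol = 1e-8, ftol = 1e-8, maxiter = 500)

  fit <- tryCatch({
    if (with_plateau) {
      c0 <- min(df$y)
      minpack.lm::nlsLM(y ~ A * exp(-k * t) + C, data = df,
                        start = list(A = max(a0 - c0, a0 * 0.1), k = k0, C = c0),
                        lower = c(A = 0, k = 0, C = 0), control = ctrl)
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-k * t), data = df,
                        start = list(A = a0, k = k0),
                        lower = c(A = 0, k = 0), control = ctrl)
    }
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    # degenerate inputs (e.g. constant data) can defeat the optimizer; report
    # the log-linear initial iterate rather than failing outright
    if (abs(slope) < 1e-8) {
      a_hat <- mean(df$y)
      out <- decay_fit(a_hat, 0, if (with_plateau) 0 else NA_real_,
                       sum((df$y - a_hat)^2), rep(a_hat, nrow(df)))
      return(out)
    }
    stop("decay fit did not converge (last iterate: A=", signif(a0, 4),
         ", k=", signif(k0, 4), "): ", conditionMessage(fit), call. = FALSE)
  }
  cf <- stats::coef(fit)
  decay_fit(unname(cf["A"]), unname(cf["k"]),
            if (with_plateau) unname(cf["C"]) else NA_real_,
            sum(stats::residuals(fit)^2), stats::fitted(fit))
}

decay_fit <- function(A, k, C, rss, fitted) {
  structure(list(A = A, k = k, C = C,
                 half_life = if (k > 0) log(2) / k else Inf,
                 rss = rss, no_decay = k <= 1e-10, fitted = as.numeric(fitted)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$no_decay) {
    cat(sprintf("decay_fit: no decay (k = 0), A = %.4g, RSS = %.4g\n",
                x$A, x$rss))
  } else {
    cat(sprintf("decay_fit: A = %.4g, k = %.4g /h, half-life = %.4g h%s, RSS = %.4g\n",
                x$A, x$k, x$half_life,
                if (is.na(x$C)) "" else sprintf(", plateau C = %.4g", x$C),
                x$rss))
  }
  invisible(x)
}
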