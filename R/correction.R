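#' Flag usable bins for copy-number analysis
#'
#' A bin is unusable if it is blacklisted, its mappability is below
#' `min_mappability`, or its count is zero across the whole cohort (a proxy
#' for unalignable sequence).
#'
#' @param counts integer vector (one sample) or matrix (bins x samples).
#' @param bins bin annotation table from [make_genome()] or [read_bins()].
#' @param min_mappability bins below this mappability are dropped
#'   (default 0.8).
#' @return logical vector, TRUE for usable bins.
#' @export
filter_bins <- function(counts, bins, min_mappability = 0.8) {
  counts <- as.matrix(counts)
  validate_bins(bins)
  if (nrow(counts) != nrow(bins)) {
    stop_field("counts (%d rows) do not align to bins (%d rows)",
               nrow(counts), nrow(bins))
  }
  !bins$blacklisted &
    bins$mappability >= min_mappability &
    rowSums(counts) > 0
}

#' Simultaneous GC/mappability loess correction of bin counts
#'
#' Removes technical depth bias by alternating one-dimensional local
#' regressions of the log-scale counts on GC content and on mappability
#' (`iterations` rounds each). The combined fitted bias is normalized to mean
#' 1 over usable bins and divided out, so corrected counts keep the raw
#' scale. A covariate that is (near-)constant is skipped with a warning.
#'
#' @param counts integer/numeric vector of raw counts for one sample.
#' @param bins bin annotation table.
#' @param usable logical mask from [filter_bins()]; only usable bins enter the
#'   fit and only they are corrected (others pass through untouched).
#' @param span loess span in (0, 1], default 0.65.
#' @param iterations alternating rounds, default 2.
#' @return numeric vector of corrected counts, same length as `counts`.
#' @export
loess_correct <- function(counts, bins, usable = NULL, span = 0.65,
                          iterations = 2L) {
  validate_bins(bins)
  if (length(counts) != nrow(bins)) stop_field("counts do not align to bins")
  if (span <= 0 || span > 1) stop_field("'span' must be in (0,1]")
  if (is.null(usable)) usable <- filter_bins(counts, bins)
  idx <- which(usable & counts > 0)
  if (length(idx) < 50) stop_field("need >= 50 usable bins with positive counts")
  y <- log2(counts[idx])
  covs <- list(gc = bins$gc[idx], mappability = bins$mappability[idx])
  log_bias <- rep(0, length(idx))
  for (it in seq_len(iterations)) {
    for (nm in names(covs)) {
      x <- covs[[nm]]
      if (stats::sd(x) < 1e-8) {
        if (it == 1) warning(sprintf("covariate '%s' is constant; skipped", nm))
        next
      }
      fit <- stats::loess((y - log_bias) ~ x, span = span, degree = 2,
                          family = "symmetric")
      comp <- stats::fitted(fit)
      log_bias <- log_bias + (comp - mean(comp))
    }
  }
  bias <- 2^log_bias
  bias <- bias / mean(bias)
  out <- as.double(counts)
  out[idx] <- counts[idx] / bias
  out
}

#' Normalize corrected counts to a median-centered log2 profile
#'
#' Log2 ratios centered on the median log2 usable count (equivalently,
#' ratios to the geometric median count), so the diploid baseline sits at 0
#' when aberrations cover less than half the usable genome. Usable bins with
#' zero count are set to the profile minimum minus 1 and flagged unusable.
#'
#' @param counts corrected counts (vector).
#' @param usable logical usability mask.
#' @return a `copy_number_profile`: list with `log2_ratio` (NA where
#'   unusable) and `usable`.
#' @export
normalize_log2 <- function(counts, usable = rep(TRUE, length(counts))) {
  if (length(counts) != length(usable)) stop_field("mask does not align to counts")
  pos <- usable & counts > 0
  if (!any(pos)) stop_field("all usable counts are zero; cannot normalize")
  log2r <- rep(NA_real_, length(counts))
  log2r[pos] <- log2(counts[pos])
  log2r[pos] <- log2r[pos] - stats::median(log2r[pos])
  zero <- usable & counts <= 0
  if (any(zero)) {
    log2r[zero] <- min(log2r[pos]) - 1
    usable[zero] <- FALSE
  }
  log2r[!usable & !zero] <- NA_real_
  structure(list(log2_ratio = log2r, usable = usable),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("copy-number profile: %d bins, %d usable, median log2 %.3g\n",
              length(x$log2_ratio), sum(x$usable),
              stats::median(x$log2_ratio[x$usable])))
  invisible(x)
}

#' Run the full bin-level correction for one sample
#'
#' Convenience wrapper: [filter_bins()] then [loess_correct()] then
#' [normalize_log2()].
#'
#' @inheritParams loess_correct
#' @param min_mappability passed to [filter_bins()].
#' @param correct if FALSE skip the loess step (for bias-free simulations).
#' @return a `copy_number_profile`.
#' @export
correct_profile <- function(counts, bins, min_mappability = 0.8, span = 0.65,
                            iterations = 2L, correct = TRUE) {
  usable <- filter_bins(counts, bins, min_mappability)
  cc <- if (correct) loess_correct(counts, bins, usable, span, iterations) else counts
  normalize_log2(cc, usable)
}
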