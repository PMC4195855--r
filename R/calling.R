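#' Log2-ratio thresholds calibrated to a minimum detectable cell fraction
#'
#' Under the diploid-baseline mixture model, a single-copy event carried by a
#' fraction `f = f_min * purity` of all cells shifts the average copy number
#' to `m = 2 + f (c - 2)`, i.e. a log2 ratio of `log2(m/2)`. The gain
#' threshold uses c = 3 and the loss threshold c = 1, so a segment is called
#' only when its deflection is at least that of a single-copy event in
#' `f_min` of the tumor cells. With `f_min = 0.30`, purity 1, the exact
#' thresholds are `log2(1.15) = 0.2016` and `log2(0.85) = -0.2345`; with
#' `mode = "rounded"` the conventional two-decimal values `0.20` / `-0.23`
#' are returned instead.
#'
#' @param f_min minimum tumor-cell fraction an event must reach to be called,
#'   in (0, 1] (default 0.30).
#' @param purity tumor-cell fraction of the specimen, in (0, 1].
#' @param mode `"exact"` (default) or `"rounded"` (two decimals).
#' @return named numeric vector `c(gain = ..., loss = ...)`.
#' @export
calling_thresholds <- function(f_min = 0.30, purity = 1,
                               mode = c("exact", "rounded")) {
  mode <- match.arg(mode)
  if (f_min <= 0 || f_min > 1) stop_field("'f_min' must be in (0,1]")
  if (purity <= 0 || purity > 1) stop_field("'purity' must be in (0,1]")
  f <- f_min * purity
  thr <- c(gain = log2(1 + f / 2), loss = log2(1 - f / 2))
  if (mode == "rounded") thr <- round(thr, 2)
  thr
}

#' Convert segment means into discrete copy-number calls
#'
#' A segment is a gain when its mean log2 ratio exceeds the gain threshold,
#' a loss when it is below the loss threshold (strict inequalities), and
#' normal otherwise. For non-normal calls the carried cell fraction is
#' estimated assuming single-copy events (c = 1 for losses, c = 3 for gains).
#'
#' @param segments data.frame from [segment_profile()] (needs `mean_log2`).
#' @param thresholds vector from [calling_thresholds()].
#' @param purity specimen purity used for the cell-fraction estimate.
#' @return `segments` with extra columns `call` (-1/0/+1) and
#'   `cell_fraction` (NA for normal segments).
#' @export
call_segments <- function(segments, thresholds = calling_thresholds(),
                          purity = 1) {
  if (!(thresholds[["gain"]] > 0 && thresholds[["loss"]] < 0)) {
    stop_field("thresholds must satisfy gain > 0 > loss")
  }
  r <- segments$mean_log2
  call <- integer(length(r))
  call[r > thresholds[["gain"]]] <- 1L
  call[r < thresholds[["loss"]]] <- -1L
  cf <- rep(NA_real_, length(r))
  is_loss <- call == -1L
  is_gain <- call == 1L
  if (any(is_loss)) cf[is_loss] <- estimate_cell_fraction(r[is_loss], 1, purity)
  if (any(is_gain)) cf[is_gain] <- estimate_cell_fraction(r[is_gain], 3, purity)
  segments$call <- call
  segments$cell_fraction <- cf
  segments
}

#' Estimate the cell fraction carrying an event from its log2 deflection
#'
#' Inverts the mixture model `2^r = 1 + f (c - 2) / 2`:
#' `f = 2 (2^r - 1) / (c - 2)`, divided by `purity` to express the fraction
#' relative to tumor cells. Values are clipped to \[0, 1\]; estimates that
#' exceed 1.05 before clipping (or are negative, i.e. the deflection sign
#' contradicts `c`) are flagged model-inconsistent via the
#' `"inconsistent"` attribute.
#'
#' @param r log2 ratio(s) of the event segment.
#' @param c total copies in aberrant cells (non-negative integer, not 2);
#'   default 1 assumes a single-copy loss for `r < 0`, supply 3 for gains.
#' @param purity tumor-cell fraction of the specimen.
#' @return numeric vector of estimated tumor-cell fractions in \[0, 1\], with
#'   a logical `"inconsistent"` attribute.
#' @export
estimate_cell_fraction <- function(r, c = 1, purity = 1) {
  if (any(c == 2)) stop_field("'c' = 2 carries no deflection; rejected")
  if (any(c < 0 | c != round(c))) stop_field("'c' must be a non-negative integer")
  if (purity <= 0 || purity > 1) stop_field("'purity' must be in (0,1]")
  f_raw <- 2 * (2^r - 1) / (c - 2) / purity
  inconsistent <- f_raw < -1e-12 | f_raw > 1.05
  structure(pmin(1, pmax(0, f_raw)), inconsistent = inconsistent)
}

#' Cell fraction of an event relative to a clonal anchor event
#'
#' The ratio of two [estimate_cell_fraction()] estimates; specimen purity
#' cancels, so with a clonal anchor (such as a 1p/19q co-deletion) the result
#' is the fraction of tumor cells carrying the event.
#'
#' @param event_r,anchor_r mean log2 ratios of the event and anchor segments.
#' @param event_c,anchor_c assumed copies in aberrant cells (default 1).
#' @return the relative fraction (NA, flagged via attribute, when the event
#'   deflection is normal-signed or zero).
#' @export
anchored_fraction <- function(event_r, anchor_r, event_c = 1, anchor_c = 1) {
  fa <- estimate_cell_fraction(anchor_r, anchor_c, purity = 1)
  if (any(fa <= 0)) stop_field("anchor fraction is 0; need a non-normal anchor")
  fe <- 2 * (2^event_r - 1) / (event_c - 2)
  undefined <- fe <= 0
  out <- fe / as.numeric(fa)
  out[undefined] <- NA_real_
  structure(out, undefined = undefined)
}

#' Call a predefined region from a sample's called segments
#'
#' A region is called loss (gain) when segments called loss (gain) cover at
#' least `min_cover` of the region's length — so a whole-chromosome loss
#' covers, and therefore calls, any distal region on that chromosome. If both
#' directions exceed the coverage threshold the loss takes precedence, with a
#' warning.
#'
#' @param segments called segments for one sample (from [call_segments()]).
#' @param region one-row data.frame / list with `chrom`, `start`, `end`
#'   (1-based inclusive bp).
#' @param min_cover minimum covered fraction of the region, default 0.9.
#' @return integer call: -1 (loss), 0 (normal), +1 (gain).
#' @export
region_call <- function(segments, region, min_cover = 0.9) {
  if (min_cover <= 0 || min_cover > 1) stop_field("'min_cover' must be in (0,1]")
  on_ch <- segments[segments$chrom == region$chrom, , drop = FALSE]
  if (nrow(on_ch) == 0) stop_field("region on chromosome '%s' is outside the profile",
                                   region$chrom)
  if (region$start < min(on_ch$start) || region$end > max(on_ch$end)) {
    stop_field("region %s:%s-%s extends beyond the profiled chromosome",
               region$chrom, format(region$start), format(region$end))
  }
  len <- region$end - region$start + 1
  ov <- pmin(on_ch$end, region$end) - pmax(on_ch$start, region$start) + 1
  ov <- pmax(ov, 0)
  cov_loss <- sum(ov[on_ch$call == -1L]) / len
  cov_gain <- sum(ov[on_ch$call == 1L]) / len
  if (cov_loss >= min_cover && cov_gain >= min_cover) {
    warning("region covered by both loss and gain calls; loss takes precedence")
    return(-1L)
  }
  if (cov_loss >= min_cover) return(-1L)
  if (cov_gain >= min_cover) return(1L)
  0L
}

#' Expand called segments back to per-bin discrete calls
#'
#' Each bin inherits the call of the segment containing it (0 for bins not
#' covered by any segment, e.g. unusable stretches outside segment spans).
#'
#' @param segments called segments for one sample (from [call_segments()]).
#' @param bins bin annotation table.
#' @return integer vector of -1/0/+1 calls, one per bin.
#' @export
segments_to_calls <- function(segments, bins) {
  calls <- integer(nrow(bins))
  for (j in seq_len(nrow(segments))) {
    hit <- bins$chrom == segments$chrom[j] &
      bins$start >= segments$start[j] & bins$end <= segments$end[j]
    calls[hit] <- segments$call[j]
  }
  calls
}

#' Call predefined regions across an external segmented cohort
#'
#' Applies the threshold model and the region-overlap rule to a SEG-style
#' table of segment means (e.g. TCGA level-3 SNP6 segments): per sample,
#' segments are called with [call_segments()] and each region is called with
#' [region_call()].
#'
#' @param seg data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean` (as from [read_seg()]).
#' @param regions data.frame of regions (`label`, `chrom`, `start`, `end`).
#' @param thresholds vector from [calling_thresholds()].
#' @param min_cover minimum covered fraction, default 0.9.
#' @return integer matrix samples x regions of calls (-1/0/+1).
#' @export
call_seg_cohort <- function(seg, regions, thresholds = calling_thresholds(),
                            min_cover = 0.9) {
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop_field("seg table is missing columns: %s",
                               paste(miss, collapse = ", "))
  samples <- unique(seg$sample)
  out <- matrix(0L, length(samples), nrow(regions),
                dimnames = list(samples, regions$label))
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    ss$mean_log2 <- ss$seg_mean
    ss <- call_segments(ss, thresholds)
    for (j in seq_len(nrow(regions))) {
      out[s, j] <- region_call(ss, regions[j, ], min_cover)
    }
  }
  out
}
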