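#' Segment a log2 profile by recursive binary splitting
#'
#' Within each chromosome, the usable bins are recursively split at the
#' position maximizing the two-sample t statistic between the left and right
#' parts; a split is accepted when a within-chromosome permutation test on
#' that maximal statistic gives p < `alpha`. Segments never get shorter than
#' `min_seg_bins` usable bins.
#'
#' @param profile a `copy_number_profile` from [normalize_log2()].
#' @param bins bin annotation table aligned to the profile.
#' @param alpha significance level for accepting a split (default 0.01).
#' @param min_seg_bins minimum usable bins per segment (>= 3, default 5).
#' @param n_perm permutations per split test (default 100).
#' @param seed integer seed; segmentation is deterministic given the seed.
#' @return data.frame of segments: `chrom`, `start`, `end` (bp, from the bin
#'   grid), `first_bin`, `last_bin` (row indices into `bins`), `n_bins`
#'   (usable bins) and `mean_log2`.
#' @export
segment_profile <- function(profile, bins, alpha = 0.01, min_seg_bins = 5L,
                            n_perm = 100L, seed = 1L) {
  stopifnot(inherits(profile, "copy_number_profile"))
  validate_bins(bins)
  if (min_seg_bins < 3) stop_field("'min_seg_bins' must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop_field("'alpha' must be in (0,1)")
  segs <- list()
  with_seed(seed, {
    for (ch in unique(bins$chrom)) {
      on_ch <- which(bins$chrom == ch)
      use <- on_ch[profile$usable[on_ch]]
      if (length(use) == 0) next
      x <- profile$log2_ratio[use]
      if (length(use) < 2 * min_seg_bins) {
        # too short to split; emit a single segment (logged)
        message(sprintf("chromosome %s: %d usable bins < 2 x min_seg_bins; single segment",
                        ch, length(use)))
        bounds <- c(0L, length(use))
      } else {
        bounds <- c(0L, rbs_breaks(x, alpha, min_seg_bins, n_perm), length(use))
      }
      for (i in seq_len(length(bounds) - 1)) {
        lo <- bounds[i] + 1L
        hi <- bounds[i + 1]
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch,
          start = bins$start[use[lo]],
          end = bins$end[use[hi]],
          first_bin = use[lo], last_bin = use[hi],
          n_bins = hi - lo + 1L,
          mean_log2 = mean(x[lo:hi]),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Post-segmentation recentering of a profile
#'
#' Bin-level median centering is biased by up to a noise SD when an
#' appreciable fraction of the genome is aberrant (the bin median lands in
#' the tail of the diploid cloud). Recentring on the median of the per-bin
#' segment means — which are nearly noise-free — restores the diploid
#' baseline to 0 as long as aberrations cover less than half of the usable
#' genome. Both the profile and the segment means are shifted.
#'
#' @param profile a `copy_number_profile`.
#' @param segments segments from [segment_profile()].
#' @return list with the shifted `profile` and `segments` and the applied
#'   `offset`.
#' @export
recenter_profile <- function(profile, segments) {
  stopifnot(inherits(profile, "copy_number_profile"))
  per_bin <- rep(segments$mean_log2, segments$n_bins)
  offset <- stats::median(per_bin)
  profile$log2_ratio <- profile$log2_ratio - offset
  segments$mean_log2 <- segments$mean_log2 - offset
  list(profile = profile, segments = segments, offset = offset)
}

# Recursive binary segmentation on one vector; returns sorted split offsets.
rbs_breaks <- function(x, alpha, min_seg, n_perm) {
  n <- length(x)
  if (n < 2 * min_seg) return(integer())
  obs <- max_split_stat(x, min_seg)
  null_max <- vapply(seq_len(n_perm), function(i) {
    max_split_stat(x[sample.int(n)], min_seg)$stat
  }, numeric(1))
  p <- (1 + sum(null_max >= obs$stat)) / (n_perm + 1)
  if (p >= alpha) return(integer())
  k <- obs$split
  c(rbs_breaks(x[seq_len(k)], alpha, min_seg, n_perm),
    k,
    k + rbs_breaks(x[(k + 1):n], alpha, min_seg, n_perm))
}

# Maximal two-sample t statistic over admissible split points, via cumsums.
max_split_stat <- function(x, min_seg) {
  n <- length(x)
  ks <- min_seg:(n - min_seg)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  ss <- (cs2[ks] - ks * m1^2) + ((tot2 - cs2[ks]) - (n - ks) * m2^2)
  sp2 <- ss / pmax(n - 2, 1)
  tstat <- abs(m1 - m2) / sqrt(pmax(sp2, 1e-12) * (1 / ks + 1 / (n - ks)))
  i <- which.max(tstat)
  list(stat = tstat[i], split = ks[i])
}
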