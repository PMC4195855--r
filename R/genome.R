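#' Build an annotated bin grid for a synthetic genome
#'
#' Creates the fixed-width genomic bins that act as the coordinate backbone of
#' all copy-number profiles: per bin a chromosome label, 1-based inclusive
#' start/end, a GC fraction, a mappability fraction and a blacklist flag.
#' GC content follows a smooth spatial process confined to \[0.3, 0.7\] (an
#' autoregressive walk along each chromosome), mappability a similar process
#' in \[0.5, 1\], and a random subset of bins is blacklisted, mimicking the
#' problematic-region lists used for real shallow-WGS data.
#'
#' @param n_chroms number of autosomes to simulate (labelled "1", "2", ...).
#' @param chrom_length_bp chromosome length(s) in bp; recycled to `n_chroms`.
#' @param bin_width bin width in bp (default 15000, the 15 kb grid used for
#'   shallow whole-genome sequencing). The last bin of a chromosome may be
#'   shorter.
#' @param gc_bias_profile `"smooth"` (spatially correlated GC) or `"flat"`
#'   (constant 0.45).
#' @param blacklist_fraction expected fraction of bins flagged as blacklisted.
#' @param seed integer seed; output is deterministic given the seed.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `gc`,
#'   `mappability`, `blacklisted`, sorted by (chrom, start).
#' @examples
#' bins <- make_genome(1, 150e3, seed = 1)
#' nrow(bins)  # 10 bins of 15 kb
#' @export
make_genome <- function(n_chroms,
                        chrom_length_bp,
                        bin_width = 15000L,
                        gc_bias_profile = c("smooth", "flat"),
                        blacklist_fraction = 0,
                        seed = 1L) {
  gc_bias_profile <- match.arg(gc_bias_profile)
  if (!is.numeric(n_chroms) || n_chroms < 1) {
    stop_field("'n_chroms' must be a positive integer, got %s", format(n_chroms))
  }
  if (any(!is.finite(chrom_length_bp)) || any(chrom_length_bp <= 0)) {
    stop_field("'chrom_length_bp' must be positive")
  }
  assert_positive(bin_width, "bin_width")
  assert_prob(blacklist_fraction, "blacklist_fraction", open_right = TRUE)
  lens <- rep_len(as.double(chrom_length_bp), n_chroms)

  with_seed(seed, {
    per_chrom <- lapply(seq_len(n_chroms), function(i) {
      n_bins <- as.integer(ceiling(lens[i] / bin_width))
      start <- (seq_len(n_bins) - 1) * bin_width + 1
      end <- pmin(seq_len(n_bins) * bin_width, lens[i])
      gc <- if (gc_bias_profile == "flat") {
        rep(0.45, n_bins)
      } else {
        smooth_process(n_bins, lo = 0.3, hi = 0.7, center = 0.45, sd = 0.05)
      }
      map <- smooth_process(n_bins, lo = 0.5, hi = 1, center = 0.92, sd = 0.04)
      data.frame(chrom = as.character(i), start = start, end = end,
                 gc = gc, mappability = map,
                 blacklisted = FALSE, stringsAsFactors = FALSE)
    })
    bins <- do.call(rbind, per_chrom)
    if (blacklist_fraction > 0) {
      bins$blacklisted <- stats::runif(nrow(bins)) < blacklist_fraction
    }
    rownames(bins) <- NULL
    bins
  })
}

# Isochore-like spatial process: an AR(1) component with a correlation
# length of ~10 bins (150 kb) plus independent bin-level jitter, clipped to
# [lo, hi]. The fast mixing makes every chromosome span the same covariate
# range, as real genomes do.
smooth_process <- function(n, lo, hi, center, sd, rho = 0.9) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) x[i] <- rho * x[i - 1] + eps[i - 1]
  }
  x <- x + stats::rnorm(n, 0, sd / 2)
  pmin(hi, pmax(lo, center + x))
}

validate_bins <- function(bins) {
  need <- c("chrom", "start", "end", "gc", "mappability", "blacklisted")
  miss <- setdiff(need, names(bins))
  if (length(miss)) stop_field("bins table is missing columns: %s",
                               paste(miss, collapse = ", "))
  if (any(bins$start > bins$end)) stop_field("bins with start > end")
  if (any(bins$gc < 0 | bins$gc > 1)) stop_field("gc outside [0,1]")
  if (any(bins$mappability < 0 | bins$mappability > 1)) {
    stop_field("mappability outside [0,1]")
  }
  invisible(bins)
}
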