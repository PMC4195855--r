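#' Describe a copy-number event
#'
#' A CNA event is an interval on one chromosome carried at an integer total
#' copy number `copies` (!= 2, the diploid state) by the cells of a clone.
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bp coordinates, `start <= end`.
#' @param copies non-negative integer total copy number, not 2.
#' @return one-row `data.frame` with columns `chrom`, `start`, `end`, `copies`.
#' @export
cna_event <- function(chrom, start, end, copies) {
  if (start > end) stop_field("event start > end (%s:%s-%s)", chrom, start, end)
  if (copies < 0 || copies != round(copies)) {
    stop_field("'copies' must be a non-negative integer")
  }
  if (copies == 2) stop_field("'copies' must differ from the diploid 2")
  data.frame(chrom = as.character(chrom), start = as.double(start),
             end = as.double(end), copies = as.integer(copies),
             stringsAsFactors = FALSE)
}

#' Define a clonal architecture for one tumor sample
#'
#' A sample is modelled as a mixture of normal (diploid) cells and tumor
#' cells; the tumor compartment is itself a mixture of clones, each carrying a
#' set of integer-copy CNA events. The fraction of all cells bearing an event
#' is `purity` times the summed prevalence of the clones that carry it. Clone
#' prevalences are fractions of the tumor compartment; any remainder is
#' diploid tumor tissue.
#'
#' @param clones named list of event tables (as returned by [cna_event()],
#'   possibly several rows via `rbind`); an empty `data.frame` is a diploid
#'   clone. The first clone is conventionally the truncal clone.
#' @param prevalences numeric vector, one entry per clone, each >= 0 and
#'   summing to at most 1.
#' @param purity tumor-cell fraction of the specimen, in (0, 1].
#' @return an object of class `clonal_architecture`.
#' @export
clonal_architecture <- function(clones, prevalences, purity = 0.6) {
  if (length(clones) != length(prevalences)) {
    stop_field("'clones' and 'prevalences' differ in length")
  }
  if (any(prevalences < 0)) stop_field("'prevalences' must be >= 0")
  if (sum(prevalences) > 1 + 1e-9) stop_field("'prevalences' must sum to <= 1")
  assert_prob(purity, "purity")
  if (purity <= 0) stop_field("'purity' must be > 0")
  if (is.null(names(clones))) {
    names(clones) <- paste0("clone", seq_along(clones))
  }
  structure(list(clones = clones,
                 prevalences = as.double(prevalences),
                 purity = purity),
            class = "clonal_architecture")
}

#' @export
print.clonal_architecture <- function(x, ...) {
  cat(sprintf("clonal architecture: %d clone(s), purity %.2f\n",
              length(x$clones), x$purity))
  for (i in seq_along(x$clones)) {
    cat(sprintf("  %s (prevalence %.2f): %d event(s)\n", names(x$clones)[i],
                x$prevalences[i], nrow(x$clones[[i]])))
  }
  invisible(x)
}

# Per-bin integer copies carried by one clone (diploid 2 outside its events).
clone_copies_per_bin <- function(bins, events) {
  copies <- rep(2, nrow(bins))
  if (is.null(events) || nrow(events) == 0) return(copies)
  for (j in seq_len(nrow(events))) {
    hit <- bins$chrom == events$chrom[j] &
      bins$start >= events$start[j] & bins$end <= events$end[j]
    copies[hit] <- events$copies[j]
  }
  copies
}

#' Expected average copy number per bin under an architecture
#'
#' The cell-population average copy number of bin b is
#' `m_b = 2 (1 - purity) + purity * (2 (1 - P) + sum_k prev_k * copies_k(b))`
#' where `P` is the summed clone prevalence; the expected log2 ratio of the
#' bin relative to a diploid baseline is `log2(m_b / 2)`.
#'
#' @param bins bin table from [make_genome()].
#' @param architecture a [clonal_architecture()].
#' @return numeric vector of expected average copies per bin.
#' @export
expected_copies <- function(bins, architecture) {
  stopifnot(inherits(architecture, "clonal_architecture"))
  validate_bins(bins)
  p <- architecture$purity
  prev <- architecture$prevalences
  tumor <- rep(2 * (1 - sum(prev)), nrow(bins))
  for (k in seq_along(architecture$clones)) {
    tumor <- tumor + prev[k] * clone_copies_per_bin(bins, architecture$clones[[k]])
  }
  2 * (1 - p) + p * tumor
}

#' Specify the technical bias injected into simulated bin counts
#'
#' Multiplicative per-bin bias: a unimodal (Gaussian-shaped in GC, peaking at
#' `gc_peak`) GC component times `mappability^map_weight`, normalized to mean
#' 1 over non-blacklisted bins so the genome-average depth is unchanged.
#'
#' @param gc_amplitude strength of the GC component (0 = none).
#' @param gc_peak GC fraction at which counts peak.
#' @param map_weight exponent on mappability (0 = none, 1 = proportional).
#' @return a list of class `bias_model`.
#' @export
bias_model <- function(gc_amplitude = 0.5, gc_peak = 0.45, map_weight = 1) {
  structure(list(gc_amplitude = gc_amplitude, gc_peak = gc_peak,
                 map_weight = map_weight), class = "bias_model")
}

bias_per_bin <- function(bins, bias) {
  raw <- exp(-bias$gc_amplitude * ((bins$gc - bias$gc_peak) / 0.25)^2) *
    bins$mappability^bias$map_weight
  keep <- !bins$blacklisted
  raw / mean(raw[keep])
}

#' Simulate per-bin read counts from a clonal architecture
#'
#' Forward model of depth-of-coverage copy-number inference: the count of bin
#' b is Poisson with mean
#' `mean_depth_per_bin * bias(gc_b, map_b) * m_b / 2`,
#' where `m_b` is the population-average copy number from
#' [expected_copies()]. With `dispersion` set, counts are negative binomial
#' with that `size` parameter instead (same mean), for robustness checks.
#'
#' @param bins bin table from [make_genome()].
#' @param architecture a [clonal_architecture()]; all events must align to bin
#'   boundaries of `bins`.
#' @param mean_depth_per_bin expected count for a diploid, bias-free bin.
#' @param seed integer seed.
#' @param bias a [bias_model()]; default injects moderate GC and mappability
#'   bias so the loess correction has work to do.
#' @param dispersion optional negative-binomial size (NULL = Poisson).
#' @return integer vector of counts, one per bin.
#' @export
simulate_bin_counts <- function(bins, architecture, mean_depth_per_bin,
                                seed = 1L, bias = bias_model(),
                                dispersion = NULL) {
  assert_positive(mean_depth_per_bin, "mean_depth_per_bin")
  validate_bins(bins)
  check_events_on_grid(bins, architecture)
  m <- expected_copies(bins, architecture)
  lambda <- mean_depth_per_bin * bias_per_bin(bins, bias) * m / 2
  with_seed(seed, {
    if (is.null(dispersion)) {
      stats::rpois(length(lambda), lambda)
    } else {
      stats::rnbinom(length(lambda), size = dispersion, mu = lambda)
    }
  })
}

# Events must start on a bin start and end on a bin end of their chromosome,
# otherwise the planted log2 ground truth would be ill-defined at bin scale.
check_events_on_grid <- function(bins, architecture) {
  for (ev in architecture$clones) {
    if (is.null(ev) || nrow(ev) == 0) next
    for (j in seq_len(nrow(ev))) {
      b <- bins[bins$chrom == ev$chrom[j], ]
      if (nrow(b) == 0) {
        stop_field("event on chromosome '%s' absent from the bin grid",
                   ev$chrom[j])
      }
      if (!ev$start[j] %in% b$start || !ev$end[j] %in% b$end) {
        stop_field("event %s:%s-%s is off the bin grid",
                   ev$chrom[j], format(ev$start[j]), format(ev$end[j]))
      }
    }
  }
  invisible(TRUE)
}
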