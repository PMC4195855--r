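# Independent oracles used to cross-check the package implementations.

# Direct per-death-time 2x2 log-rank oracle: loops over death times and sums
# observed-minus-expected deaths with the hypergeometric variance.
oracle_logrank_chisq <- function(time, event, group1) {
  group1 <- as.logical(group1)
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# Textbook Holm step-down adjustment.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Textbook Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Seeded evaluation that restores the caller's RNG stream.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Small flat genome for fast tests.
flat_bins <- function(n_bins, bin_width = 15000L, chrom = "1") {
  data.frame(chrom = chrom,
             start = (seq_len(n_bins) - 1) * bin_width + 1,
             end = seq_len(n_bins) * bin_width,
             gc = 0.45, mappability = 0.95, blacklisted = FALSE,
             stringsAsFactors = FALSE)
}

# Architecture with a single clonal event at given purity.
single_event_arch <- function(event, purity = 1, prevalence = 1) {
  clonal_architecture(list(clone1 = event), prevalence, purity)
}
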