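#' Bin grid emulating the autosomes recurrently aberrant in low-grade glioma
#'
#' A compact stand-in genome restricted to the chromosomes that carry the
#' recurrent low-grade-glioma CNAs (1, 4, 9, 10, 11, 13, 19, 22), with
#' GRCh37-like lengths rounded to the 15 kb grid. Chromosome 10 ends at
#' 135,435,000 bp so the distal 10q25.2-qter region
#' (112,950,001-135,435,000) sits exactly on the grid.
#'
#' @param seed integer seed for the GC/mappability processes.
#' @param gc_bias_profile passed to [make_genome()].
#' @return bin table as from [make_genome()], with the original chromosome
#'   names.
#' @export
glioma_bins <- function(seed = 1L, gc_bias_profile = "smooth") {
  lens <- c("1" = 249240000, "4" = 191160000, "9" = 141210000,
            "10" = 135435000, "11" = 135000000, "13" = 115110000,
            "19" = 59130000, "22" = 51300000)
  bins <- make_genome(length(lens), unname(lens), bin_width = 15000L,
                      gc_bias_profile = gc_bias_profile, seed = seed)
  bins$chrom <- names(lens)[as.integer(bins$chrom)]
  bins
}

#' Recurrent CNA loci of the synthetic glioma cohort
#'
#' Grid-aligned loci for the planted prognostic events (1p loss, 19q loss,
#' distal or whole 10q loss) and the recurrent passenger aberrations, with
#' their cohort prevalences. Prevalences mirror the discovery-cohort
#' frequencies (distal 10q loss 18%, 1p/19q co-deletion ~41%, 9p 21%,
#' 13q 17%, 22q 31%, ...).
#'
#' @return data.frame `locus`, `chrom`, `start`, `end`, `direction`,
#'   `prevalence`.
#' @export
glioma_cna_loci <- function() {
  data.frame(
    locus = c("1p_loss", "19q_loss", "10q_distal_loss", "chr4_loss",
              "9p_loss", "11p_loss", "13q_loss", "22q_loss",
              "11q_gain", "10p_gain"),
    chrom = c("1", "19", "10", "4", "9", "11", "13", "22", "11", "10"),
    start = c(1, 27000001, 112950001, 1, 1, 1, 1, 1, 53700001, 1),
    end = c(125010000, 59130000, 135435000, 191160000, 47010000,
            53700000, 115110000, 51300000, 135000000, 39000000),
    direction = c(-1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, 1L, 1L),
    prevalence = c(0.41, 0.41, 0.18, 0.18, 0.21, 0.13, 0.17, 0.31,
                   0.10, 0.10),
    stringsAsFactors = FALSE)
}

#' Simulate a discovery-like cohort of called copy-number profiles
#'
#' Generates `n` patients with bin-level discrete calls and exponential
#' survival tied to their prognostic CNA status. Patients fall into the four
#' 1p/19q x 10q groups with probabilities (neither 0.44, 1p/19q-only 0.38,
#' 10q-only 0.15, both 0.03); 10q carriers lose the whole chromosome with
#' probability 5/18 and the distal 10q25.2-qter region otherwise. Passenger
#' aberrations from [glioma_cna_loci()] are drawn independently at their
#' prevalences and carry no survival effect. Hazard ratios default to 2.91
#' for distal 10q loss and 0.30 for the 1p/19q co-deletion, on a baseline
#' median of 200.4 months with administrative censoring at 240 months
#' (~47% of patients deceased).
#'
#' @param n number of patients (default 98).
#' @param bins bin table from [glioma_bins()] (built on the fly if NULL).
#' @param hr_10q,hr_codel planted hazard ratios.
#' @param seed integer seed.
#' @return list with `bins`, `bin_calls` (bins x patients integer matrix),
#'   `surv` (id, time_months, event) and `truth` (per-patient group and
#'   carrier status per locus).
#' @export
simulate_lgg_cohort <- function(n = 98L, bins = NULL, hr_10q = 2.91,
                                hr_codel = 0.30, seed = 1L) {
  if (is.null(bins)) bins <- glioma_bins(seed = derive_seed(seed, 101L))
  loci <- glioma_cna_loci()
  loci_idx <- lapply(seq_len(nrow(loci)), function(j) {
    which(bins$chrom == loci$chrom[j] & bins$start >= loci$start[j] &
            bins$end <= loci$end[j])
  })
  names(loci_idx) <- loci$locus
  chr10_idx <- which(bins$chrom == "10")
  with_seed(seed, {
    grp <- sample(c("neither", "1p/19q-only", "10q-only", "both"), n,
                  replace = TRUE, prob = c(0.44, 0.38, 0.15, 0.03))
    codel <- grp %in% c("1p/19q-only", "both")
    tenq <- grp %in% c("10q-only", "both")
    whole10 <- tenq & stats::runif(n) < 5 / 18
    passenger <- sapply(seq_len(nrow(loci)), function(j) {
      stats::runif(n) < loci$prevalence[j]
    })
    colnames(passenger) <- loci$locus
    # prognostic loci are driven by the group assignment, not the passenger draw
    passenger[, "1p_loss"] <- codel
    passenger[, "19q_loss"] <- codel
    passenger[, "10q_distal_loss"] <- tenq
    calls <- matrix(0L, nrow(bins), n,
                    dimnames = list(NULL, sprintf("P%03d", seq_len(n))))
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(loci))) {
        if (passenger[i, j]) calls[loci_idx[[j]], i] <- loci$direction[j]
      }
      if (whole10[i]) calls[chr10_idx, i] <- -1L
    }
    truth <- data.frame(id = colnames(calls), group = grp, codel = codel,
                        tenq = tenq, whole10 = whole10,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(passenger[, !colnames(passenger) %in%
      c("1p_loss", "19q_loss", "10q_distal_loss"), drop = FALSE]))
    model <- survival_model(baseline_median_months = 16.7 * 12,
                            hazard_ratios = c(tenq = hr_10q, codel = hr_codel),
                            horizon_months = 240)
    surv <- simulate_survival(truth, model, seed = derive_seed(seed, 202L))
    list(bins = bins, bin_calls = calls, surv = surv, truth = truth)
  })
}
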