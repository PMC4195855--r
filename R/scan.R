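#' Reduce bin-level calls across a cohort to common regions
#'
#' Collapses consecutive bins whose call vector across all samples is
#' identical into maximal regions (the common-region reduction used before
#' the survival scan and the heterogeneity comparisons).
#'
#' @param calls integer matrix bins x samples of -1/0/+1 calls.
#' @param bins bin annotation table aligned to the rows of `calls`.
#' @return list with `regions` (data.frame `label`, `chrom`, `start`, `end`,
#'   `first_bin`, `last_bin`) and `calls` (matrix samples x regions of the
#'   constant call vectors).
#' @export
reduce_to_regions <- function(calls, bins) {
  calls <- as.matrix(calls)
  validate_bins(bins)
  if (nrow(calls) != nrow(bins)) stop_field("calls do not align to bins")
  if (ncol(calls) < 1) stop_field("need >= 1 sample")
  key <- do.call(paste, c(as.data.frame(calls), list(sep = ",")))
  new_region <- c(TRUE, key[-1] != key[-length(key)] |
                    bins$chrom[-1] != bins$chrom[-nrow(bins)])
  rid <- cumsum(new_region)
  first <- which(new_region)
  last <- c(first[-1] - 1L, nrow(bins))
  regions <- data.frame(
    chrom = bins$chrom[first],
    start = bins$start[first],
    end = bins$end[last],
    first_bin = first, last_bin = last,
    stringsAsFactors = FALSE)
  regions$label <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  rc <- t(calls[first, , drop = FALSE])
  colnames(rc) <- regions$label
  list(regions = regions, calls = rc)
}

#' Genome-wide permutation log-rank survival scan with region fusion
#'
#' For every region, patients carrying the aberration (call equal to
#' `direction`) are compared with the rest of the cohort by a permutation
#' log-rank test. Maximal runs of consecutive same-chromosome regions with
#' p below `alpha_fuse` are then fused into final regions; fused regions are
#' re-tested and Benjamini-Hochberg correction is applied across all final
#' regions (discovery mode).
#'
#' For a fused region the default carrier rule (`fuse_carrier = "any"`) counts
#' a patient as a carrier when it carries any constituent region — a larger
#' loss always counts as carrying a smaller one, the same inclusion logic by
#' which a whole-chromosome loss carries a distal region. The alternative
#' `"span"` rule instead requires the carried constituents to cover at least
#' `min_cover` of the fused span; because fusion then can only shrink the
#' carrier set, a significant region fused with a weaker neighbour loses
#' carriers and the re-test loses power, so `"span"` is not the default.
#'
#' @param region_calls integer matrix samples x regions (-1/0/+1), e.g. from
#'   [reduce_to_regions()] or [call_seg_cohort()].
#' @param regions data.frame with `label`, `chrom`, `start`, `end` matching
#'   the columns of `region_calls`.
#' @param surv data.frame `id`, `time_months`, `event`, one row per sample in
#'   row order of `region_calls`.
#' @param direction -1 to scan losses (the default; gains showed no survival
#'   association in the reference cohort) or +1 for gains.
#' @param n_perm permutations per test (default 10000).
#' @param alpha_fuse fusion threshold on the raw p-value (default 0.05).
#' @param min_cover coverage fraction for the `"span"` carrier rule
#'   (default 0.9).
#' @param min_carriers regions with fewer carriers are skipped (default 2).
#' @param fuse_carrier carrier rule for fused regions, `"any"` (default) or
#'   `"span"`; see Details.
#' @param seed master seed; per-region permutation streams are derived from
#'   it by region index.
#' @return data.frame of final (possibly fused) regions with columns `label`,
#'   `chrom`, `start`, `end`, `n_carriers`, `statistic`, `p_raw`, `p_adj`
#'   (BH), `fused_from` (number of constituent regions), `hr`, `ci_low`,
#'   `ci_high`, `median_carrier_months`, `median_rest_months`.
#' @export
scan_regions <- function(region_calls, regions, surv, direction = -1L,
                         n_perm = 10000L, alpha_fuse = 0.05, min_cover = 0.9,
                         min_carriers = 2L, fuse_carrier = c("any", "span"),
                         seed = 1L) {
  fuse_carrier <- match.arg(fuse_carrier)
  if (!direction %in% c(-1L, 1L)) stop_field("'direction' must be -1 or +1")
  if (alpha_fuse <= 0 || alpha_fuse >= 1) stop_field("'alpha_fuse' must be in (0,1)")
  check_cohort(region_calls, regions, surv)
  carrier <- region_calls == direction
  p_raw <- rep(NA_real_, nrow(regions))
  for (j in seq_len(nrow(regions))) {
    if (sum(carrier[, j]) < min_carriers) next
    p_raw[j] <- permutation_p(surv$time_months, surv$event, carrier[, j],
                              n_perm, derive_seed(seed, j))$p
  }
  # fuse maximal same-chromosome runs of consecutive regions below alpha_fuse
  sig <- !is.na(p_raw) & p_raw < alpha_fuse
  run_break <- c(TRUE, regions$chrom[-1] != regions$chrom[-nrow(regions)] |
                   sig[-1] != sig[-length(sig)])
  run_id <- cumsum(run_break)
  final <- list()
  for (g in unique(run_id)) {
    idx <- which(run_id == g)
    if (sig[idx[1]] && length(idx) >= 1) {
      final[[length(final) + 1]] <- list(idx = idx, fused = length(idx) > 1)
    } else {
      for (j in idx) final[[length(final) + 1]] <- list(idx = j, fused = FALSE)
    }
  }
  rows <- lapply(seq_along(final), function(i) {
    idx <- final[[i]]$idx
    span <- data.frame(chrom = regions$chrom[idx[1]],
                       start = min(regions$start[idx]),
                       end = max(regions$end[idx]), stringsAsFactors = FALSE)
    if (length(idx) > 1) {
      if (fuse_carrier == "any") {
        carry <- rowSums(carrier[, idx, drop = FALSE]) > 0
      } else {
        len <- regions$end[idx] - regions$start[idx] + 1
        cov <- carrier[, idx, drop = FALSE] %*% len / sum(len)
        carry <- as.vector(cov >= min_cover)
      }
      p <- if (sum(carry) >= min_carriers) {
        permutation_p(surv$time_months, surv$event, carry, n_perm,
                      derive_seed(seed, nrow(regions) + i))$p
      } else NA_real_
    } else {
      carry <- carrier[, idx]
      p <- p_raw[idx]
    }
    st <- summarize_group_survival(surv, carry)
    data.frame(label = sprintf("%s:%d-%d", span$chrom, span$start, span$end),
               chrom = span$chrom, start = span$start, end = span$end,
               n_carriers = sum(carry), statistic = st$statistic,
               p_raw = p, fused_from = length(idx),
               hr = st$hr, ci_low = st$ci_low, ci_high = st$ci_high,
               median_carrier_months = st$median_carrier,
               median_rest_months = st$median_rest,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adj[tested] <- stats::p.adjust(out$p_raw[tested], method = "BH")
  rownames(out) <- NULL
  out[order(match(out$chrom, unique(regions$chrom)), out$start), ]
}

#' Test fixed a-priori regions in a validation cohort
#'
#' No fusion; raw permutation p-values are adjusted with the step-down
#' Holm-Bonferroni procedure across the tested regions (validation mode).
#'
#' @inheritParams scan_regions
#' @return data.frame with `label`, `n_carriers`, `statistic`, `p_raw`,
#'   `p_adj` (Holm), `hr`, `ci_low`, `ci_high` and group medians.
#' @export
validate_regions <- function(region_calls, regions, surv, direction = -1L,
                             n_perm = 10000L, min_carriers = 2L, seed = 1L) {
  check_cohort(region_calls, regions, surv)
  carrier <- region_calls == direction
  rows <- lapply(seq_len(nrow(regions)), function(j) {
    carry <- carrier[, j]
    p <- if (sum(carry) >= min_carriers) {
      permutation_p(surv$time_months, surv$event, carry, n_perm,
                    derive_seed(seed, j))$p
    } else NA_real_
    st <- summarize_group_survival(surv, carry)
    data.frame(label = regions$label[j], n_carriers = sum(carry),
               statistic = st$statistic, p_raw = p,
               hr = st$hr, ci_low = st$ci_low, ci_high = st$ci_high,
               median_carrier_months = st$median_carrier,
               median_rest_months = st$median_rest, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adj[tested] <- stats::p.adjust(out$p_raw[tested], method = "holm")
  rownames(out) <- NULL
  out
}

check_cohort <- function(region_calls, regions, surv) {
  if (ncol(region_calls) != nrow(regions)) {
    stop_field("region_calls columns do not match the regions table")
  }
  if (nrow(region_calls) != nrow(surv)) {
    stop_field("region_calls rows do not match the survival table")
  }
  if (anyNA(surv$time_months) || anyNA(surv$event)) {
    stop_field("missing survival data for scanned patients")
  }
  invisible(TRUE)
}

# Log-rank statistic, Cox HR (Breslow ties, Wald CI) and KM group medians
# for a carrier-vs-rest contrast. Degenerate contrasts yield NAs.
summarize_group_survival <- function(surv, carrier) {
  out <- list(statistic = NA_real_, hr = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_,
              median_carrier = if (any(carrier)) {
                km_median(surv$time_months[carrier], surv$event[carrier])
              } else NA_real_,
              median_rest = if (any(!carrier)) {
                km_median(surv$time_months[!carrier], surv$event[!carrier])
              } else NA_real_)
  if (length(unique(carrier)) < 2 || sum(surv$event) < 1) return(out)
  lr <- suppressWarnings(logrank(surv$time_months, surv$event, carrier))
  out$statistic <- lr$statistic
  if (sum(surv$event[carrier]) >= 1 && sum(surv$event[!carrier]) >= 1) {
    hr <- hazard_ratio(surv$time_months, surv$event, carrier)
    out$hr <- hr$hr
    out$ci_low <- hr$ci_low
    out$ci_high <- hr$ci_high
  }
  out
}

#' Stratify a cohort into the four 1p/19q x 10q prognostic groups
#'
#' 1p/19q co-deletion requires loss of both arms; the groups are
#' `"10q-only"` (distal 10q loss without co-deletion, unfavorable),
#' `"1p/19q-only"` (favorable), `"both"` and `"neither"`.
#'
#' @param call_1p,call_19q,call_10q integer call vectors (-1/0/+1) per patient.
#' @return character vector of group labels.
#' @export
stratify_four_groups <- function(call_1p, call_19q, call_10q) {
  codel <- call_1p == -1L & call_19q == -1L
  tenq <- call_10q == -1L
  ifelse(tenq & codel, "both",
         ifelse(tenq, "10q-only",
                ifelse(codel, "1p/19q-only", "neither")))
}

#' Kaplan-Meier median survival
#'
#' The smallest time at which the Kaplan-Meier survival curve drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param time,event survival outcome.
#' @return median in the same units as `time` (possibly `NA`).
#' @export
km_median <- function(time, event) {
  if (length(time) < 1) stop_field("need >= 1 observation")
  if (sum(event) == 0) return(NA_real_)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit)
  idx <- which(s$surv <= 0.5 + 1e-12)
  if (!length(idx)) return(NA_real_)
  s$time[idx[1]]
}

#' Hazard ratio of carriers vs rest with a 95% Wald confidence interval
#'
#' One-covariate Cox proportional-hazards partial likelihood (Breslow tie
#' handling). A monotone likelihood (e.g. one group with all-early events)
#' yields an unbounded interval and is flagged.
#'
#' @param time,event survival outcome.
#' @param group carrier indicator (logical or 0/1); the HR is for carriers
#'   relative to non-carriers.
#' @return list `hr`, `ci_low`, `ci_high`, `se_log_hr`, `flagged`.
#' @export
hazard_ratio <- function(time, event, group) {
  z <- as_group01(group)
  if (length(unique(z)) < 2) stop_field("both groups must be non-empty")
  if (sum(event[z == 1]) < 1 || sum(event[z == 0]) < 1) {
    stop_field("each group needs >= 1 event for a hazard ratio")
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  flagged <- !is.finite(beta) || !is.finite(se) || se > 10
  list(hr = exp(beta),
       ci_low = exp(beta - 1.959964 * se),
       ci_high = exp(beta + 1.959964 * se),
       se_log_hr = se,
       flagged = flagged)
}
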