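# Log-rank machinery, permutation p-values, region reduction, the fused scan,
# validation adjustment, stratification, KM medians and hazard ratios.

test_that("log-rank matches the hand-computed 2x2 example", {
  lr <- logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(lr$obs_minus_exp, 2 - 5 / 6)
  expect_equal(lr$var, 17 / 36)
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
})

test_that("log-rank agrees with the per-death-time oracle and survdiff", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:10, 1)
    time <- sample(1:6, n, replace = TRUE)      # deliberate ties
    event <- rbinom(n, 1, 0.7)
    group <- c(0, 1, rbinom(n - 2, 1, 0.5))     # both groups non-empty
    if (sum(event) == 0) event[1] <- 1
    lr <- suppressWarnings(logrank(time, event, group))
    expect_equal(lr$statistic, oracle_logrank_chisq(time, event, group),
                 tolerance = 1e-9, label = sprintf("oracle seed %d", s))
    if (lr$var > 0) {
      sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
      expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-6,
                   label = sprintf("survdiff seed %d", s))
    }
  }
})

test_that("log-rank edge cases behave", {
  # identical outcome multisets in both groups -> statistic 0
  lr <- logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1), c(0, 1, 0, 1, 0, 1))
  expect_lt(lr$statistic, 0.2)
  expect_warning(logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 0, 0)),
                 "no events")
  expect_error(logrank(1:4, c(1, 1, 1, 1), c(1, 1, 1, 1)), "non-empty")
})

test_that("permutation p-values are seeded, never zero, and 1 for null stats", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(1, 8)
  group <- c(1, 0, 1, 0, 1, 0, 1, 0)
  p1 <- permutation_p(time, event, group, n_perm = 200, seed = 4)
  p2 <- permutation_p(time, event, group, n_perm = 200, seed = 4)
  expect_identical(p1, p2)
  expect_gt(p1$p, 0)
  # constant carrier vector
  expect_equal(permutation_p(time, event, rep(1, 8), 100, 1)$p, 1)
  # observed statistic 0: every permutation ties or exceeds
  g0 <- c(0, 1, 0, 1, 0, 1, 0, 1)
  t0 <- rep(c(1, 1), 4)
  expect_equal(permutation_p(t0, event, g0, 100, 2)$p, 1)
})

test_that("region reduction finds the breakpoint union", {
  bins <- rbind(flat_bins(50, chrom = "1"), flat_bins(50, chrom = "2"))
  # identical calls genome-wide -> one region per chromosome
  calls <- matrix(0L, 100, 3)
  red <- reduce_to_regions(calls, bins)
  expect_equal(nrow(red$regions), 2L)

  # one focal loss -> 3 regions on that chromosome
  calls2 <- calls
  calls2[10:20, 2] <- -1L
  red2 <- reduce_to_regions(calls2, bins)
  expect_equal(sum(red2$regions$chrom == "1"), 3L)
  expect_equal(unname(red2$calls[2, 2]), -1L)

  # staggered fixture: boundaries equal the union of event breakpoints
  calls3 <- matrix(0L, 100, 5)
  starts <- c(5, 12, 30, 41, 60)
  ends <- c(25, 18, 44, 70, 95)
  for (k in 1:5) calls3[starts[k]:ends[k], k] <- -1L
  red3 <- reduce_to_regions(calls3, bins)
  # brute-force oracle: first bins of runs of distinct adjacent call vectors
  key <- apply(calls3, 1, paste, collapse = ",")
  brk <- c(1, which(key[-1] != key[-100] | bins$chrom[-1] != bins$chrom[-100]) + 1)
  expect_equal(red3$regions$first_bin, brk)
})

test_that("consecutive significant regions are fused and re-tested", {
  bins <- flat_bins(30, chrom = "5")
  n <- 40
  carrier <- c(rep(TRUE, 12), rep(FALSE, 28))
  calls <- matrix(0L, 30, n)
  calls[1:10, carrier] <- -1L    # region A: carriers 1-12
  calls[11:20, c(which(carrier), 13)] <- -1L  # region B: carriers 1-13
  calls[21:30, 1:2] <- 1L        # a gain elsewhere
  # carriers die mostly early, with overlap so the Cox fit stays finite
  surv <- data.frame(id = paste0("p", 1:n),
                     time_months = c(seq(2, 60, length.out = 12),
                                     seq(30, 178, length.out = 28)),
                     event = 1L)
  red <- reduce_to_regions(calls, bins)
  sc <- scan_regions(red$calls, red$regions, surv, direction = -1L,
                     n_perm = 400, seed = 6)
  fused <- sc[sc$fused_from > 1, ]
  expect_equal(nrow(fused), 1L)
  expect_equal(fused$fused_from, 2L)
  expect_equal(fused$n_carriers, 13)  # union of constituent carriers
  # fusion never decreases region length
  expect_gte(fused$end - fused$start + 1,
             max(red$regions$end - red$regions$start + 1))
  expect_lt(fused$p_raw, 0.05)
  expect_gt(fused$hr, 1)  # carriers fare worse
})

test_that("a null cohort passes through the scan without fusion", {
  bins <- flat_bins(30, chrom = "5")
  n <- 20
  calls <- matrix(0L, 30, n)
  calls[1:10, seq(1, 19, 2)] <- -1L
  calls[11:30, seq(2, 20, 2)] <- -1L
  # carrier and non-carrier outcome multisets identical -> statistic 0, p = 1
  surv <- data.frame(id = paste0("p", 1:n),
                     time_months = rep(1:10, each = 2), event = 1L)
  red <- reduce_to_regions(calls, bins)
  sc <- scan_regions(red$calls, red$regions, surv, direction = -1L,
                     n_perm = 100, seed = 7)
  expect_equal(nrow(sc), nrow(red$regions))
  expect_true(all(sc$fused_from == 1))
})

test_that("validation applies Holm and leaves single regions unadjusted", {
  bins <- flat_bins(10, chrom = "3")
  n <- 30
  calls <- matrix(0L, 10, n)
  calls[1:10, 1:10] <- -1L
  surv <- data.frame(id = paste0("p", 1:n),
                     time_months = c(seq(2, 40, length.out = 10),
                                     seq(25, 88, length.out = 20)),
                     event = 1L)
  red <- reduce_to_regions(calls, bins)
  v <- validate_regions(red$calls, red$regions, surv, n_perm = 200, seed = 8)
  expect_equal(v$p_adj, v$p_raw)  # single region: Holm is the identity
})

test_that("multiple-testing adjustments match the textbook step procedures", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(p.adjust(p, "holm"), oracle_holm(p))
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  set.seed(99)
  for (i in 1:10) {
    q <- runif(sample(3:12, 1))
    expect_equal(p.adjust(q, "holm"), oracle_holm(q))
    expect_equal(p.adjust(q, "BH"), oracle_bh(q))
    # BH dominates Holm pointwise; both are monotone in raw p
    expect_true(all(oracle_bh(q) <= oracle_holm(q) + 1e-12))
    o <- order(q)
    expect_true(all(diff(oracle_bh(q)[o]) >= -1e-12))
    expect_true(all(diff(oracle_holm(q)[o]) >= -1e-12))
  }
})

test_that("four-group stratification follows the co-deletion definition", {
  call_1p <- c(-1L, -1L, 0L, -1L, 0L)
  call_19q <- c(-1L, 0L, 0L, -1L, 0L)
  call_10q <- c(0L, -1L, -1L, -1L, 0L)
  expect_equal(stratify_four_groups(call_1p, call_19q, call_10q),
               c("1p/19q-only", "10q-only", "10q-only", "both", "neither"))
})

test_that("cohort group sizes match the planted prevalences", {
  coh <- simulate_lgg_cohort(n = 400, seed = 31)
  frac <- table(coh$truth$group) / 400
  expect_lt(abs(frac[["10q-only"]] - 0.15), 0.06)
  expect_lt(abs(frac[["1p/19q-only"]] - 0.38), 0.08)
  # bin-level calls agree with the truth flags via the region rule
  red <- reduce_to_regions(coh$bin_calls[coh$bins$chrom == "10", , drop = FALSE],
                           coh$bins[coh$bins$chrom == "10", ])
  distal <- which(red$regions$start <= 112950001 &
                    red$regions$end >= 135435000)
  expect_equal(unname(red$calls[, distal] == -1L), coh$truth$tenq)
})

test_that("KM medians follow the survival-curve definition", {
  expect_equal(km_median(c(1, 2, 3, 4), c(1, 1, 1, 1)), 2)
  expect_true(is.na(km_median(c(5, 6, 7), c(0, 0, 0))))
})

test_that("hazard ratios recover symmetry and reciprocity", {
  set.seed(55)
  time <- rexp(200, 0.01)
  event <- rbinom(200, 1, 0.8)
  group <- rep(c(0, 1), 100)
  hr <- hazard_ratio(time, event, group)
  expect_lt(abs(log(hr$hr)), 3 * hr$se_log_hr)
  hr_swapped <- hazard_ratio(time, event, 1 - group)
  expect_equal(hr$hr, 1 / hr_swapped$hr, tolerance = 1e-6)
  expect_true(hr$ci_low < hr$hr && hr$hr < hr$ci_high)
  expect_error(hazard_ratio(time, rep(0:1, 100) * c(rep(0, 100), rep(1, 100)),
                            c(rep(0, 100), rep(1, 100))), "event")
})

test_that("a completely separating group is flagged", {
  time <- c(1, 2, 3, 4, 100, 110, 120, 130)
  event <- c(1, 1, 1, 1, 1, 1, 1, 1)
  group <- c(1, 1, 1, 1, 0, 0, 0, 0)
  hr <- suppressWarnings(hazard_ratio(time, event, group))
  expect_true(hr$flagged)
})
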