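# Shared region grid, spatial/temporal CNA classification and summaries.

test_that("the shared grid drops regions below 5 Mbp", {
  bins <- flat_bins(1000)  # one 15 Mb chromosome
  calls <- matrix(0L, 1000, 2)
  calls[101:400, 1] <- -1L   # 4.5 Mbp region -> excluded
  grid <- shared_grid(calls, bins)
  expect_false(any(grid$regions$end - grid$regions$start + 1 < 5e6))
  expect_false(any(grid$calls == -1L))

  calls[101:450, 1] <- -1L   # 5.25 Mbp -> retained
  grid2 <- shared_grid(calls, bins)
  expect_true(any(grid2$calls == -1L))

  # identical samples -> chromosome-scale regions only
  same <- matrix(rep(c(rep(-1L, 500), rep(0L, 500)), 2), ncol = 2)
  grid3 <- shared_grid(same, bins)
  expect_equal(nrow(grid3$regions), 2L)

  expect_error(shared_grid(matrix(0L, 1000, 1), bins), ">= 2 samples")
})

test_that("the shared grid equals the breakpoint union minus sub-5 Mbp pieces", {
  bins <- flat_bins(2000)  # 30 Mb
  calls <- matrix(0L, 2000, 3)
  calls[1:700, 1] <- -1L       # 10.5 Mb
  calls[401:1400, 2] <- -1L    # 15 Mb
  calls[1200:2000, 3] <- 1L    # 12 Mb
  grid <- shared_grid(calls, bins)
  key <- apply(calls, 1, paste, collapse = ",")
  first <- c(1, which(key[-1] != key[-2000]) + 1)
  last <- c(first[-1] - 1, 2000)
  keep <- (last - first + 1) * 15000 >= 5e6
  expect_equal(grid$regions$first_bin, first[keep])
})

test_that("spatial categories count samples sharing the same call", {
  rc <- rbind(c(-1L, -1L, 0L, 1L),
              c(-1L, -1L, 0L, 0L),
              c(-1L, 0L, 0L, 0L),
              c(-1L, 0L, -1L, 0L))
  colnames(rc) <- paste0("r", 1:4)
  cl <- classify_spatial(rc)
  expect_equal(cl$category[cl$region == "r1"], "all")
  expect_equal(cl$category[cl$region == "r2"], "some")
  expect_equal(cl$category[cl$region == "r3"], "one")
  expect_equal(cl$category[cl$region == "r4"], "one")
  # a region with loss in some samples and gain in another yields two CNAs
  rc2 <- rbind(c(-1L), c(1L), c(-1L), c(0L))
  cl2 <- classify_spatial(rc2)
  expect_equal(nrow(cl2), 2L)
  expect_setequal(cl2$category, c("some", "one"))
})

test_that("spatial classification is invariant to sample order", {
  set.seed(17)
  rc <- matrix(sample(c(-1L, 0L, 1L), 40, replace = TRUE), nrow = 4)
  colnames(rc) <- paste0("r", 1:10)
  a <- classify_spatial(rc)
  b <- classify_spatial(rc[c(3, 1, 4, 2), ])
  expect_equal(a[order(a$region, a$direction), c("region", "direction", "category")],
               b[order(b$region, b$direction), c("region", "direction", "category")],
               ignore_attr = TRUE)
})

test_that("temporal categories compare initial and recurrence calls", {
  ini <- c(a = -1L, b = -1L, c = 0L, d = 1L)
  rec <- c(a = -1L, b = 0L, c = -1L, d = 1L)
  cl <- classify_temporal(ini, rec)
  expect_equal(cl$category[cl$region == "a"], "shared")
  expect_equal(cl$category[cl$region == "b"], "initial_only")
  expect_equal(cl$category[cl$region == "c"], "recurrence_only")
  expect_equal(cl$category[cl$region == "d"], "shared")
  # identical profiles are all shared
  expect_true(all(classify_temporal(ini, ini)$category == "shared"))
})

test_that("summaries reproduce integer-percentage reporting", {
  s <- summarize_heterogeneity(c(rep("heterogeneous", 84), rep("all", 40)))
  expect_equal(s$n[s$category == "heterogeneous"], 84L)
  expect_equal(s$percent[s$category == "heterogeneous"], 68)
  expect_equal(s$percent[s$category == "all"], 32)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s$n), 124L)

  s2 <- summarize_heterogeneity(c(rep("shared", 99), rep("initial_only", 31),
                                  rep("recurrence_only", 77)))
  expect_equal(s2$percent[s2$category == "shared"], 48)
  expect_equal(s2$percent[s2$category == "initial_only"], 15)
  expect_equal(s2$percent[s2$category == "recurrence_only"], 37)

  expect_equal(summarize_heterogeneity("one")$percent, 100)
  expect_equal(nrow(summarize_heterogeneity(character())), 0L)
})

# End-to-end: simulate multi-region counts, run the full bin-to-call pipeline
# per region, and recover the planted spatial categories on the shared grid.
test_that("planted spatial categories are recovered through the full pipeline", {
  bins <- make_genome(3, 30e6, 15e3, seed = 41)  # 3 x 2000 bins
  bins$chrom <- c("1", "10", "13")[as.integer(bins$chrom)]
  trunk <- cna_event("1", 1, 15e6, 1L)
  s10 <- cna_event("10", 15000001, 30e6, 1L)
  s13 <- cna_event("13", 1, 15e6, 1L)
  # nested clones: every clone carries the truncal event, so it stays clonal
  arch <- clonal_architecture(
    list(trunk_only = trunk, with_s10 = rbind(trunk, s10),
         with_s13 = rbind(trunk, s13)),
    c(0.10, 0.45, 0.45), purity = 0.6)
  presence <- rbind(rep(TRUE, 4),
                    c(TRUE, TRUE, TRUE, FALSE),
                    c(FALSE, TRUE, FALSE, FALSE))
  mr <- simulate_multiregion(arch, 4, mixing_noise = 0, seed = 42,
                             presence = presence)
  thr <- calling_thresholds(0.30, purity = 0.6)
  calls <- sapply(seq_along(mr$regions), function(r) {
    cts <- simulate_bin_counts(bins, mr$regions[[r]], 120, seed = 400 + r)
    prof <- correct_profile(cts, bins)
    rc <- recenter_profile(prof, segment_profile(prof, bins, seed = 500 + r))
    segs <- call_segments(rc$segments, thr, purity = 0.6)
    segments_to_calls(segs, bins)
  })
  grid <- shared_grid(calls, bins)
  cl <- classify_spatial(grid$calls, grid$regions)
  got <- function(ch, a, b) {
    i <- grid$regions$chrom == ch & grid$regions$start >= a &
      grid$regions$end <= b
    cl$category[cl$region %in% grid$regions$label[i] & cl$direction == -1L]
  }
  expect_true(all(got("1", 1, 15e6) == "all"))      # truncal never subclonal
  expect_true(all(got("10", 15000001, 30e6) == "some"))
  expect_true(all(got("13", 1, 15e6) == "one"))
})

test_that("planted temporal categories are recovered through the full pipeline", {
  bins <- make_genome(3, 30e6, 15e3, seed = 51)  # chr4 stays diploid so
  bins$chrom <- c("1", "4", "10")[as.integer(bins$chrom)]  # CNAs cover < 50%
  trunk <- cna_event("1", 1, 15e6, 1L)
  arch <- clonal_architecture(list(trunk = trunk), 0.9, purity = 0.6)
  pair <- simulate_recurrence(arch,
    gained_events = list(g10 = cna_event("10", 15000001, 30e6, 1L)),
    gained_prevalences = 0.6)
  thr <- calling_thresholds(0.30, purity = 0.6)
  profiles <- mapply(function(a, k) {
    cts <- simulate_bin_counts(bins, a, 120, seed = 600 + k)
    prof <- correct_profile(cts, bins)
    rc <- recenter_profile(prof, segment_profile(prof, bins, seed = 700 + k))
    segments_to_calls(call_segments(rc$segments, thr, purity = 0.6), bins)
  }, list(pair$initial, pair$recurrence), 1:2)
  calls <- profiles
  colnames(calls) <- c("initial", "recurrence")
  grid <- shared_grid(calls, bins)
  cl <- classify_temporal(grid$calls[1, ], grid$calls[2, ], grid$regions)
  lab10 <- grid$regions$label[grid$regions$chrom == "10" &
                                grid$regions$start >= 15000001]
  lab1 <- grid$regions$label[grid$regions$chrom == "1" &
                               grid$regions$end <= 15e6]
  expect_true(all(cl$category[cl$region %in% lab10] == "recurrence_only"))
  expect_true(all(cl$category[cl$region %in% lab1] == "shared"))
})
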