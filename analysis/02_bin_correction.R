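#!/usr/bin/env Rscript
# Bin-level correction demo: simulate a tumor profile with injected GC and
# mappability bias, apply blacklist/mappability filtering and the alternating
# GC/mappability loess, and quantify the noise reduction.

suppressPackageStartupMessages(library(lggcna))
dir.create("results", showWarnings = FALSE)

bins <- make_genome(4, 30e6, 15e3, blacklist_fraction = 0.02, seed = 7)
arch <- clonal_architecture(
  list(trunk = rbind(cna_event("1", 1, 15e6, 1L),
                     cna_event("3", 15000001, 30e6, 3L))),
  prevalences = 1, purity = 0.6)
counts <- simulate_bin_counts(bins, arch, mean_depth_per_bin = 60, seed = 8,
                              bias = bias_model(gc_amplitude = 0.8))

usable <- filter_bins(counts, bins)
raw <- normalize_log2(counts, usable)
corrected_counts <- loess_correct(counts, bins, usable)
prof <- normalize_log2(corrected_counts, usable)

v_raw <- var(raw$log2_ratio[raw$usable])
v_cor <- var(prof$log2_ratio[prof$usable])
rho_gc <- cor(prof$log2_ratio[prof$usable], bins$gc[prof$usable],
              method = "spearman")

cat("GC/mappability loess correction on a biased 0.6-purity profile:\n")
cat(sprintf("  usable bins: %d of %d\n", sum(usable), nrow(bins)))
cat(sprintf("  log2 variance: raw %.4f -> corrected %.4f (%.0f%% reduction)\n",
            v_raw, v_cor, 100 * (1 - v_cor / v_raw)))
cat(sprintf("  residual GC correlation (Spearman): %.3f\n", rho_gc))

write_matrix(cbind(log2_ratio = prof$log2_ratio, usable = prof$usable),
             bins, "results/corrected_profile.tsv")
cat("  profile written to results/corrected_profile.tsv\n")
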