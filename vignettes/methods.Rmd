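---
title: "Copy-number calling and survival scanning for shallow WGS of low-grade glioma: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling and survival scanning for shallow WGS of low-grade glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lggcna)
```

# The problem

Diffuse low-grade gliomas carry chromosomal copy-number aberrations (CNAs)
with opposite prognostic meaning: the 1p/19q co-deletion is favorable and
truncal, while loss of distal 10q (10q25.2–qter, often as a whole-chromosome
loss) is unfavorable and frequently subclonal — present in only a fraction of
the tumor cells, and sometimes surfacing only in the recurrent tumor. The
package implements the complete analysis chain for detecting such events
from shallow whole-genome sequencing (sWGS) depth-of-coverage data and
relating them to overall survival, exercised end-to-end on synthetic cohorts
with known ground truth.

# The copy-number mixture model

All calling rests on one identity. A specimen is a mixture of normal diploid
cells and tumor cells (purity $p$); a CNA with integer total copy number
$c \neq 2$ carried by a fraction $f$ of the tumor cells shifts the
population-average copy number of the affected bins to

$$ m = 2\,(1 - p f) + c\,p f = 2 + p f\,(c - 2), $$

so the expected log2 ratio against the diploid baseline is
$r = \log_2(m/2)$. Everything else is inversion or thresholding of this
identity:

* **Calling thresholds** (`calling_thresholds`). The minimum detectable
  tumor-cell fraction `f_min = 0.30` and single-copy events ($c = 3$ gain,
  $c = 1$ loss) give, at purity 1, $\log_2 1.15 = 0.2016$ and
  $\log_2 0.85 = -0.2345$ — conventionally printed as 0.20 and −0.23. Both
  the exact and the two-decimal rounded thresholds are available
  (`mode = "exact"` / `"rounded"`); segments are compared with strict
  inequalities, so a mean of exactly −0.23 is still normal.
* **Cell-fraction estimation** (`estimate_cell_fraction`) inverts the model:
  $f = 2\,(2^r - 1)/(c - 2)$, divided by purity. Single-copy events are
  assumed unless $c$ is supplied, because depth-of-coverage data alone do
  not identify $c$. Estimates above 1.05 before clipping, or with a
  deflection sign contradicting $c$, are flagged model-inconsistent.
* **Anchored fractions** (`anchored_fraction`). Dividing the event's
  fraction estimate by that of a clonal anchor event (the 1p/19q
  co-deletion in this disease) cancels purity. This is how an intermediate
  10q deflection is read as a loss in roughly 30–35% of the tumor cells.

# From counts to calls

**Forward model and simulator.** `simulate_bin_counts` draws the count of
bin $b$ as Poisson with mean
$\lambda_b = \text{depth} \times \text{bias}(gc_b, map_b) \times m_b/2$
(negative-binomial optionally, for robustness checks). The injected bias is
a unimodal GC component (Gaussian-shaped, peaking at GC 0.45, amplitude 0.5
by default) times mappability, normalized to mean 1. The bin grid
(`make_genome`) is 15 kb — the resolution at which uniquely aligned sWGS
reads are counted — with GC and mappability drawn from an isochore-like
spatial process (≈150 kb correlation length plus bin-level jitter, GC
confined to [0.3, 0.7], mappability to [0.5, 1]). The fast mixing matters:
every chromosome must span the common GC range, as real genomes do,
otherwise GC would be confounded with chromosome-scale CNAs and any GC
correction could absorb copy-number signal.

**Correction** (`filter_bins`, `loess_correct`, `normalize_log2`). Bins are
dropped when blacklisted, below mappability 0.8, or zero across the cohort.
The "simultaneous" GC/mappability correction is realized as alternating
one-dimensional robust loess fits (span 0.65, degree 2, two rounds) of the
log-scale counts on GC and on mappability; the combined fitted bias is
normalized to mean 1 and divided out, which makes the correction invariant
to global rescaling of the counts. A constant covariate is skipped with a
warning. Normalization centers log2 ratios on the median log2 usable count.

**Segmentation and recentering** (`segment_profile`, `recenter_profile`).
Segmentation is recursive binary splitting: the split maximizing the
two-sample t statistic is accepted when a within-chromosome permutation test
(default 100 shuffles) gives p < 0.01, with a minimum segment length of 5
usable bins; it is deterministic given a seed. Bin-level median centering is
biased by up to a per-bin noise SD once an appreciable part of the genome is
aberrant — the bin median lands in the tail of the diploid cloud — so after
segmentation the profile is recentered on the per-bin median of segment
means, which are nearly noise-free. The diploid baseline is then correct
whenever aberrations cover less than half of the usable genome; beyond that
the centering (like any ratio-based method without an external anchor) is
undefined, and profiles in that regime should be interpreted via the
anchored fractions instead.

**Region calls** (`region_call`, `call_seg_cohort`). A predefined region
(e.g. 1p, 19q excluding the centromere, or distal 10q) is called lost/gained
when same-direction segments cover at least 90% of its length. A
whole-chromosome loss therefore counts as carrying any distal region — the
inclusion direction used throughout. External segmented cohorts (TCGA-style
SEG tables) are called the same way, with the same thresholds.

# The survival scan

`reduce_to_regions` collapses bins whose call vector across the cohort is
constant into maximal common regions. Per region, carriers (call equal to
the scanned direction; losses by default, since gains showed no survival
association in this disease) are compared with the rest of the cohort by a
log-rank test computed from first principles, with significance estimated
by permutation (default 10,000): outcome pairs are permuted jointly across
patients, call labels fixed, and $p = (1 + \#\{T^\ast \ge T\})/(B+1)$, never
exactly zero. Permuting outcomes rather than calls preserves the
genome-wide correlation structure of calls within patients. Per-region
permutation streams are derived from one master seed by region index, so
results are reproducible regardless of evaluation order.

Consecutive same-chromosome regions with p < 0.05 are fused into final
regions and re-tested. A patient carries a fused region when it carries
*any* constituent region. The stricter alternative — requiring carried
constituents to cover ≥90% of the fused span — is available
(`fuse_carrier = "span"`) but not the default: under that rule fusion can
only shrink the carrier set, so a strongly significant region fused with a
weaker neighbour (the distal 10q region merging with proximal chromosome-10
regions driven by whole-chromosome losses) loses most of its carriers and
the re-test throws the discovery away. Benjamini–Hochberg correction is
applied across final regions in discovery mode; `validate_regions` re-tests
fixed a-priori regions without fusion and adjusts with step-down
Holm–Bonferroni. Hazard ratios with Wald 95% intervals come from a
one-covariate Cox partial likelihood (Breslow ties, via the survival
package); group medians from the Kaplan–Meier estimator (median = smallest
time with survival ≤ 0.5). `stratify_four_groups` forms the
{10q-only, 1p/19q-only, both, neither} prognostic groups, where co-deletion
requires loss of both arms.

# Heterogeneity classification

For one patient's samples — spatially distinct same-surgery regions or an
initial/recurrence pair — `shared_grid` reduces the calls to common regions
and drops regions under 5 Mbp (applied to the reduced regions, not raw
segments). A CNA's identity across samples is (shared region, direction);
a region lost in one sample and gained in another therefore counts as two
CNAs. Spatial categories are *all* / *some* (more than one but not all) /
*one* by the number of samples sharing the call; temporal categories are
*shared* / *initial_only* / *recurrence_only* by set comparison.
`summarize_heterogeneity` reports counts and integer-rounded percentages,
matching the field's reporting style (84 of 124 → 68%).

# The synthetic cohorts

`simulate_lgg_cohort` emulates a 98-patient discovery-style cohort at the
call level on a compact genome restricted to the recurrently aberrant
autosomes (1, 4, 9, 10, 11, 13, 19, 22; GRCh37-like lengths on the 15 kb
grid, chromosome 10 ending at 135,435,000 so the distal region
112,950,001–135,435,000 sits exactly on the grid). Patients fall into the
four prognostic groups with probabilities 0.44 / 0.38 / 0.15 / 0.03;
10q carriers lose the whole chromosome with probability 5/18; recurrent
passenger losses and gains (9p 21%, 13q 17%, 22q 31%, chr4 18%, 11p 13%,
11q and 10p gains 10%) are drawn independently and carry no survival
effect. Survival is exponential with baseline median 200.4 months
(16.7 years, the no-10q-loss group), hazard ratios 2.91 for distal 10q loss
and 0.30 for the co-deletion acting multiplicatively, and administrative
censoring at 240 months, which yields ≈47–48% deceased. Default purity is
0.6, matching a >60% tumor-cell selection rule.

Multi-region sampling (`simulate_multiregion`) keeps the truncal clone in
every region and renormalizes the prevalences of the clones present in a
region to the whole-tumor total — a region is a full-density sample of its
local clone mixture. Recurrences (`simulate_recurrence`) inherit all
non-lost clones and add gained clones private to the recurrence; ground
truth categories follow by construction.

What the generators do *not* emulate: read-level artifacts (FFPE fragment
length, duplicates, mapping errors are summarized into the bin-level bias
and blacklist), allele-specific signals (copy-neutral LOH is invisible to
depth-of-coverage data), sex chromosomes, inter-chromosomal correlation of
passenger events, and non-exponential hazards. Passing tests therefore
demonstrate correctness of the analysis chain under its stated model, not
performance on any particular real cohort.

# Numerical choices and scales

* Coordinates are 1-based inclusive internally; BED input is converted at
  the boundary. Time is months throughout.
* Segmentation defaults: alpha 0.01, 100 permutations per split, minimum 5
  bins — chosen so a −1 step of 50 bins at noise SD 0.1 is localized within
  ±2 bins, while a flat profile stays a single segment.
* Administrative censoring at a horizon (240 months by default, within the
  follow-up range of long archival cohorts) replaces a second random
  censoring process; an optional `censoring_rate` adds uniform random
  censoring for robustness checks.
* Property tests and the bundled analyses run at desk scale: permutation
  counts of 500–1,000 where the reference setting is 10,000 (the p-value
  floor $(B+1)^{-1}$ is the only consequence), cohorts of 98–5,000
  patients, genomes of a few thousand bins. The analysis scripts state the
  sizes they use.
* Tie-breaks: equal loss and gain coverage of a region resolves to loss
  with a warning (mixed-call regions do not arise in practice); the
  log-rank permutation comparison uses ≥ with a 1e-12 tolerance so exact
  ties count against rejection.

# Known limitations

The threshold model assumes single-copy events against a diploid baseline;
high-level amplifications or homozygous deletions bias fraction estimates
(flagged, not resolved). Centering requires aberrations to cover < 50% of
the usable genome. The scan tests one region at a time against
carriers-vs-rest; it is a univariate screen, not a multivariable model.
The 30% calibration of the printed thresholds does not state whether purity
is factored in; the implementation keeps `f_min` and `purity` separate so
either reading can be reproduced (the printed values correspond to
purity 1).
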