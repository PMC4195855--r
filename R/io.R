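# Tab-separated file interfaces. All files carry a one-line header, use dot
# decimal separators and 1-based inclusive coordinates internally; BED input
# (0-based half-open) is converted at the boundary.

#' Default run configuration
#'
#' The defaults reproduce the reference analysis settings: 15 kb bins, a
#' minimum detectable tumor-cell fraction of 0.30 (exact thresholds
#' log2(1.15)/log2(0.85), printed conventionally as 0.20/-0.23), 10,000
#' permutations, fusion at p < 0.05, a 5 Mbp minimum region for heterogeneity
#' comparisons, a 90% region-overlap rule, BH adjustment for discovery and
#' Holm for validation.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(bin_width = 15000L,
       f_min = 0.30,
       thresholds_mode = "exact",
       purity = 0.6,
       n_perm = 10000L,
       alpha_fuse = 0.05,
       min_region_bp = 5e6,
       min_cover = 0.90,
       min_mappability = 0.8,
       loess_span = 0.65,
       loess_iterations = 2L,
       adjust_discovery = "bh",
       adjust_validation = "holm")
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a bin annotation table
#'
#' Six-column TSV (`chrom`, `start`, `end`, `gc`, `mappability`,
#' `blacklisted`), BED-like but with 1-based inclusive coordinates.
#'
#' @param path file path.
#' @return bin table (for the reader).
#' @export
read_bins <- function(path) {
  bins <- read_tsv(path)
  bins$chrom <- as.character(bins$chrom)
  bins$blacklisted <- as.logical(bins$blacklisted)
  validate_bins(bins)
}

#' @rdname read_bins
#' @param bins bin table to write.
#' @export
write_bins <- function(bins, path) {
  validate_bins(bins)
  write_tsv(bins, path)
}

#' Read / write a bins-by-samples numeric matrix (counts, log2 ratios, calls)
#'
#' First three columns are `chrom`, `start`, `end`; remaining columns are one
#' per sample.
#'
#' @param path file path.
#' @return list with `bins_key` (chrom/start/end data.frame) and `values`
#'   (numeric matrix).
#' @export
read_matrix <- function(path) {
  x <- read_tsv(path)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) stop_field("matrix file lacks chrom/start/end columns")
  vals <- as.matrix(x[, setdiff(names(x), need), drop = FALSE])
  if (any(duplicated(colnames(vals)))) stop_field("duplicate sample ids in matrix file")
  list(bins_key = x[, need], values = vals)
}

#' @rdname read_matrix
#' @param bins bin table supplying the coordinate key.
#' @param values matrix to write (bins x samples).
#' @export
write_matrix <- function(values, bins, path) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(bins)) stop_field("values do not align to bins")
  write_tsv(cbind(bins[, c("chrom", "start", "end")], as.data.frame(values)),
            path)
}

#' Read / write a patient survival table
#'
#' Columns `id`, `time_months`, `event` (0/1). Duplicate ids, missing columns
#' or event flags outside \{0, 1\} are rejected.
#'
#' @param path file path.
#' @return survival data.frame (for the reader).
#' @export
read_survival <- function(path) {
  x <- read_tsv(path)
  need <- c("id", "time_months", "event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_field("survival file is missing columns: %s",
                               paste(miss, collapse = ", "))
  if (any(duplicated(x$id))) stop_field("duplicate patient ids in survival file")
  if (!all(x$event %in% c(0, 1))) stop_field("event flags must be 0 or 1")
  x$id <- as.character(x$id)
  x
}

#' @rdname read_survival
#' @param surv survival table to write.
#' @export
write_survival <- function(surv, path) write_tsv(surv, path)

#' Read / write SEG-format segment tables
#'
#' The writer emits `sample`, `chrom`, `start`, `end`, `n_bins`, `seg_mean`
#' plus any extra columns (e.g. `call`, `cell_fraction`). The reader also
#' accepts the TCGA level-3 dialect (header `Sample`, `Chromosome`, `Start`,
#' `End`, `Num_Probes`, `Segment_Mean`), strips `chr` prefixes, and passes
#' unknown columns through with a warning.
#'
#' @param path file path.
#' @return segment data.frame with canonical column names (for the reader).
#' @export
read_seg <- function(path) {
  x <- read_tsv(path)
  canon <- c(sample = "sample", Sample = "sample", ID = "sample",
             chrom = "chrom", Chromosome = "chrom", chromosome = "chrom",
             start = "start", Start = "start", loc.start = "start",
             end = "end", End = "end", loc.end = "end",
             n_bins = "n_bins", Num_Probes = "n_bins", num.mark = "n_bins",
             seg_mean = "seg_mean", Segment_Mean = "seg_mean",
             seg.mean = "seg_mean")
  nm <- names(x)
  mapped <- canon[nm]
  known <- !is.na(mapped)
  extra <- nm[!known & !nm %in% c("call", "cell_fraction")]
  if (length(extra)) {
    warning(sprintf("ignoring unrecognized SEG columns: %s",
                    paste(extra, collapse = ", ")))
  }
  names(x)[known] <- mapped[known]
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_field("SEG file is missing columns: %s",
                               paste(miss, collapse = ", "))
  x$chrom <- sub("^chr", "", as.character(x$chrom))
  x$sample <- as.character(x$sample)
  x
}

#' @rdname read_seg
#' @param seg segment table to write.
#' @export
write_seg <- function(seg, path) {
  need <- c("sample", "chrom", "start", "end")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop_field("SEG table is missing columns: %s",
                               paste(miss, collapse = ", "))
  write_tsv(seg, path)
}

#' Read region definitions (BED or 1-based table dialect)
#'
#' BED input (`dialect = "bed"`, no header: chrom, start, end, optional name)
#' uses 0-based half-open coordinates and is converted to the 1-based
#' inclusive internal convention; the `"table"` dialect is a headered TSV
#' with columns `label`, `chrom`, `start`, `end` already 1-based inclusive.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"table"`.
#' @return data.frame `label`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_regions <- function(path, dialect = c("table", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    x <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (ncol(x) < 3) stop_field("BED file needs >= 3 columns")
    out <- data.frame(
      label = if (ncol(x) >= 4) as.character(x[[4]]) else
        sprintf("%s:%d-%d", x[[1]], x[[2]] + 1, x[[3]]),
      chrom = sub("^chr", "", as.character(x[[1]])),
      start = as.double(x[[2]]) + 1,
      end = as.double(x[[3]]),
      stringsAsFactors = FALSE)
  } else {
    x <- read_tsv(path)
    need <- c("label", "chrom", "start", "end")
    miss <- setdiff(need, names(x))
    if (length(miss)) stop_field("region table is missing columns: %s",
                                 paste(miss, collapse = ", "))
    out <- data.frame(label = as.character(x$label),
                      chrom = sub("^chr", "", as.character(x$chrom)),
                      start = as.double(x$start), end = as.double(x$end),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$start > out$end)
  if (length(bad)) {
    stop_field("region start > end at line %d of %s", bad[1] + (dialect == "table"),
               path)
  }
  out
}
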