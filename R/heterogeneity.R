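#' Shared region grid for one patient's samples
#'
#' Reduces the bin-level calls of all samples from one patient (spatially
#' distinct regions and/or initial-recurrence pairs) to common regions and
#' drops regions smaller than `min_region_bp` (default 5 Mbp), the minimum
#' size considered for heterogeneity comparisons.
#'
#' @param calls integer matrix bins x samples of -1/0/+1 calls (>= 2 samples).
#' @param bins bin annotation table.
#' @param min_region_bp minimum region size in bp (default 5e6).
#' @return list with `regions` and `calls` (samples x regions) as in
#'   [reduce_to_regions()], restricted to regions of at least `min_region_bp`.
#' @export
shared_grid <- function(calls, bins, min_region_bp = 5e6) {
  calls <- as.matrix(calls)
  if (ncol(calls) < 2) stop_field("need >= 2 samples for a shared grid")
  red <- reduce_to_regions(calls, bins)
  keep <- (red$regions$end - red$regions$start + 1) >= min_region_bp
  list(regions = red$regions[keep, , drop = FALSE],
       calls = red$calls[, keep, drop = FALSE])
}

#' Classify CNAs across spatially distinct regions of one tumor
#'
#' Every (region, direction) aberration detected in at least one sample is
#' categorized by how many samples share the same non-normal call: present in
#' `"all"` regions, in `"some"` (more than one but not all), or in `"one"`.
#'
#' @param region_calls integer matrix samples x regions on a shared grid
#'   (from [shared_grid()]).
#' @param regions matching region table (optional, used for labels).
#' @return data.frame with `region`, `direction` (-1/+1), `n_detected`,
#'   `n_samples`, `category`.
#' @export
classify_spatial <- function(region_calls, regions = NULL) {
  region_calls <- as.matrix(region_calls)
  n_samples <- nrow(region_calls)
  if (n_samples < 2) stop_field("need >= 2 spatial samples")
  labels <- colnames(region_calls) %||% as.character(seq_len(ncol(region_calls)))
  if (!is.null(regions)) labels <- regions$label
  rows <- list()
  for (j in seq_len(ncol(region_calls))) {
    for (dir in c(-1L, 1L)) {
      k <- sum(region_calls[, j] == dir)
      if (k == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        region = labels[j], direction = dir, n_detected = k,
        n_samples = n_samples,
        category = if (k == n_samples) "all" else if (k == 1) "one" else "some",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region = character(), direction = integer(),
                      n_detected = integer(), n_samples = integer(),
                      category = character()))
  }
  do.call(rbind, rows)
}

#' Classify CNAs between an initial tumor and its paired recurrence
#'
#' Per (region, direction) on the shared grid: detected in both profiles ->
#' `"shared"`, only in the initial tumor -> `"initial_only"`, only in the
#' recurrence -> `"recurrence_only"`.
#'
#' @param initial_calls,recurrence_calls integer call vectors (-1/0/+1) on a
#'   shared region grid.
#' @param regions matching region table (optional, used for labels).
#' @return data.frame with `region`, `direction`, `category`.
#' @export
classify_temporal <- function(initial_calls, recurrence_calls, regions = NULL) {
  if (length(initial_calls) != length(recurrence_calls)) {
    stop_field("initial and recurrence call vectors must share one grid")
  }
  labels <- names(initial_calls) %||% as.character(seq_along(initial_calls))
  if (!is.null(regions)) labels <- regions$label
  rows <- list()
  for (j in seq_along(initial_calls)) {
    for (dir in c(-1L, 1L)) {
      in_i <- initial_calls[j] == dir
      in_r <- recurrence_calls[j] == dir
      if (!in_i && !in_r) next
      rows[[length(rows) + 1]] <- data.frame(
        region = labels[j], direction = dir,
        category = if (in_i && in_r) "shared"
                   else if (in_i) "initial_only" else "recurrence_only",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region = character(), direction = integer(),
                      category = character()))
  }
  do.call(rbind, rows)
}

#' Summarize CNA heterogeneity categories
#'
#' Counts and fractions per category, with integer-rounded percentages
#' (matching the conventional reporting style, e.g. 84 of 124 CNAs -> 68%).
#'
#' @param categories character vector of per-CNA category assignments (or a
#'   classification data.frame with a `category` column).
#' @return data.frame `category`, `n`, `fraction`, `percent`; zero rows for
#'   empty input.
#' @export
summarize_heterogeneity <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (!length(categories)) {
    return(data.frame(category = character(), n = integer(),
                      fraction = double(), percent = double()))
  }
  tab <- table(categories)
  data.frame(category = names(tab),
             n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             percent = round(100 * as.numeric(tab) / sum(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}
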