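#' Spawn spatially distinct same-surgery regions from one architecture
#'
#' The truncal clone (by convention the first) is present in every region;
#' every subclone is present in only a subset of regions, with its prevalence
#' jittered by `mixing_noise` where present. A region samples the local clone
#' mixture at the full tumor density: the prevalences of the clones present
#' in a region are renormalized so their total matches the whole-tumor clone
#' total. This yields known ground-truth spatial categories per event:
#' present in all regions, in more than one but not all, or in exactly one.
#'
#' @param architecture a [clonal_architecture()] describing the whole tumor.
#' @param n_regions number of regions sampled (>= 2).
#' @param mixing_noise SD of the multiplicative (log-normal) jitter applied to
#'   subclone prevalences across regions.
#' @param seed integer seed.
#' @param presence optional logical matrix (clones x regions) fixing which
#'   clone is present in which region; the truncal row must be all TRUE.
#'   Default: random non-empty subsets for each subclone.
#' @return list with `regions` (list of per-region architectures), `presence`
#'   (clones x regions logical matrix) and `truth` (data.frame of events with
#'   their ground-truth spatial category).
#' @export
simulate_multiregion <- function(architecture, n_regions, mixing_noise = 0.05,
                                 seed = 1L, presence = NULL) {
  stopifnot(inherits(architecture, "clonal_architecture"))
  if (n_regions < 2) stop_field("'n_regions' must be >= 2")
  k <- length(architecture$clones)
  with_seed(seed, {
    if (is.null(presence)) {
      presence <- matrix(TRUE, k, n_regions)
      if (k > 1) {
        for (i in 2:k) {
          n_in <- sample.int(n_regions, 1)
          idx <- sample.int(n_regions, n_in)
          presence[i, ] <- FALSE
          presence[i, idx] <- TRUE
        }
      }
    }
    presence <- matrix(as.logical(presence), k, n_regions)
    if (!all(presence[1, ])) stop_field("truncal clone must be present in every region")
    dimnames(presence) <- list(names(architecture$clones),
                               paste0("region_", seq_len(n_regions)))
    regions <- lapply(seq_len(n_regions), function(r) {
      prev <- architecture$prevalences * presence[, r]
      if (mixing_noise > 0 && k > 1) {
        jitter <- exp(stats::rnorm(k, 0, mixing_noise))
        jitter[1] <- 1
        prev <- prev * jitter
      }
      prev <- prev / sum(prev) * sum(architecture$prevalences)
      clonal_architecture(architecture$clones, prev, architecture$purity)
    })
    truth <- event_presence_truth(architecture, presence)
    list(regions = regions, presence = presence, truth = truth)
  })
}

# Ground-truth spatial category per distinct event across regions.
event_presence_truth <- function(architecture, presence) {
  n_regions <- ncol(presence)
  rows <- list()
  for (i in seq_along(architecture$clones)) {
    ev <- architecture$clones[[i]]
    if (is.null(ev) || nrow(ev) == 0) next
    ev$clone <- names(architecture$clones)[i]
    ev$n_regions_present <- sum(presence[i, ])
    rows[[length(rows) + 1]] <- ev
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = double(), end = double(),
                      copies = integer(), clone = character(),
                      n_regions_present = integer(), category = character()))
  }
  out <- do.call(rbind, rows)
  # an event carried by several clones is present wherever any carrier is
  key <- paste(out$chrom, out$start, out$end, sign(out$copies - 2))
  agg <- tapply(out$n_regions_present, key, max)
  out <- out[!duplicated(key), ]
  out$n_regions_present <- as.integer(agg[paste(out$chrom, out$start, out$end,
                                                sign(out$copies - 2))])
  out$category <- ifelse(out$n_regions_present == n_regions, "all",
                         ifelse(out$n_regions_present == 1, "one", "some"))
  rownames(out) <- NULL
  out
}

#' Derive a paired recurrent tumor from an initial architecture
#'
#' The recurrence inherits all clones of the initial tumor except those named
#' in `lost_clones`; `gained_events` are added as new clones private to the
#' recurrence. Ground-truth temporal categories per event follow: events only
#' in lost clones are "initial_only", gained events are "recurrence_only",
#' everything else is "shared".
#'
#' @param initial_architecture a [clonal_architecture()].
#' @param gained_events named list of event tables gained at recurrence.
#' @param gained_prevalences prevalences of the gained clones (recycled).
#' @param lost_clones character vector of clone names absent from the
#'   recurrence.
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return list with `initial`, `recurrence` (architectures) and `truth`
#'   (events with ground-truth temporal category).
#' @export
simulate_recurrence <- function(initial_architecture,
                                gained_events = list(),
                                gained_prevalences = 0.4,
                                lost_clones = character(),
                                seed = 1L) {
  stopifnot(inherits(initial_architecture, "clonal_architecture"))
  nm <- names(initial_architecture$clones)
  bad <- setdiff(lost_clones, nm)
  if (length(bad)) stop_field("unknown clone(s): %s", paste(bad, collapse = ", "))
  if (nm[1] %in% lost_clones) stop_field("the truncal clone cannot be lost")
  keep <- !(nm %in% lost_clones)
  clones_rec <- initial_architecture$clones[keep]
  prev_rec <- initial_architecture$prevalences[keep]
  if (length(gained_events)) {
    if (is.null(names(gained_events))) {
      names(gained_events) <- paste0("gained", seq_along(gained_events))
    }
    gp <- rep_len(gained_prevalences, length(gained_events))
    clones_rec <- c(clones_rec, gained_events)
    prev_rec <- c(prev_rec, gp)
    if (sum(prev_rec) > 1) prev_rec <- prev_rec / sum(prev_rec)
  }
  recurrence <- clonal_architecture(clones_rec, prev_rec,
                                    initial_architecture$purity)
  truth <- temporal_truth(initial_architecture, lost_clones, gained_events)
  list(initial = initial_architecture, recurrence = recurrence, truth = truth)
}

temporal_truth <- function(initial, lost_clones, gained_events) {
  rows <- list()
  for (i in seq_along(initial$clones)) {
    ev <- initial$clones[[i]]
    if (is.null(ev) || nrow(ev) == 0) next
    ev$category <- if (names(initial$clones)[i] %in% lost_clones) {
      "initial_only"
    } else {
      "shared"
    }
    rows[[length(rows) + 1]] <- ev
  }
  for (i in seq_along(gained_events)) {
    ev <- gained_events[[i]]
    if (is.null(ev) || nrow(ev) == 0) next
    ev$category <- "recurrence_only"
    rows[[length(rows) + 1]] <- ev
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = double(), end = double(),
                      copies = integer(), category = character()))
  }
  out <- do.call(rbind, rows)
  # shared status wins if the same event sits in both a kept and a lost clone
  key <- paste(out$chrom, out$start, out$end, sign(out$copies - 2))
  pick <- tapply(seq_len(nrow(out)), key, function(ix) {
    sh <- ix[out$category[ix] == "shared"]
    if (length(sh)) sh[1] else ix[1]
  })
  out <- out[sort(unlist(pick)), ]
  rownames(out) <- NULL
  out
}
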