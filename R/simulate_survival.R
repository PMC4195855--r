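#' Define an exponential proportional-hazards survival model
#'
#' Event times are exponential with rate `log(2) / baseline_median_months`
#' multiplied by the product of the hazard ratios whose predicate columns are
#' TRUE for a patient. Censoring is administrative at `horizon_months`
#' (patients still alive at the horizon are censored there), optionally with
#' an extra independent random-censoring fraction.
#'
#' @param baseline_median_months median survival of the baseline group, in
#'   months. Default 200.4 (16.7 years, the no-10q-loss group of a low-grade
#'   glioma cohort).
#' @param hazard_ratios named numeric vector of positive hazard ratios; names
#'   are logical columns of the patient status table.
#' @param horizon_months administrative censoring horizon (default 240, i.e.
#'   20 years of follow-up).
#' @param censoring_rate fraction of patients additionally censored at a
#'   uniform random time before the horizon, in \[0, 1).
#' @return list of class `survival_model`.
#' @export
survival_model <- function(baseline_median_months = 16.7 * 12,
                           hazard_ratios = c(),
                           horizon_months = 240,
                           censoring_rate = 0) {
  assert_positive(baseline_median_months, "baseline_median_months")
  assert_positive(horizon_months, "horizon_months")
  assert_prob(censoring_rate, "censoring_rate", open_right = TRUE)
  if (length(hazard_ratios)) {
    if (is.null(names(hazard_ratios)) || any(!nzchar(names(hazard_ratios)))) {
      stop_field("'hazard_ratios' must be a named vector")
    }
    if (any(hazard_ratios <= 0)) stop_field("hazard ratios must be positive")
  }
  structure(list(baseline_median_months = baseline_median_months,
                 hazard_ratios = hazard_ratios,
                 horizon_months = horizon_months,
                 censoring_rate = censoring_rate),
            class = "survival_model")
}

#' Simulate survival outcomes tied to copy-number status
#'
#' @param status data.frame with a column `id` plus one logical (or 0/1)
#'   column per predicate named in the model's `hazard_ratios`.
#' @param model a [survival_model()].
#' @param seed integer seed.
#' @return data.frame `id`, `time_months`, `event` (1 = deceased).
#' @export
simulate_survival <- function(status, model, seed = 1L) {
  stopifnot(inherits(model, "survival_model"))
  if (!"id" %in% names(status)) stop_field("'status' needs an 'id' column")
  n <- nrow(status)
  log_hr <- rep(0, n)
  for (nm in names(model$hazard_ratios)) {
    if (!nm %in% names(status)) {
      stop_field("status table lacks predicate column '%s'", nm)
    }
    log_hr <- log_hr + as.numeric(as.logical(status[[nm]])) *
      log(model$hazard_ratios[[nm]])
  }
  rate <- log(2) / model$baseline_median_months * exp(log_hr)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate)
    t_cens <- rep(model$horizon_months, n)
    if (model$censoring_rate > 0) {
      drop <- stats::runif(n) < model$censoring_rate
      t_cens[drop] <- stats::runif(sum(drop), 0, model$horizon_months)
    }
    data.frame(id = status$id,
               time_months = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}
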