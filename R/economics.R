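# Threshold-sweep diagnostic yield and cost-efficiency tables: cumulative
# colonoscopies and cancers, direct cost, cost per cancer, and per-score
# detection rates.

# Round half up (the published tables round 0.5 away from zero, unlike R's
# banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Economics configuration
#'
#' @param tariff Cost per colonoscopy in EUR (default 530, the national
#'   public tariff with sedation).
#' @param total_patients,total_cancers Cohort denominators for cumulative
#'   percentages; default \code{NA} derives them from the data.
#' @return List of class \code{economics_config}.
#' @export
economics_config <- function(tariff = 530, total_patients = NA,
                             total_cancers = NA) {
  stopifnot(tariff > 0)
  structure(list(tariff = tariff, total_patients = total_patients,
                 total_cancers = total_cancers),
            class = "economics_config")
}

#' Cumulative detection and cost table over score thresholds
#'
#' For each threshold t (descending), counts the colonoscopies and cancers
#' among patients with value >= t and derives the cumulative detection and
#' workload percentages (one decimal, half-up), the direct cost (count times
#' tariff, exact), the cost per cancer detected (rounded half-up to whole
#' EUR; undefined — \code{NA} — when no cancers are captured), the
#' colonoscopy reduction relative to the full cohort, and cancers per scope.
#'
#' @param values Per-patient score or FIT values.
#' @param malignant_flags 0/1 malignancy indicators, same length.
#' @param thresholds Numeric thresholds, sorted descending.
#' @param config An \code{\link{economics_config}}.
#' @return Data frame with one row per threshold: \code{threshold},
#'   \code{colonoscopies}, \code{cancers}, \code{detection_cum_pct},
#'   \code{colonoscopy_cum_pct}, \code{direct_cost}, \code{cost_per_cancer},
#'   \code{colonoscopy_reduction_pct}, \code{cancers_per_scope}.
#' @examples
#' fx <- expand_band_fixture(published_band_fixture("complex"))
#' cumulative_table(fx$value, fx$malignant, 12:0)[6, ]  # >=7: 82 scopes, 62 cancers
#' @export
cumulative_table <- function(values, malignant_flags, thresholds,
                             config = economics_config()) {
  if (length(values) != length(malignant_flags))
    stop("'values' and 'malignant_flags' must have the same length")
  if (is.unsorted(rev(thresholds), strictly = FALSE) && length(thresholds) > 1)
    stop("'thresholds' must be sorted descending")
  malignant_flags <- as.integer(malignant_flags)
  total_patients <- if (is.na(config$total_patients)) length(values)
                    else config$total_patients
  total_cancers <- if (is.na(config$total_cancers)) sum(malignant_flags)
                   else config$total_cancers
  if (length(thresholds) == 0)
    return(data.frame(threshold = numeric(0), colonoscopies = numeric(0),
                      cancers = numeric(0), detection_cum_pct = numeric(0),
                      colonoscopy_cum_pct = numeric(0),
                      direct_cost = numeric(0), cost_per_cancer = numeric(0),
                      colonoscopy_reduction_pct = numeric(0),
                      cancers_per_scope = numeric(0)))
  rows <- lapply(thresholds, function(t) {
    sel <- values >= t
    n <- sum(sel)
    cc <- sum(malignant_flags[sel])
    data.frame(
      threshold = t,
      colonoscopies = n,
      cancers = cc,
      detection_cum_pct = round_half_up(100 * cc / total_cancers, 1),
      colonoscopy_cum_pct = round_half_up(100 * n / total_patients, 1),
      direct_cost = n * config$tariff,
      cost_per_cancer = if (cc > 0)
        round_half_up(n * config$tariff / cc) else NA_real_,
      colonoscopy_reduction_pct = round_half_up(100 * (1 - n / total_patients), 1),
      cancers_per_scope = if (n > 0) round_half_up(cc / n, 2) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' FIT-only threshold table
#'
#' \code{\link{cumulative_table}} applied to raw FIT values at the published
#' FIT-only cut-offs (2000, 1000, 200, 50 ng Hb/g by default).
#'
#' @param fit_values Per-patient FIT values.
#' @param malignant_flags 0/1 malignancy indicators.
#' @param config An \code{\link{economics_config}}.
#' @param thresholds FIT cut-offs, descending.
#' @return As \code{\link{cumulative_table}}; empty threshold list gives an
#'   empty table.
#' @export
fit_threshold_table <- function(fit_values, malignant_flags,
                                config = economics_config(),
                                thresholds = c(2000, 1000, 200, 50)) {
  if (length(thresholds) == 0)
    return(cumulative_table(fit_values, malignant_flags, numeric(0), config))
  cumulative_table(fit_values, malignant_flags, thresholds, config)
}

#' Strategy comparison summary
#'
#' Benchmarks named triage strategies (each one row of a threshold table)
#' against universal colonoscopy: colonoscopies, direct cost in kEUR (one
#' decimal), cancers detected, cost per cancer (whole EUR) and cancers per
#' scope (two decimals).
#'
#' @param rows Named list of single-row data frames from
#'   \code{\link{cumulative_table}}; names are the strategy labels.
#' @param config An \code{\link{economics_config}} whose
#'   \code{total_patients}/\code{total_cancers} define the universal row.
#' @return Data frame with one row per strategy plus
#'   \code{"universal colonoscopy"}.
#' @export
strategy_summary <- function(rows, config = economics_config()) {
  if (anyDuplicated(names(rows))) stop("duplicate strategy names")
  if (is.na(config$total_patients) || is.na(config$total_cancers))
    stop("config must carry total_patients and total_cancers")
  one <- function(label, n, cc) {
    if (n == 0) stop("strategy '", label, "' performs no colonoscopies")
    data.frame(
      strategy = label,
      colonoscopies = n,
      direct_cost_keur = round_half_up(n * config$tariff / 1000, 1),
      cancers = cc,
      cost_per_cancer = round_half_up(n * config$tariff / cc),
      cancers_per_scope = round_half_up(cc / n, 2)
    )
  }
  out <- lapply(names(rows), function(nm)
    one(nm, rows[[nm]]$colonoscopies, rows[[nm]]$cancers))
  out <- c(out, list(one("universal colonoscopy", config$total_patients,
                         config$total_cancers)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Malignancy detection rate at each exact score value
#'
#' The fraction of patients at exactly each score value with a malignant
#' lesion; scores with no patients are omitted.
#'
#' @param scores Per-patient score values.
#' @param malignant_flags 0/1 indicators.
#' @return Data frame with \code{score}, \code{n_patients}, \code{n_cancers},
#'   \code{detection_rate} (proportion in [0, 1]), ordered by score.
#' @export
detection_rate_by_score <- function(scores, malignant_flags) {
  if (length(scores) == 0) stop("empty input")
  malignant_flags <- as.integer(malignant_flags)
  sc <- sort(unique(scores))
  out <- data.frame(
    score = sc,
    n_patients = vapply(sc, function(s) sum(scores == s), numeric(1)),
    n_cancers = vapply(sc, function(s) sum(malignant_flags[scores == s]),
                       numeric(1))
  )
  out$detection_rate <- out$n_cancers / out$n_patients
  out
}
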