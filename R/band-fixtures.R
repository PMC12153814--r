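# Exact per-band (patients, cancers) fixtures implied by the published
# cumulative threshold tables, obtained by differencing consecutive
# cumulative rows. Re-cumulating these bands reproduces the printed tables.

# Cumulative rows as printed: thresholds descending.
cumulative_fixture_rows <- function(score_kind) {
  switch(score_kind,
    complex = data.frame(
      threshold = 12:0,
      colonoscopies = c(3, 7, 15, 25, 46, 82, 172, 350, 647, 996, 1300, 1468, 1550),
      cancers = c(3, 7, 14, 21, 38, 62, 83, 96, 105, 111, 111, 111, 111)
    ),
    simplified = data.frame(
      threshold = 7:0,
      colonoscopies = c(5, 18, 59, 232, 557, 970, 1317, 1550),
      cancers = c(3, 10, 19, 46, 75, 90, 100, 111)
    ),
    fit_only = data.frame(
      threshold = c(2000, 1000, 200, 50, 20),
      colonoscopies = c(38, 83, 357, 889, 1550),
      cancers = c(18, 36, 76, 98, 111)
    ),
    stop("unknown score kind: '", score_kind,
         "' (expected complex, simplified or fit_only)")
  )
}

#' Per-band patient and cancer counts from the published cumulative tables
#'
#' Differences the printed cumulative threshold tables of the complex score,
#' the simplified score and the FIT-only strategy into exclusive bands: the
#' band at value \code{v} holds the patients whose score (or FIT stratum
#' lower edge) equals \code{v}. Totals are 1550 patients and 111 cancers for
#' every kind. The FIT-only table prints no explicit bottom row; its lowest
#' band starts at the positivity cut-off of 20 and absorbs the remaining
#' patients and cancers.
#'
#' @param score_kind One of \code{"complex"}, \code{"simplified"},
#'   \code{"fit_only"}.
#' @return Data frame with columns \code{score_value}, \code{n_patients},
#'   \code{n_cancers}, ordered by decreasing \code{score_value}.
#' @examples
#' bands <- published_band_fixture("complex")
#' colSums(bands[, c("n_patients", "n_cancers")])
#' @export
published_band_fixture <- function(score_kind = "complex") {
  cum <- cumulative_fixture_rows(score_kind)
  data.frame(
    score_value = cum$threshold,
    n_patients = diff(c(0, cum$colonoscopies)),
    n_cancers = diff(c(0, cum$cancers)),
    row.names = NULL
  )
}

#' Expand band counts into per-patient pseudo-records
#'
#' Turns a band fixture into one pseudo-record per patient, carrying the band
#' value and a malignancy flag, so that threshold sweeps can be re-computed
#' from patient-level data.
#'
#' @param bands Data frame as returned by \code{\link{published_band_fixture}}.
#' @return Data frame with columns \code{value} and \code{malignant}.
#' @export
expand_band_fixture <- function(bands) {
  stopifnot(all(c("score_value", "n_patients", "n_cancers") %in% names(bands)))
  if (any(bands$n_cancers > bands$n_patients) || any(bands$n_cancers < 0))
    stop("band cancer counts must lie in [0, n_patients]")
  value <- rep(bands$score_value, bands$n_patients)
  malignant <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    c(rep(1L, bands$n_cancers[i]),
      rep(0L, bands$n_patients[i] - bands$n_cancers[i]))
  }))
  data.frame(value = value, malignant = as.integer(malignant))
}
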