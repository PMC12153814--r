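# Composite (complex) and simplified point-based malignancy risk scores, the
# three-tier triage grid, and Youden-optimal thresholds.

fit_band <- function(fit_value) {
  # 1 = <200, 2 = 200-999, 3 = 1000-1999, 4 = >=2000 (ng/mL)
  findInterval(fit_value, c(-Inf, 200, 1000, 2000))
}

check_required <- function(values, fields) {
  for (f in fields) {
    if (is.null(values[[f]]) || any(is.na(values[[f]])))
      stop("missing required field '", f, "' (score after imputation)")
  }
}

#' Complex composite malignancy risk score
#'
#' Five-domain points score for a FIT-positive subject. Age + FIT contributes
#' 1-5 points from a 2 x 4 grid: the FIT band (<200 / 200-999 / 1000-1999 /
#' >=2000 ng/mL) gives 1-4 points and age >= 60 adds one. Education +
#' environment contributes \code{min(2, education band + rural)}, where the
#' education band scores 0 for ISCED 5+, 1 for ISCED 3-4 and 2 for ISCED <= 2,
#' and rural residence adds one; this reproduces the three anchor
#' combinations (higher education + urban = 0, secondary + urban = 1, low
#' education + rural = 2) and extends monotonically between them.
#' Comorbidities score 0/1/2 for none, one-to-two, and three-or-more
#' conditions; antithrombotics score 0/1/2 for none, antiplatelet only, and
#' anticoagulant or combined use; male sex adds one point unless
#' \code{include_sex = FALSE}. The total ranges 1-12 with sex included.
#'
#' @param age Age in years (vectorized, as are all arguments).
#' @param fit_value FIT in ng/mL; must be >= 20 (a FIT-positive subject).
#' @param education ISCED level 0-8.
#' @param environment \code{"rural"} or \code{"urban"}.
#' @param comorbidity_count Number of comorbid conditions.
#' @param antiplatelet,anticoagulant 0/1 indicators.
#' @param sex \code{"male"} or \code{"female"}.
#' @param include_sex Include the optional sex point (default TRUE).
#' @return Data frame of per-domain points (\code{age_fit_points},
#'   \code{education_env_points}, \code{comorbidity_points},
#'   \code{medication_points}, \code{sex_points}) and \code{total}.
#' @examples
#' # worked high-risk vignette: 4 + 2 + 1 + 1 + 1 = 9
#' score_complex(62, 1200, 2, "rural", 2, 1, 0, "male")$total
#' @export
score_complex <- function(age, fit_value, education, environment,
                          comorbidity_count, antiplatelet, anticoagulant,
                          sex, include_sex = TRUE) {
  check_required(list(age = age, fit_value = fit_value, education = education,
                      environment = environment,
                      comorbidity_count = comorbidity_count,
                      antiplatelet = antiplatelet,
                      anticoagulant = anticoagulant,
                      sex = if (include_sex) sex else "female"),
                 c("age", "fit_value", "education", "environment",
                   "comorbidity_count", "antiplatelet", "anticoagulant",
                   "sex"))
  if (any(fit_value < 20))
    stop("FIT below 20: not a FIT-positive subject")
  if (!all(environment %in% c("rural", "urban")))
    stop("'environment' must be rural or urban")
  if (!all(education %in% 0:8)) stop("'education' must be an ISCED level 0-8")
  age_fit <- fit_band(fit_value) + (age >= 60)
  edu_band <- ifelse(education >= 5, 0L, ifelse(education >= 3, 1L, 2L))
  edu_env <- pmin(2L, edu_band + (environment == "rural"))
  com <- ifelse(comorbidity_count == 0, 0L,
                ifelse(comorbidity_count <= 2, 1L, 2L))
  med <- ifelse(anticoagulant == 1, 2L, ifelse(antiplatelet == 1, 1L, 0L))
  sex_pts <- if (include_sex) as.integer(sex == "male") else 0L
  data.frame(
    age_fit_points = as.integer(age_fit),
    education_env_points = as.integer(edu_env),
    comorbidity_points = as.integer(com),
    medication_points = as.integer(med),
    sex_points = as.integer(sex_pts),
    total = as.integer(age_fit + edu_env + com + med + sex_pts)
  )
}

#' Simplified malignancy risk score
#'
#' Three-domain score for primary care: FIT band 0-3 (<200 / 200-999 /
#' 1000-1999 / >=2000 ng/mL), age 0-2 (<60 / 60-69 / >=70 years) and
#' comorbidities 0-2 (none / 1-2 / >=3). Total 0-7.
#'
#' @inheritParams score_complex
#' @return Data frame with \code{fit_points}, \code{age_points},
#'   \code{comorbidity_points} and \code{total}.
#' @examples
#' score_simplified(72, 2500, 3)$total  # maximum: 7
#' @export
score_simplified <- function(age, fit_value, comorbidity_count) {
  check_required(list(age = age, fit_value = fit_value,
                      comorbidity_count = comorbidity_count),
                 c("age", "fit_value", "comorbidity_count"))
  if (any(fit_value < 20))
    stop("FIT below 20: not a FIT-positive subject")
  fit_pts <- fit_band(fit_value) - 1L
  age_pts <- ifelse(age < 60, 0L, ifelse(age < 70, 1L, 2L))
  com <- ifelse(comorbidity_count == 0, 0L,
                ifelse(comorbidity_count <= 2, 1L, 2L))
  data.frame(
    fit_points = as.integer(fit_pts),
    age_points = as.integer(age_pts),
    comorbidity_points = as.integer(com),
    total = as.integer(fit_pts + age_pts + com)
  )
}

#' Score a participant table
#'
#' Applies \code{\link{score_complex}} or \code{\link{score_simplified}} to
#' every row of a participant data frame.
#'
#' @param table Participant data frame (columns as produced by
#'   \code{\link{generate_cohort}}).
#' @param type \code{"complex"} or \code{"simplified"}.
#' @param include_sex Passed to \code{\link{score_complex}}.
#' @return The per-row score breakdown data frame.
#' @export
score_cohort <- function(table, type = c("complex", "simplified"),
                         include_sex = TRUE) {
  type <- match.arg(type)
  if (type == "complex")
    score_complex(table$age, table$fit_value, table$education,
                  table$environment, table$comorbidity_count,
                  table$antiplatelet, table$anticoagulant, table$sex,
                  include_sex = include_sex)
  else
    score_simplified(table$age, table$fit_value, table$comorbidity_count)
}

#' Triage recommendation from a complex score total
#'
#' The shared triage grid: 0-3 points is low risk (repeat FIT in two years),
#' 4-6 is moderate risk (colonoscopy within six months), 7 or more is high
#' risk (immediate colonoscopy).
#'
#' @param total Complex score total(s), each in 0-12.
#' @return Data frame with \code{category} (low/moderate/high) and
#'   \code{recommendation}.
#' @examples
#' triage(9)$category  # "high"
#' @export
triage <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 12))
    stop("'total' must lie in 0-12")
  category <- ifelse(total <= 3, "low", ifelse(total <= 6, "moderate", "high"))
  recommendation <- c(low = "repeat FIT in 2 years",
                      moderate = "colonoscopy within 6 months",
                      high = "immediate colonoscopy")[category]
  data.frame(category = unname(category),
             recommendation = unname(recommendation))
}

#' Youden-optimal score threshold
#'
#' Sweeps the integer cut-offs of a score (positive when score >= t) and
#' returns the threshold maximising Youden's J = sensitivity + specificity
#' - 1, breaking ties toward the lower (more sensitive) threshold.
#'
#' @param scores Numeric scores.
#' @param malignant_flags 0/1 outcome; both classes must be present.
#' @return List with \code{threshold} and \code{J}.
#' @export
youden_threshold <- function(scores, malignant_flags) {
  malignant_flags <- as.integer(malignant_flags)
  if (length(unique(malignant_flags)) < 2)
    stop("both classes must be present")
  candidates <- seq(floor(min(scores)), ceiling(max(scores)))
  n_pos <- sum(malignant_flags == 1)
  n_neg <- sum(malignant_flags == 0)
  j <- vapply(candidates, function(t) {
    sens <- sum(scores >= t & malignant_flags == 1) / n_pos
    spec <- sum(scores < t & malignant_flags == 0) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]  # lower threshold on ties
  list(threshold = candidates[best], J = j[best])
}
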