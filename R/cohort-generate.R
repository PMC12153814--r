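# Synthetic cohort generation: truncated-lognormal FIT values, truncated
# normal ages, categorical profiles per cluster, MCAR missingness and the
# non-completer arm of the screening programme.

# Moments of a lognormal(mu, sigma) doubly truncated to [lo, hi] on the
# original scale.
trunc_lnorm_moments <- function(mu, sigma, lo, hi) {
  la <- log(lo); lb <- log(hi)
  z <- stats::pnorm((lb - mu) / sigma) - stats::pnorm((la - mu) / sigma)
  mk <- function(k) {
    exp(k * mu + k^2 * sigma^2 / 2) *
      (stats::pnorm((lb - mu - k * sigma^2) / sigma) -
         stats::pnorm((la - mu - k * sigma^2) / sigma)) / z
  }
  m1 <- mk(1); m2 <- mk(2)
  list(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Find lognormal parameters whose [lo, hi]-truncated distribution has the
# target mean and sd. Starts from the untruncated moment match; when
# truncation is negligible the start is already the solution.
match_trunc_lnorm <- function(mean, sd, lo, hi) {
  stopifnot(mean > lo, mean < hi, sd > 0)
  cv2 <- (sd / mean)^2
  s0 <- sqrt(log1p(cv2))
  mu0 <- log(mean) - s0^2 / 2
  obj <- function(p) {
    m <- trunc_lnorm_moments(p[1], exp(p[2]), lo, hi)
    log(m$mean / mean)^2 + log(m$sd / sd)^2
  }
  if (obj(c(mu0, log(s0))) < 1e-8) return(list(mu = mu0, sigma = s0))
  fit <- stats::optim(c(mu0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF draw from the doubly truncated lognormal.
rtrunc_lnorm <- function(n, mu, sigma, lo, hi) {
  pa <- stats::pnorm((log(lo) - mu) / sigma)
  pb <- stats::pnorm((log(hi) - mu) / sigma)
  u <- stats::runif(n, pa, pb)
  exp(mu + sigma * stats::qnorm(u))
}

# Inverse-CDF draw from a [lo, hi]-truncated normal.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# Map the coarse education band to an ISCED 0-8 level.
band_to_isced <- function(band) {
  base <- c(primary = 1L, gymnasium = 2L, high_school = 3L,
            postsecondary = 4L, bachelor = 6L)
  out <- integer(length(band))
  hi <- band == "master_doctorate"
  out[!hi] <- base[band[!hi]]
  # master/doctorate split uniformly across ISCED 7-8
  out[hi] <- sample(c(7L, 8L), sum(hi), replace = TRUE)
  out
}

# Comorbidity category -> count: "multiple" means three or more conditions.
category_to_count <- function(category) {
  ifelse(category == "none", 0L, ifelse(category == "multiple", 3L, 1L))
}

# Medication prevalence conditional on comorbidity category, calibrated to
# the cohort-level margins (antiplatelet 14.97%, anticoagulant 5.61%) given
# the overall cardiac/multiple share.
medication_probs <- function(category) {
  high <- category %in% c("cardiac", "multiple")
  list(antiplatelet = ifelse(high, 0.245, 0.04),
       anticoagulant = ifelse(high, 0.096, 0.01))
}

# Within-cluster malignancy risk index. FIT contributes through its stratum
# (the 20-50 / 50-200 / 200-1000 / 1000-2000 / >=2000 bands in which the
# published yield tables report cancer counts), converted to a normal score;
# the remainder is an equal-weight index of the socio-clinical factors the
# cohort links to malignancy beyond FIT (rural residence, low education,
# male sex, antithrombotic use). Age and comorbidity burden act on
# malignancy through cluster composition alone.
risk_index <- function(fit_value, environment, education, sex,
                       antiplatelet, anticoagulant, fit_weight) {
  n <- length(fit_value)
  stratum <- findInterval(fit_value, c(50, 200, 1000, 2000))
  zf <- stats::qnorm((rank(stratum, ties.method = "average") - 0.5) / n)
  extra <- (environment == "rural") + (education <= 2) + (sex == "male") +
    antiplatelet + anticoagulant
  ze <- if (stats::sd(extra) > 0) (extra - mean(extra)) / stats::sd(extra)
        else rep(0, n)
  r <- fit_weight * zf + (1 - fit_weight) * ze
  if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r
}

# Draw per-patient diagnoses from a cluster's diagnosis distribution while
# coupling malignant diagnoses to higher-risk patients: the count per
# category is a plain multinomial draw, but the malignant diagnoses
# (carcinoma, malignant polyp) are assigned to the patients ranked highest
# on a latent propensity u = rho * risk + sqrt(1 - rho^2) * noise. rho = 0
# recovers independent assignment; positive rho reproduces the dose-response
# between the risk factors and cancer yield seen in the published
# score-band and FIT-stratum tables.
allocate_diagnoses <- function(risk, diagnosis_probs, rho = 0) {
  n <- length(risk)
  drawn <- sample(diagnosis_categories(), n, replace = TRUE,
                  prob = diagnosis_probs)
  if (rho <= 0) return(drawn)
  is_mal <- drawn %in% malignant_diagnoses()
  m <- sum(is_mal)
  if (m == 0 || m == n) return(drawn)
  u <- rho * risk + sqrt(1 - rho^2) * stats::rnorm(n)
  out <- character(n)
  top <- order(u, decreasing = TRUE)[seq_len(m)]
  out[top] <- sample(drawn[is_mal])
  out[-top] <- sample(drawn[!is_mal])
  out
}

# Per-segment BBPS score distributions matching the reported segment means
# (right 2.33, transverse 2.54, left 2.71).
bbps_segment_probs <- list(
  right = c(0.02, 0.08, 0.45, 0.45),
  transverse = c(0.01, 0.05, 0.33, 0.61),
  left = c(0.005, 0.025, 0.225, 0.745)
)

sample_bbps <- function(n, segment) {
  sample(0:3, n, replace = TRUE, prob = bbps_segment_probs[[segment]])
}

empty_cohort <- function() {
  data.frame(
    age = integer(0), sex = character(0), environment = character(0),
    education = integer(0), comorbidity_category = character(0),
    comorbidity_count = integer(0), antiplatelet = integer(0),
    anticoagulant = integer(0), fit_value = numeric(0),
    diagnosis = character(0), malignant = integer(0),
    completed_colonoscopy = logical(0),
    bbps_right = integer(0), bbps_transverse = integer(0),
    bbps_left = integer(0), cluster = integer(0),
    stringsAsFactors = FALSE
  )
}

generate_one_cluster <- function(spec, config) {
  n <- spec$size
  if (n == 0) return(empty_cohort())
  age <- as.integer(round(rtrunc_norm(n, spec$age_mean, spec$age_sd,
                                      config$age_bounds[1], config$age_bounds[2])))
  fp <- match_trunc_lnorm(spec$fit_mean, spec$fit_sd,
                          config$fit_floor, config$fit_cap)
  fit_value <- rtrunc_lnorm(n, fp$mu, fp$sigma, config$fit_floor, config$fit_cap)
  sex <- ifelse(stats::runif(n) < spec$sex_male_prob, "male", "female")
  environment <- ifelse(stats::runif(n) < spec$rural_prob, "rural", "urban")
  edu_band <- sample(education_bands(), n, replace = TRUE,
                     prob = spec$education_probs)
  education <- band_to_isced(edu_band)
  comorbidity_category <- sample(comorbidity_categories(), n, replace = TRUE,
                                 prob = spec$comorbidity_probs)
  comorbidity_count <- category_to_count(comorbidity_category)
  mp <- medication_probs(comorbidity_category)
  antiplatelet <- as.integer(stats::runif(n) < mp$antiplatelet)
  anticoagulant <- as.integer(stats::runif(n) < mp$anticoagulant)
  risk <- risk_index(fit_value, environment, education, sex,
                     antiplatelet, anticoagulant, config$fit_weight)
  diagnosis <- allocate_diagnoses(risk, spec$diagnosis_probs,
                                  config$malignancy_coupling)
  malignant <- as.integer(diagnosis %in% malignant_diagnoses())
  data.frame(
    age = age, sex = sex, environment = environment, education = education,
    comorbidity_category = comorbidity_category,
    comorbidity_count = comorbidity_count,
    antiplatelet = antiplatelet, anticoagulant = anticoagulant,
    fit_value = fit_value, diagnosis = diagnosis, malignant = malignant,
    completed_colonoscopy = TRUE,
    bbps_right = sample_bbps(n, "right"),
    bbps_transverse = sample_bbps(n, "transverse"),
    bbps_left = sample_bbps(n, "left"),
    cluster = spec$label,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic FIT-positive cohort
#'
#' Draws one participant table with the cluster structure described by
#' \code{config$cluster_specs}. Per-cluster sample sizes match the
#' specification exactly; ages are truncated-normal draws rounded to whole
#' years inside the screening window; FIT values follow a lognormal whose
#' truncated (positivity floor to analyser cap) moments match each cluster's
#' mean and standard deviation; categorical features are independent draws
#' from the cluster's composition; the malignancy flag is derived from the
#' sampled diagnosis (carcinoma or malignant polyp). The result is
#' reproducible for a fixed \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A data frame with one row per participant, including the
#'   generating \code{cluster} label and \code{completed_colonoscopy = TRUE}.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' table(cohort$cluster)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("'config' must be a cohort_config")
  set.seed(config$seed)
  parts <- lapply(config$cluster_specs, generate_one_cluster, config = config)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Inject missing-completely-at-random values
#'
#' Sets each cell of the named variables to \code{NA} independently with the
#' given per-variable probability. Rates above 5% are rejected: variables
#' missing more than that are excluded from analysis rather than imputed.
#'
#' @param table Participant data frame.
#' @param rates Named numeric vector, variable -> missingness rate in
#'   \code{[0, 0.05]}.
#' @param seed Integer seed.
#' @return The table with \code{NA}s injected.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  if (length(rates) == 0) return(table)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("'rates' must be named by variable")
  if (any(rates < 0)) stop("missingness rates must be non-negative")
  if (any(rates > 0.05))
    stop("missingness rates above 5% are not supported; such variables are excluded, not imputed")
  missing_vars <- setdiff(names(rates), names(table))
  if (length(missing_vars))
    stop("unknown variables: ", paste(missing_vars, collapse = ", "))
  set.seed(seed)
  for (v in names(rates)) {
    hit <- stats::runif(nrow(table)) < rates[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Default non-completer distribution shifts
#'
#' Marginal parameters of the FIT-positive subjects who declined colonoscopy,
#' as reported in the completer/non-completer sensitivity comparison:
#' age 63.4 +/- 7.0 years, FIT 260 +/- 710 ng/mL, 50.8% male, 55.7% rural,
#' and a comorbidity mix with 32.2% free of comorbidity.
#'
#' @return Named list of generator parameters understood by
#'   \code{\link{generate_noncompleters}}.
#' @export
noncompleter_shifts <- function() {
  list(
    age_mean = 63.4, age_sd = 7.0,
    fit_mean = 260, fit_sd = 710,
    male_prob = 0.508, rural_prob = 0.557,
    comorbidity_probs = c(none = 0.322, cardiac = 0.337, multiple = 0.231,
                          diabetes = 0.017, other = 0.093)
  )
}

# Empirical generator parameters of an existing participant table.
table_generator_params <- function(table) {
  n <- nrow(table)
  list(
    age_mean = mean(table$age), age_sd = stats::sd(table$age),
    fit_mean = mean(table$fit_value), fit_sd = stats::sd(table$fit_value),
    male_prob = mean(table$sex == "male"),
    rural_prob = mean(table$environment == "rural"),
    comorbidity_probs = prop.table(table(factor(table$comorbidity_category,
                                                levels = comorbidity_categories())))
  )
}

#' Generate the non-completer arm
#'
#' Produces \code{n} FIT-positive records for subjects who declined
#' colonoscopy (\code{completed_colonoscopy = FALSE}; no diagnosis, no bowel
#' preparation scores). The generating distribution is either the reported
#' non-completer profile (\code{\link{noncompleter_shifts}}, the default), or
#' the empirical profile of a supplied completer table, with
#' \code{shift_config} entries overriding individual parameters. Supplying a
#' completer table with an empty \code{shift_config} therefore draws
#' non-completers from the completers' own distribution (a null scenario for
#' sensitivity-analysis calibration).
#'
#' @param n Number of records (>= 0).
#' @param completer_table Optional completer data frame whose empirical
#'   marginals serve as the baseline parameters.
#' @param shift_config Named list overriding baseline parameters; see
#'   \code{\link{noncompleter_shifts}} for the full set.
#' @param seed Integer seed.
#' @param fit_floor,fit_cap FIT truncation bounds.
#' @param age_bounds Screening age window.
#' @return Data frame of non-completer records.
#' @export
generate_noncompleters <- function(n, completer_table = NULL,
                                   shift_config = if (is.null(completer_table))
                                     noncompleter_shifts() else list(),
                                   seed = 1L, fit_floor = 20, fit_cap = 9999.99,
                                   age_bounds = c(50, 74)) {
  if (n < 0) stop("'n' must be non-negative")
  base <- if (is.null(completer_table)) noncompleter_shifts()
          else table_generator_params(completer_table)
  p <- utils::modifyList(base, shift_config)
  out0 <- empty_cohort()
  out0$diagnosis <- character(0)
  if (n == 0) return(out0[, setdiff(names(out0),
                                    c("bbps_right", "bbps_transverse",
                                      "bbps_left", "cluster"))])
  set.seed(seed)
  age <- as.integer(round(rtrunc_norm(n, p$age_mean, p$age_sd,
                                      age_bounds[1], age_bounds[2])))
  fp <- match_trunc_lnorm(p$fit_mean, p$fit_sd, fit_floor, fit_cap)
  fit_value <- rtrunc_lnorm(n, fp$mu, fp$sigma, fit_floor, fit_cap)
  comorbidity_category <- sample(comorbidity_categories(), n, replace = TRUE,
                                 prob = p$comorbidity_probs[comorbidity_categories()])
  mp <- medication_probs(comorbidity_category)
  data.frame(
    age = age,
    sex = ifelse(stats::runif(n) < p$male_prob, "male", "female"),
    environment = ifelse(stats::runif(n) < p$rural_prob, "rural", "urban"),
    education = band_to_isced(sample(education_bands(), n, replace = TRUE,
                                     prob = c(0.06, 0.20, 0.52, 0.09, 0.09, 0.04))),
    comorbidity_category = comorbidity_category,
    comorbidity_count = category_to_count(comorbidity_category),
    antiplatelet = as.integer(stats::runif(n) < mp$antiplatelet),
    anticoagulant = as.integer(stats::runif(n) < mp$anticoagulant),
    fit_value = fit_value,
    diagnosis = NA_character_,
    malignant = NA_integer_,
    completed_colonoscopy = FALSE,
    stringsAsFactors = FALSE
  )
}
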