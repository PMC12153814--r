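# Generative specification of the five published patient clusters and the
# cohort-level configuration used by the synthetic cohort generator.

#' Education bands used in the cluster profiles
#'
#' Coarse six-level education classification (primary school, gymnasium, high
#' school, postsecondary studies, bachelor-level higher education,
#' master/doctorate) as reported per cluster. Finer ISCED 0-8 levels are
#' derived from these bands at generation time.
#'
#' @return Character vector of the six band labels, in increasing order of
#'   attainment.
#' @export
education_bands <- function() {
  c("primary", "gymnasium", "high_school", "postsecondary",
    "bachelor", "master_doctorate")
}

#' Comorbidity categories
#'
#' @return Character vector of the five comorbidity categories: none, cardiac
#'   pathology, multiple (three or more) comorbidities, diabetes mellitus,
#'   other.
#' @export
comorbidity_categories <- function() {
  c("none", "cardiac", "multiple", "diabetes", "other")
}

#' Colonoscopy diagnosis categories
#'
#' @return Character vector of the diagnosis categories used in the cluster
#'   profiles.
#' @export
diagnosis_categories <- function() {
  c("serrated_adenoma", "tubular_adenoma", "normal", "inflammatory",
    "carcinoma", "adenomatous_polyp", "hyperplastic_polyp",
    "malignant_polyp", "serrated_polyp")
}

#' Diagnoses counted as malignant lesions
#' @return Character vector: carcinoma and malignant polyp.
#' @export
malignant_diagnoses <- function() c("carcinoma", "malignant_polyp")

#' Construct a cluster generative specification
#'
#' A \code{cluster_spec} describes one patient cluster generatively: its size,
#' age and FIT first two moments, and categorical composition (sex, residence,
#' education, comorbidity, colonoscopy diagnosis). The malignancy rate must be
#' consistent with the probability mass the diagnosis distribution puts on
#' malignant categories.
#'
#' @param label Integer cluster id (0-4 for the published profiles).
#' @param size Number of patients in the cluster (>= 0).
#' @param age_mean,age_sd Age moments in years (sd >= 0).
#' @param fit_mean,fit_sd FIT moments in ng/mL (sd >= 0).
#' @param sex_male_prob Probability of male sex.
#' @param rural_prob Probability of rural residence.
#' @param education_probs Named probability vector over
#'   \code{\link{education_bands}}.
#' @param comorbidity_probs Named probability vector over
#'   \code{\link{comorbidity_categories}}.
#' @param diagnosis_probs Named probability vector over
#'   \code{\link{diagnosis_categories}}.
#' @param malignancy_rate Probability of a malignant lesion; must agree with
#'   the mass of \code{diagnosis_probs} on \code{\link{malignant_diagnoses}}
#'   within 0.02.
#' @return An object of class \code{cluster_spec}.
#' @export
cluster_spec <- function(label, size, age_mean, age_sd, fit_mean, fit_sd,
                         sex_male_prob, rural_prob, education_probs,
                         comorbidity_probs, diagnosis_probs, malignancy_rate) {
  stopifnot(size >= 0, age_sd >= 0, fit_sd >= 0)
  check_prob <- function(p, levels, what) {
    if (!all(levels %in% names(p)))
      stop("'", what, "' must be named over: ", paste(levels, collapse = ", "))
    p <- p[levels]
    if (any(p < 0)) stop("'", what, "' has negative entries")
    if (abs(sum(p) - 1) > 1e-9)
      stop("'", what, "' must sum to 1 (got ", format(sum(p)), ")")
    p
  }
  check_scalar_prob <- function(x, what) {
    if (x < 0 || x > 1) stop("'", what, "' must lie in [0, 1]")
    x
  }
  education_probs <- check_prob(education_probs, education_bands(), "education_probs")
  comorbidity_probs <- check_prob(comorbidity_probs, comorbidity_categories(),
                                  "comorbidity_probs")
  diagnosis_probs <- check_prob(diagnosis_probs, diagnosis_categories(),
                                "diagnosis_probs")
  sex_male_prob <- check_scalar_prob(sex_male_prob, "sex_male_prob")
  rural_prob <- check_scalar_prob(rural_prob, "rural_prob")
  malignancy_rate <- check_scalar_prob(malignancy_rate, "malignancy_rate")
  malignant_mass <- sum(diagnosis_probs[malignant_diagnoses()])
  if (abs(malignant_mass - malignancy_rate) > 0.02)
    stop("malignancy_rate (", format(malignancy_rate),
         ") inconsistent with diagnosis mass on malignant categories (",
         format(malignant_mass), ")")
  structure(list(
    label = as.integer(label), size = as.integer(size),
    age_mean = age_mean, age_sd = age_sd,
    fit_mean = fit_mean, fit_sd = fit_sd,
    sex_male_prob = sex_male_prob, rural_prob = rural_prob,
    education_probs = education_probs,
    comorbidity_probs = comorbidity_probs,
    diagnosis_probs = diagnosis_probs,
    malignancy_rate = malignancy_rate
  ), class = "cluster_spec")
}

# Build a spec from raw per-category counts; probabilities are the counts
# normalised over their own total (printed education counts do not always sum
# to the cluster size).
spec_from_counts <- function(label, size, age_mean, age_sd, fit_mean, fit_sd,
                             male_n, rural_n, edu_counts, com_counts,
                             dx_counts, malignant_n) {
  cluster_spec(
    label = label, size = size,
    age_mean = age_mean, age_sd = age_sd,
    fit_mean = fit_mean, fit_sd = fit_sd,
    sex_male_prob = male_n / size,
    rural_prob = rural_n / size,
    education_probs = stats::setNames(edu_counts / sum(edu_counts), education_bands()),
    comorbidity_probs = stats::setNames(com_counts / sum(com_counts),
                                        comorbidity_categories()),
    diagnosis_probs = stats::setNames(dx_counts / sum(dx_counts),
                                      diagnosis_categories()),
    malignancy_rate = malignant_n / size
  )
}

#' Published five-cluster generative specifications
#'
#' The default cluster specifications emulating the reported five-cluster
#' structure of the 1550-patient FIT-positive colonoscopy cohort: a small
#' high-FIT cluster with a 50.91% malignancy rate, two serrated-adenoma
#' clusters (younger and older) with no malignant lesions, a large low-risk
#' mixed-polyp cluster (5.32% malignancy) and an older intermediate-risk
#' cluster (11.11% malignancy).
#'
#' @return A list of five \code{\link{cluster_spec}} objects with sizes
#'   55, 242, 677, 423 and 153.
#' @export
default_cluster_specs <- function() {
  list(
    # High-FIT malignant group
    spec_from_counts(0L, 55, 64.49, 6.14, 3425.61, 2301.57,
                     male_n = 47, rural_n = 20,
                     edu_counts = c(0, 10, 30, 3, 7, 5),
                     com_counts = c(15, 21, 14, 1, 4),
                     dx_counts = c(8, 5, 7, 1, 27, 3, 2, 1, 1),
                     malignant_n = 28),
    # Younger serrated-adenoma group
    spec_from_counts(1L, 242, 58.07, 4.52, 158.18, 249.37,
                     male_n = 135, rural_n = 119,
                     edu_counts = c(8, 36, 136, 26, 27, 8),
                     com_counts = c(105, 76, 27, 6, 28),
                     dx_counts = c(242, 0, 0, 0, 0, 0, 0, 0, 0),
                     malignant_n = 0),
    # Low-risk mixed-polyp group
    spec_from_counts(2L, 677, 58.48, 4.79, 138.59, 228.74,
                     male_n = 324, rural_n = 397,
                     edu_counts = c(44, 115, 368, 47, 61, 42),
                     com_counts = c(319, 182, 89, 13, 74),
                     dx_counts = c(0, 113, 363, 21, 34, 60, 74, 2, 10),
                     malignant_n = 36),
    # Intermediate-risk older group
    spec_from_counts(3L, 423, 69.63, 2.84, 158.50, 240.85,
                     male_n = 229, rural_n = 200,
                     edu_counts = c(33, 110, 191, 40, 22, 23),
                     com_counts = c(70, 159, 147, 3, 44),
                     dx_counts = c(0, 67, 202, 8, 47, 37, 49, 0, 13),
                     malignant_n = 47),
    # Older serrated-adenoma group
    spec_from_counts(4L, 153, 69.31, 2.95, 179.98, 263.31,
                     male_n = 105, rural_n = 65,
                     edu_counts = c(6, 30, 85, 17, 8, 6),
                     com_counts = c(21, 51, 64, 3, 14),
                     dx_counts = c(153, 0, 0, 0, 0, 0, 0, 0, 0),
                     malignant_n = 0)
  )
}

#' Cohort generation configuration
#'
#' @param cluster_specs List of \code{\link{cluster_spec}} objects; defaults to
#'   \code{\link{default_cluster_specs}()}.
#' @param seed Integer random seed.
#' @param fit_floor Positivity cut-off on the FIT scale (default 20; only
#'   FIT-positive subjects enter the cohort).
#' @param fit_cap Upper bound for simulated FIT values (default 9999.99, the
#'   analyser's reporting maximum).
#' @param age_bounds Screening eligibility window, default \code{c(50, 74)}.
#' @param missingness_rates Named vector of missing-completely-at-random rates
#'   (each <= 0.05) applied by \code{\link{inject_missingness}}; default none.
#' @param malignancy_coupling Within-cluster coupling strength in
#'   \code{[0, 1)} between malignant diagnoses and a latent risk propensity
#'   (Gaussian copula): 0 makes malignancy independent of the risk factors
#'   within cluster.
#' @param fit_weight Share in \code{[0, 1]} of the risk propensity carried by
#'   the FIT normal score; the remainder is an equal-weight index of the
#'   socio-clinical factors linked to malignancy beyond FIT (rural residence,
#'   low education, male sex, antithrombotics). The defaults of both
#'   parameters are calibrated once, jointly against the published
#'   distribution of cancers across complex-score bands and FIT strata and
#'   the published score/FIT discrimination profile.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(cluster_specs = default_cluster_specs(),
                          seed = 1L, fit_floor = 20, fit_cap = 9999.99,
                          age_bounds = c(50, 74),
                          missingness_rates = numeric(0),
                          malignancy_coupling = 0.7, fit_weight = 0.5) {
  stopifnot(fit_floor >= 20, fit_cap > fit_floor,
            length(age_bounds) == 2, age_bounds[1] < age_bounds[2],
            malignancy_coupling >= 0, malignancy_coupling < 1,
            fit_weight >= 0, fit_weight <= 1)
  if (length(missingness_rates) && any(missingness_rates > 0.05))
    stop("missingness rates above 5% are not supported")
  ok <- vapply(cluster_specs, inherits, logical(1), what = "cluster_spec")
  if (!all(ok)) stop("'cluster_specs' must be a list of cluster_spec objects")
  structure(list(
    cluster_specs = cluster_specs, seed = as.integer(seed),
    fit_floor = fit_floor, fit_cap = fit_cap, age_bounds = age_bounds,
    missingness_rates = missingness_rates,
    malignancy_coupling = malignancy_coupling, fit_weight = fit_weight
  ), class = "cohort_config")
}
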