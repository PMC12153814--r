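# Strategy evaluation: ROC/AUC with bootstrap confidence intervals, DeLong
# paired AUC comparison, precision-recall, group-fairness metrics, the
# completer/non-completer sensitivity comparison and inverse-probability
# weighting for colonoscopy completion.

# AUC as the Mann-Whitney pair statistic (ties count one half), via ranks.
auc_mann_whitney <- function(values, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with AUC and bootstrap confidence interval
#'
#' Builds the empirical ROC curve over the observed thresholds, computes the
#' AUC (equal to the Mann-Whitney concordance probability, ties counting one
#' half), and attaches a stratified percentile bootstrap 95% interval.
#'
#' @param values Scores; higher means more likely positive.
#' @param labels 0/1 outcomes; both classes required.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Interval coverage (default 0.95).
#' @return List of class \code{roc_curve}: \code{thresholds},
#'   \code{sensitivity}, \code{fpr} (1 - specificity), \code{auc},
#'   \code{ci_low}, \code{ci_high}.
#' @export
roc_auc <- function(values, labels, n_boot = 2000, seed = 1L,
                    conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(values >= t & labels == 1) / n1,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(values >= t & labels == 0) / n0,
                numeric(1))
  auc <- auc_mann_whitney(values, labels)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    pos <- which(labels == 1); neg <- which(labels == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, n1, replace = TRUE),
               sample(neg, n0, replace = TRUE))
      auc_mann_whitney(values[idx], labels[idx])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(thresholds = thr, sensitivity = sens, fpr = fpr,
                 auc = auc, ci_low = ci[1], ci_high = ci[2]),
            class = "roc_curve")
}

# Placement values underlying the DeLong covariance estimate.
delong_placements <- function(values, labels) {
  x <- values[labels == 1]
  y <- values[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong paired comparison of two AUCs
#'
#' Compares the AUCs of two score vectors over the same outcomes using the
#' DeLong placement-value covariance estimate for paired (correlated) ROC
#' curves, returning the AUC difference and a two-sided normal p-value.
#'
#' @param values_a,values_b Score vectors of equal length.
#' @param labels Shared 0/1 outcomes.
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta_auc},
#'   \code{variance}, \code{z} and \code{p_value}.
#' @export
delong_compare <- function(values_a, values_b, labels) {
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(labels))
    stop("'values_a', 'values_b' and 'labels' must have equal length")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pa <- delong_placements(values_a, labels)
  pb <- delong_placements(values_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, variance = v,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Precision-recall curve and average precision
#'
#' Ranks by decreasing score and accumulates precision at each retrieved
#' positive; average precision is the step-wise integral of precision over
#' recall (the mean of precision at the rank of each positive).
#'
#' @param values Scores.
#' @param labels 0/1 outcomes; at least one positive required.
#' @return List with \code{curve} (data frame: recall, precision) and
#'   \code{average_precision}.
#' @export
pr_curve_ap <- function(values, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positive cases")
  ord <- order(values, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / n_pos
  ap <- sum(precision[y == 1]) / n_pos
  list(curve = data.frame(recall = recall, precision = precision),
       average_precision = ap)
}

#' Group-fairness audit of a triage rule
#'
#' Computes the standard group-fairness metrics of a binary high-risk
#' assignment across a two-group split of the cohort: statistical parity
#' difference (SPD, difference in high-risk assignment rates, unprivileged
#' minus privileged), equal-opportunity difference (EOD, difference in true
#' positive rates among subjects with malignant lesions), and the disparate
#' impact ratio (DIR, ratio of favorable-outcome rates, where the favorable
#' outcome is escaping the high-risk tier), checked against the accepted
#' 0.8-1.25 fairness band. The unprivileged group is rural residence, or low
#' education (ISCED at or below \code{low_isced_max}; 2 by default, with 3 as
#' the alternative convention).
#'
#' @param records Participant data frame.
#' @param high_risk_flags Logical/0-1 high-risk assignment (e.g. complex
#'   score >= 7).
#' @param malignant_flags 0/1 outcomes.
#' @param grouping \code{"environment"} or \code{"education_band"}.
#' @param scores Optional continuous scores for per-group AUC.
#' @param low_isced_max Education split point (default ISCED <= 2 is "low").
#' @return List of class \code{fairness_report}: \code{grouping},
#'   \code{spd}, \code{eod}, \code{dir}, \code{dir_within_band},
#'   \code{group_sizes}, and (with \code{scores}) \code{auc_by_group} and
#'   \code{max_auc_gap}.
#' @export
fairness_audit <- function(records, high_risk_flags, malignant_flags,
                           grouping = c("environment", "education_band"),
                           scores = NULL, low_isced_max = 2) {
  grouping <- match.arg(grouping)
  high <- as.logical(high_risk_flags)
  mal <- as.integer(malignant_flags)
  unpriv <- switch(grouping,
    environment = records$environment == "rural",
    education_band = records$education <= low_isced_max)
  if (all(unpriv) || !any(unpriv)) stop("both groups must be non-empty")
  rate <- function(x, g) mean(x[g])
  spd <- rate(high, unpriv) - rate(high, !unpriv)
  tpr <- function(g) {
    pos <- mal == 1 & g
    if (!any(pos)) return(NA_real_)
    mean(high[pos])
  }
  eod <- tpr(unpriv) - tpr(!unpriv)
  favorable <- !high
  dir <- rate(favorable, unpriv) / rate(favorable, !unpriv)
  out <- list(grouping = grouping, spd = spd, eod = eod, dir = dir,
              dir_within_band = !is.na(dir) && dir >= 0.8 && dir <= 1.25,
              group_sizes = c(unprivileged = sum(unpriv),
                              privileged = sum(!unpriv)))
  if (!is.null(scores)) {
    auc_for <- function(g) {
      if (length(unique(mal[g])) < 2) return(NA_real_)
      auc_mann_whitney(scores[g], mal[g])
    }
    out$auc_by_group <- c(unprivileged = auc_for(unpriv),
                          privileged = auc_for(!unpriv))
    out$max_auc_gap <- abs(diff(out$auc_by_group))
  }
  structure(out, class = "fairness_report")
}

#' Completer versus non-completer comparison
#'
#' Welch t-tests for the continuous variables (age, FIT value) and chi-square
#' tests (no continuity correction by default) for the categorical indicators
#' (sex, residence, any/cardiac/multiple comorbidity), mirroring the
#' sensitivity analysis of colonoscopy adherence.
#'
#' @param completers,noncompleters Non-empty participant data frames.
#' @param yates Apply Yates continuity correction to 2x2 tables
#'   (default FALSE).
#' @return Data frame with \code{variable}, \code{test}, \code{statistic},
#'   \code{p_value}, and per-group summaries (\code{completers},
#'   \code{noncompleters}).
#' @export
completer_comparison <- function(completers, noncompleters, yates = FALSE) {
  if (nrow(completers) == 0 || nrow(noncompleters) == 0)
    stop("both groups must be non-empty")
  cont_row <- function(var) {
    a <- completers[[var]]; b <- noncompleters[[var]]
    tt <- stats::t.test(a, b)
    data.frame(variable = var, test = "welch_t",
               statistic = unname(tt$statistic), p_value = tt$p.value,
               completers = sprintf("%.1f ± %.1f", mean(a), stats::sd(a)),
               noncompleters = sprintf("%.1f ± %.1f", mean(b), stats::sd(b)))
  }
  cat_row <- function(var, indicator, label) {
    a <- indicator(completers); b <- indicator(noncompleters)
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    data.frame(variable = label, test = "chi_square",
               statistic = unname(ct$statistic), p_value = ct$p.value,
               completers = sprintf("%d (%.1f%%)", sum(a), 100 * mean(a)),
               noncompleters = sprintf("%d (%.1f%%)", sum(b), 100 * mean(b)))
  }
  out <- rbind(
    cont_row("age"),
    cont_row("fit_value"),
    cat_row("sex", function(d) d$sex == "male", "sex_male"),
    cat_row("environment", function(d) d$environment == "rural",
            "environment_rural"),
    cat_row("comorbidity", function(d) d$comorbidity_category != "none",
            "any_comorbidity"),
    cat_row("comorbidity", function(d) d$comorbidity_category == "cardiac",
            "cardiac_comorbidity"),
    cat_row("comorbidity", function(d) d$comorbidity_category == "multiple",
            "multiple_comorbidities")
  )
  rownames(out) <- NULL
  out
}

#' Inverse-probability-of-completion weights
#'
#' Fits a logistic model of colonoscopy completion on age, sex, FIT value,
#' residence and comorbidity count over the combined completer/non-completer
#' table, and derives inverse-probability weights (1/p for completers,
#' 1/(1-p) for non-completers) plus stabilized versions scaled by the
#' marginal completion rate. Estimated probabilities at or outside
#' (0.01, 0.99) lead to weight truncation at the 1st/99th weight percentiles,
#' with a message.
#'
#' @param records Data frame containing both completers and non-completers
#'   with a logical \code{completed_colonoscopy} column.
#' @return List of class \code{iptw_result}: \code{model},
#'   \code{coefficients}, \code{p_completion}, \code{weights},
#'   \code{stabilized_weights}, \code{truncated} (logical).
#' @export
iptw_weights <- function(records) {
  comp <- records$completed_colonoscopy
  if (length(unique(comp)) < 2)
    stop("completion status must vary across records")
  fit <- stats::glm(completed_colonoscopy ~ age + sex + fit_value +
                      environment + comorbidity_count,
                    data = records, family = stats::binomial())
  p <- stats::fitted(fit)
  w <- ifelse(comp, 1 / p, 1 / (1 - p))
  truncated <- FALSE
  if (any(p <= 0.01 | p >= 0.99)) {
    q <- stats::quantile(w, c(0.01, 0.99))
    w <- pmin(pmax(w, q[1]), q[2])
    truncated <- TRUE
    message("extreme completion probabilities: weights truncated at the 1st/99th percentiles")
  }
  rate <- mean(comp)
  sw <- ifelse(comp, rate, 1 - rate) * w
  structure(list(model = fit, coefficients = stats::coef(fit),
                 p_completion = p, weights = unname(w),
                 stabilized_weights = unname(sw), truncated = truncated),
            class = "iptw_result")
}
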