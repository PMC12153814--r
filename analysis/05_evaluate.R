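#!/usr/bin/env Rscript
# Strategy evaluation on the simulated cohort: ROC comparison with DeLong
# tests and bootstrap intervals, precision-recall for malignancy, fairness
# audit of the high-risk assignment, and the completer/IPTW sensitivity
# analysis.

library(fittriage)

seed <- 20260928L
cohort <- read.csv("results/cohort_scored.csv", stringsAsFactors = FALSE)
full <- read.csv("results/cohort_complete.csv", stringsAsFactors = FALSE)
noncompleters <- read.csv("results/noncompleters.csv",
                          stringsAsFactors = FALSE)

# --- discrimination -----------------------------------------------------
roc_cx <- roc_auc(cohort$complex_total, cohort$malignant, n_boot = 2000,
                  seed = seed)
roc_fit <- roc_auc(cohort$fit_value, cohort$malignant, n_boot = 2000,
                   seed = seed)
roc_sp <- roc_auc(cohort$simplified_total, cohort$malignant, n_boot = 2000,
                  seed = seed)
cat(sprintf("AUC complex %.3f [%.3f-%.3f], FIT %.3f [%.3f-%.3f], simplified %.3f [%.3f-%.3f]\n",
            roc_cx$auc, roc_cx$ci_low, roc_cx$ci_high,
            roc_fit$auc, roc_fit$ci_low, roc_fit$ci_high,
            roc_sp$auc, roc_sp$ci_low, roc_sp$ci_high))
dl <- delong_compare(cohort$complex_total, cohort$fit_value,
                     cohort$malignant)
cat(sprintf("DeLong complex vs FIT: dAUC %.3f, p = %.4g\n",
            dl$delta_auc, dl$p_value))
pr <- pr_curve_ap(cohort$complex_total, cohort$malignant)
cat(sprintf("Average precision of the complex score: %.3f\n",
            pr$average_precision))
curves <- rbind(
  data.frame(strategy = "complex", fpr = roc_cx$fpr,
             sensitivity = roc_cx$sensitivity),
  data.frame(strategy = "fit", fpr = roc_fit$fpr,
             sensitivity = roc_fit$sensitivity),
  data.frame(strategy = "simplified", fpr = roc_sp$fpr,
             sensitivity = roc_sp$sensitivity)
)
write.csv(curves, "results/roc_curves.csv", row.names = FALSE)

# --- fairness audit of the high-risk tier -------------------------------
high <- cohort$complex_total >= 7
for (grouping in c("environment", "education_band")) {
  f <- fairness_audit(full, high, cohort$malignant, grouping,
                      scores = cohort$complex_total)
  cat(sprintf("%s: SPD %.3f, EOD %s, DIR %.2f (within 0.8-1.25: %s), AUC gap %.3f\n",
              grouping, f$spd,
              ifelse(is.na(f$eod), "undefined", sprintf("%.3f", f$eod)),
              f$dir, f$dir_within_band, f$max_auc_gap))
}

# --- completer sensitivity and completion weighting ---------------------
cmp <- completer_comparison(full, noncompleters)
write.csv(cmp, "results/completer_comparison.csv", row.names = FALSE)
cat("Completer vs non-completer comparison:\n")
print(cmp[, c("variable", "test", "statistic", "p_value")])

shared <- c("age", "sex", "fit_value", "environment", "comorbidity_count",
            "completed_colonoscopy")
records <- rbind(full[, shared], noncompleters[, shared])
w <- iptw_weights(records)
cat("Completion-model coefficients:\n")
print(round(w$coefficients, 4))
wc <- w$stabilized_weights[records$completed_colonoscopy]
unw <- glm(cohort$malignant ~ cohort$complex_total, family = binomial())
wei <- suppressWarnings(glm(cohort$malignant ~ cohort$complex_total,
                            family = binomial(), weights = wc))
cat(sprintf("Score-malignancy log-odds slope: unweighted %.4f, IPTW-weighted %.4f\n",
            coef(unw)[2], coef(wei)[2]))
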