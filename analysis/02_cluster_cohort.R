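#!/usr/bin/env Rscript
# Stratify the simulated cohort: impute the observed table, embed the
# encoded features with the autoencoder, pick k by silhouette, cluster, and
# validate the assignment with the feed-forward network. Requires
# 01_simulate_cohort.R to have run.

library(fittriage)

seed <- 20260928L
observed <- read.csv("results/cohort_observed.csv", stringsAsFactors = FALSE)

# one completed dataset for the clustering itself (the scoring analysis in
# 03 uses the full five for pooled estimates)
completed <- mice_impute(observed,
                         columns = c("age", "fit_value", "education",
                                     "environment", "comorbidity_category",
                                     "sex", "comorbidity_count"),
                         seed = seed)[[1]]
# keep the count consistent with any imputed category
completed$comorbidity_count <-
  ifelse(completed$comorbidity_category == "none", 0L,
         ifelse(completed$comorbidity_category == "multiple", 3L, 1L))

feats <- clustering_features(completed)
ae <- train_autoencoder(feats, autoencoder_config(seed = seed))
sel <- select_k_silhouette(ae$latent, k_range = 2:10, seed = 42)
cat("Silhouette by k:\n")
print(round(sel$silhouette_by_k, 4))
cat("Selected k:", sel$k, "\n")

labels <- kmeans_latent(ae$latent, 5, seed = 42)
completed$recovered_cluster <- labels
write.csv(completed, "results/cohort_clustered.csv", row.names = FALSE)
write.csv(ae$history, "results/autoencoder_history.csv", row.names = FALSE)

profile <- data.frame(
  cluster = sort(unique(labels)),
  n = as.integer(table(labels)),
  malignancy_rate = round(as.numeric(tapply(completed$malignant, labels,
                                            mean)), 4),
  mean_fit = round(as.numeric(tapply(completed$fit_value, labels, mean)), 1),
  mean_age = round(as.numeric(tapply(completed$age, labels, mean)), 1)
)
write.csv(profile, "results/recovered_cluster_profile.csv", row.names = FALSE)
cat("Recovered cluster profile:\n")
print(profile)

proj <- pca_project(ae$latent, 2, feature_matrix = feats)
cat("PCA axis labels:", paste(proj$axis_labels, collapse = " | "), "\n")
write.csv(data.frame(proj$projection, cluster = labels),
          "results/latent_pca.csv", row.names = FALSE)

val <- validate_clusters_ffnn(feats, labels, validator_config(seed = seed))
cat(sprintf("FFNN validation: CV accuracy %.3f, hold-out accuracy %.3f, mean one-vs-rest AUC %.3f\n",
            val$cv_accuracy, val$holdout_accuracy, val$holdout_auc))
imp <- permutation_importance(val$model, feats, labels, n_repeats = 5,
                              seed = seed)
write.csv(data.frame(feature = names(imp), importance = imp),
          "results/permutation_importance.csv", row.names = FALSE)
cat("Top cluster-defining features:",
    paste(head(names(imp), 4), collapse = ", "), "\n")
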