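test_that("autoencoder compresses low-rank structure and reports training history", {
  set.seed(31)
  basis <- matrix(rnorm(2 * 12), 2, 12)
  x <- matrix(rnorm(500 * 2), 500, 2) %*% basis
  x <- scale(x)
  cfg <- autoencoder_config(seed = 31, dropout_rate = 0)
  ae <- train_autoencoder(x, cfg)
  # latent shape contract
  expect_equal(ncol(ae$latent), 8)
  expect_equal(nrow(ae$latent), 500)
  # the data lie on a 2-dimensional manifold: an 8-d bottleneck must
  # reconstruct them nearly perfectly (PCA on 2 components already would)
  mse <- mean((ae$reconstruct(x) - x)^2)
  expect_lt(mse, 0.1)
  # loss decreases: final below initial, and monotone after smoothing
  h <- ae$history$train_loss
  expect_lt(h[length(h)], h[1])
  sm <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.01))
  # determinism for a fixed seed
  ae2 <- train_autoencoder(x, cfg)
  expect_equal(ae$latent, ae2$latent)
  expect_error(train_autoencoder(rbind(x, NA)), "missing")
})

test_that("k-means recovers well-separated blobs and handles degenerate input", {
  # two point-masses at distance 10
  x <- rbind(matrix(0, 20, 2), matrix(10, 25, 2)) +
    matrix(rnorm(90, sd = 0.01), 45, 2)
  lab <- kmeans_latent(x, 2, seed = 42)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:45])), 1)
  expect_true(lab[1] != lab[45])
  # identical points: arbitrary but valid labels, zero inertia
  same <- matrix(1, 12, 3)
  lab2 <- kmeans_latent(same, 2, seed = 1)
  expect_equal(sort(unique(lab2)), c(0L, 1L))
  expect_equal(attr(lab2, "tot_withinss"), 0)
  # five separated gaussian blobs: near-perfect agreement with truth
  blobs <- make_blobs(n_per = 60, seed = 33)
  lab3 <- kmeans_latent(blobs$x, 5, seed = 42)
  expect_gte(adjusted_rand(lab3, blobs$labels), 0.95)
  # determinism and errors
  expect_identical(as.integer(kmeans_latent(blobs$x, 5, seed = 42)),
                   as.integer(lab3))
  expect_error(kmeans_latent(x[1:3, ], 5), "at least k")
  expect_error(kmeans_latent(x, 1), "at least 2")
})

test_that("silhouette selection matches brute force and picks the true k", {
  # four points forming two distant pairs: hand-checkable silhouette
  x <- matrix(c(0, 0, 0.5, 0, 10, 0, 10.5, 0), 4, 2, byrow = TRUE)
  lab <- c(0, 0, 1, 1)
  # hand calculation: a = 0.5 for every point; b = mean distance to the
  # other pair = (9.5 + 10) / 2 or (10 + 10.5) / 2
  s1 <- (9.75 - 0.5) / 9.75
  s2 <- (10.25 - 0.5) / 10.25
  hand <- mean(c(s1, s1, s2, s2))
  expect_equal(mean_silhouette(x, lab), hand, tolerance = 1e-12)
  expect_equal(silhouette_brute_force(x, lab), hand, tolerance = 1e-12)

  # brute-force equality on a random instance
  set.seed(34)
  y <- matrix(rnorm(40 * 3), 40, 3)
  klab <- kmeans_latent(y, 3, seed = 42)
  expect_equal(mean_silhouette(y, klab), silhouette_brute_force(y, klab),
               tolerance = 1e-10)

  # three separated blobs: silhouette peaks at k = 3
  blobs <- make_blobs(n_per = 40, k = 3, sep = 6, seed = 35)
  sel <- select_k_silhouette(blobs$x, k_range = 2:6, seed = 42)
  expect_equal(sel$k, 3)
  expect_equal(unname(sel$silhouette_by_k[as.character(sel$k)]),
               max(sel$silhouette_by_k))
  expect_error(select_k_silhouette(y[1:3, ], 2:10), "more rows")
  expect_error(select_k_silhouette(y, integer(0)), "empty")
})

test_that("PCA projection orders components and labels axes by correlation", {
  set.seed(36)
  # variance concentrated along the first coordinate
  x <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1))
  p <- pca_project(x, 2, feature_matrix = x,
                   feature_names = c("dominant", "minor"))
  expect_true(p$explained_variance[1] > p$explained_variance[2])
  expect_gt(abs(cor(p$projection[, 1], x[, 1])), 0.99)
  expect_equal(p$axis_labels[1], "dominant + minor")
  # pure one-direction variance: PC1 explains ~100%
  z <- cbind(rnorm(100), 0)
  p2 <- pca_project(z + matrix(rnorm(200, sd = 1e-6), 100, 2), 2,
                    feature_matrix = z + matrix(rnorm(200, sd = 1e-6), 100, 2))
  expect_gt(p2$explained_variance[1], 0.999)
  expect_error(pca_project(x[1, , drop = FALSE], 2, x), "fewer samples")
})

test_that("the FFNN validator separates synthetic clusters and collapses under shuffled labels", {
  blobs <- make_blobs(n_per = 50, seed = 37)
  cfg <- validator_config(seed = 37)
  rep <- validate_clusters_ffnn(blobs$x, blobs$labels, cfg)
  expect_gte(rep$holdout_accuracy, 0.85)
  expect_true(all(rep$auc_by_cluster > 0.9, na.rm = TRUE))
  expect_equal(nrow(rep$fold_metrics), 5)
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in%
                    names(rep$fold_metrics)))
  # shuffled labels: accuracy near the majority-class rate
  set.seed(38)
  shuffled <- sample(blobs$labels)
  rep0 <- validate_clusters_ffnn(blobs$x, shuffled, cfg)
  majority <- max(table(shuffled)) / length(shuffled)
  expect_lt(abs(rep0$cv_accuracy - majority), 0.05)
  expect_error(validate_clusters_ffnn(blobs$x, rep(0, nrow(blobs$x))),
               "two classes")
  expect_error(validate_clusters_ffnn(blobs$x,
                                      c(rep(0, nrow(blobs$x) - 2), 1, 1)),
               "members")
})

test_that("random-forest ranking is stable under feature duplication", {
  blobs <- make_blobs(n_per = 40, d = 4, seed = 39)
  cfg <- validator_config(seed = 39, epochs = 10)
  r1 <- validate_clusters_ffnn(blobs$x, blobs$labels, cfg)
  xdup <- cbind(blobs$x, f1_copy = blobs$x[, "f1"])
  r2 <- validate_clusters_ffnn(xdup, blobs$labels, cfg)
  top1 <- names(r1$feature_ranking)[1:2]
  top2 <- names(r2$feature_ranking)
  # a duplicated column must not displace informative features from the top
  expect_true(all(top1 %in% c(top2[1:3], "f1_copy")))
})

test_that("permutation importance isolates label-defining features", {
  set.seed(40)
  n <- 300
  signal <- rep(c(0, 4), each = n / 2)
  x <- cbind(signal = signal + rnorm(n, sd = 0.2), noise = rnorm(n))
  labels <- rep(c("a", "b"), each = n / 2)
  cfg <- validator_config(seed = 40, epochs = 30, dropout_rate = 0.2,
                          holdout_dropout_rate = 0.2)
  rep <- validate_clusters_ffnn(x, labels, cfg)
  imp <- permutation_importance(rep$model, x, labels, n_repeats = 5, seed = 4)
  expect_equal(names(imp)[1], "signal")
  expect_gt(imp["signal"], imp["noise"])
  expect_lt(abs(imp["noise"]), 0.05)
  expect_identical(imp, permutation_importance(rep$model, x, labels,
                                               n_repeats = 5, seed = 4))
  expect_error(permutation_importance(NULL, x, labels, 5), "fitted")
  expect_error(permutation_importance(rep$model, x, labels, 0), "at least 1")
})

test_that("the full pipeline recovers the published malignancy gradient", {
  co <- generate_cohort(cohort_config(seed = 3))
  feats <- cohort_features(co)
  ae <- train_autoencoder(feats, autoencoder_config(seed = 3))
  lab <- kmeans_latent(ae$latent, 5, seed = 42)
  expect_equal(length(unique(lab)), 5)
  mal <- tapply(co$malignant, lab, mean)
  fit <- tapply(co$fit_value, lab, mean)
  # the highest-FIT recovered cluster carries the highest malignancy rate
  expect_equal(unname(which.max(fit)), unname(which.max(mal)))
  # at least two recovered clusters are free of malignancy (serrated groups)
  expect_gte(sum(mal == 0), 2)
})
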