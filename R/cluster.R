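# Unsupervised stratification: autoencoder latent embedding, k-means with
# silhouette-based model selection, and PCA projection with clinically
# labelled axes.

#' Autoencoder configuration
#'
#' Architecture and optimisation settings for the dimensionality-reduction
#' autoencoder: dense encoding layers of 32, 16 and 8 units (latent dimension
#' 8), mirrored decoder, ReLU activations, mean-squared-error loss, Adam
#' (learning rate 0.001, beta1 0.9, beta2 0.999), 100 epochs with batch size
#' 32, L2 weight penalty and dropout for regularisation, and a seeded 10%
#' validation split for loss monitoring.
#'
#' @param encoder_widths Hidden encoder widths ending in the latent layer.
#' @param latent_dim Latent dimension (must equal the last encoder width).
#' @param epochs,batch_size Training schedule.
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param l2_penalty L2 weight penalty.
#' @param dropout_rate Dropout on hidden layers during training.
#' @param batch_norm Batch-normalize hidden layers (default FALSE: the
#'   normalization whitens the bottleneck and weakens the scale contrasts
#'   that separate patient groups in the latent space).
#' @param linear_latent Use an identity (linear) activation on the bottleneck
#'   layer so the embedding preserves both directions of every latent axis
#'   (default FALSE: the bottleneck is ReLU like the other hidden layers).
#' @param validation_fraction Fraction of rows held out for loss monitoring.
#' @param seed Integer seed for weight initialisation, batch order and the
#'   validation split.
#' @return List of class \code{autoencoder_config}.
#' @export
autoencoder_config <- function(encoder_widths = c(32, 16, 8), latent_dim = 8,
                               epochs = 100, batch_size = 32,
                               learning_rate = 0.001, beta1 = 0.9,
                               beta2 = 0.999, l2_penalty = 1e-4,
                               dropout_rate = 0.1, batch_norm = FALSE,
                               linear_latent = FALSE,
                               validation_fraction = 0.1, seed = 1L) {
  stopifnot(latent_dim == encoder_widths[length(encoder_widths)],
            epochs > 0, batch_size > 0,
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(encoder_widths = encoder_widths, latent_dim = latent_dim,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 l2_penalty = l2_penalty, dropout_rate = dropout_rate,
                 batch_norm = batch_norm, linear_latent = linear_latent,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

#' Train the dimensionality-reduction autoencoder
#'
#' Fits a symmetric dense autoencoder (encoder widths
#' \code{config$encoder_widths}, mirrored decoder, linear reconstruction
#' output) on a standardized feature matrix by mini-batch Adam under an MSE
#' loss. A seeded validation split is monitored each epoch.
#'
#' @param x Numeric matrix, standardized, no missing values.
#' @param config An \code{\link{autoencoder_config}}.
#' @return List with \code{encode(newx)} (maps rows to the latent space),
#'   \code{reconstruct(newx)}, \code{latent} (the training rows' embedding),
#'   \code{history} (per-epoch train/validation loss) and the fitted network.
#' @export
train_autoencoder <- function(x, config = autoencoder_config()) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(is.na(x))) stop("input matrix contains missing values")
  d <- ncol(x)
  widths <- c(d, config$encoder_widths,
              rev(config$encoder_widths)[-1], d)
  n_encoder_layers <- length(config$encoder_widths)
  set.seed(config$seed)
  n <- nrow(x)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  train_x <- if (length(val_idx)) x[-val_idx, , drop = FALSE] else x
  val <- if (length(val_idx))
    list(x = x[val_idx, , drop = FALSE], y = x[val_idx, , drop = FALSE])
  else NULL
  trained <- net_train(widths, train_x, train_x, output = "linear",
                       epochs = config$epochs, batch_size = config$batch_size,
                       lr = config$learning_rate, beta1 = config$beta1,
                       beta2 = config$beta2, l2 = config$l2_penalty,
                       dropout = config$dropout_rate, val = val,
                       patience = Inf, seed = config$seed,
                       batch_norm = isTRUE(config$batch_norm),
                       linear_hidden = if (isTRUE(config$linear_latent))
                         n_encoder_layers else integer(0))
  encode <- function(newx) {
    newx <- as.matrix(newx)
    fw <- net_forward(trained$net, newx, output = "linear")
    fw$a[[n_encoder_layers + 1]]
  }
  reconstruct <- function(newx) net_predict(trained, as.matrix(newx))
  list(encode = encode, reconstruct = reconstruct, latent = encode(x),
       history = trained$history, net = trained$net, config = config)
}

#' K-means on the latent space with careful seeding
#'
#' Lloyd's k-means initialised by k-means++-style D^2 seeding, repeated for
#' \code{restarts} seeded restarts, keeping the solution with the smallest
#' total within-cluster sum of squares. Deterministic for a fixed seed; every
#' returned cluster is non-empty. Labels are 0-based to match the published
#' cluster ids.
#'
#' @param latent Numeric matrix of latent coordinates.
#' @param k Number of clusters (>= 2, <= rows).
#' @param seed Base random seed (default 42).
#' @param restarts Number of seeded restarts (default 10).
#' @return Integer vector of cluster labels in \code{0..k-1} with attributes
#'   \code{centers} and \code{tot_withinss}.
#' @export
kmeans_latent <- function(latent, k, seed = 42L, restarts = 10L) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (k < 2) stop("'k' must be at least 2")
  if (n < k) stop("need at least k rows (", k, "), got ", n)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kpp_seed(latent, k)
    fit <- tryCatch(
      stats::kmeans(latent, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit))
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(latent, centers = centers,
                                       iter.max = 100,
                                       algorithm = "MacQueen")),
        error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    # Degenerate input: fewer distinct points than clusters. Keep genuine
    # groups apart and split duplicated points arbitrarily so every cluster
    # is non-empty; splitting coincident points adds no within-cluster
    # scatter.
    distinct <- unique(latent)
    if (nrow(distinct) >= k)
      stop("k-means failed to produce k non-empty clusters")
    lab <- match(split(latent, row(latent)), split(distinct, row(distinct)))
    while (length(unique(lab)) < k) {
      big <- as.integer(names(which.max(table(lab))))
      lab[which(lab == big)[1]] <- max(lab) + 1L
    }
    tw <- sum(vapply(split(seq_len(n), lab), function(ix) {
      ctr <- colMeans(latent[ix, , drop = FALSE])
      sum(sweep(latent[ix, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
    return(structure(as.integer(factor(lab)) - 1L,
                     centers = rowsum(latent, lab) / as.vector(table(lab)),
                     tot_withinss = tw))
  }
  structure(as.integer(best$cluster) - 1L,
            centers = best$centers, tot_withinss = best$tot.withinss)
}

# k-means++ D^2 seeding: each next centre is drawn with probability
# proportional to its squared distance to the nearest chosen centre.
kpp_seed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Mean silhouette width of a clustering
#'
#' @param x Numeric matrix of coordinates.
#' @param labels Cluster labels (any coding; at least two clusters).
#' @return Mean silhouette width over all points.
#' @export
mean_silhouette <- function(x, labels) {
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop("need at least two clusters")
  sil <- cluster::silhouette(f, stats::dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by silhouette score
#'
#' Runs \code{\link{kmeans_latent}} for each candidate k and returns the k
#' maximising the mean silhouette width, with ties broken toward the smaller
#' k.
#'
#' @param latent Numeric latent matrix.
#' @param k_range Candidate cluster counts (default 2 to 10).
#' @param seed Seed passed to each k-means run.
#' @return List with \code{k} (the selected count), \code{silhouette_by_k}
#'   (named numeric vector) and \code{labels} (labels at the selected k).
#' @export
select_k_silhouette <- function(latent, k_range = 2:10, seed = 42L) {
  if (length(k_range) == 0) stop("empty k range")
  latent <- as.matrix(latent)
  if (nrow(latent) <= max(k_range))
    stop("need more rows than the largest candidate k")
  scores <- numeric(length(k_range))
  labels_by_k <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    labels_by_k[[i]] <- kmeans_latent(latent, k_range[i], seed = seed)
    scores[i] <- mean_silhouette(latent, labels_by_k[[i]])
  }
  names(scores) <- k_range
  best <- which(scores == max(scores))[1]  # ties toward smaller k
  list(k = k_range[best], silhouette_by_k = scores,
       labels = labels_by_k[[best]])
}

#' PCA projection with clinically labelled axes
#'
#' Projects the latent space onto its leading principal components (ordered
#' by explained variance) and labels each axis by the two original features
#' whose absolute correlation with that component is largest (ties broken by
#' feature name order), so that axes read as clinical gradients rather than
#' abstract components.
#'
#' @param latent Numeric latent matrix.
#' @param n_components 2 or 3.
#' @param feature_matrix Numeric matrix of the original (encoded) features,
#'   same rows as \code{latent}.
#' @param feature_names Column names for \code{feature_matrix}; defaults to
#'   its colnames.
#' @return List with \code{projection} (n x n_components), \code{axis_labels}
#'   (e.g. \code{"diagnosis + fit_value"}), and \code{explained_variance}
#'   (proportions).
#' @export
pca_project <- function(latent, n_components = 2, feature_matrix,
                        feature_names = colnames(feature_matrix)) {
  latent <- as.matrix(latent)
  if (!n_components %in% c(2, 3)) stop("'n_components' must be 2 or 3")
  if (nrow(latent) < n_components)
    stop("fewer samples than requested components")
  pc <- stats::prcomp(latent, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  proj <- pc$x[, seq_len(nc), drop = FALSE]
  fm <- as.matrix(feature_matrix)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(fm)))
  colnames(fm) <- feature_names
  axis_labels <- vapply(seq_len(nc), function(j) {
    r <- abs(suppressWarnings(stats::cor(proj[, j], fm)))[1, ]
    r[is.na(r)] <- 0
    ord <- order(-r, names(r))
    paste(names(r)[ord[1:2]], collapse = " + ")
  }, character(1))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(projection = proj, axis_labels = axis_labels,
       explained_variance = ev[seq_len(nc)])
}
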