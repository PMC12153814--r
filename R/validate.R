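# Supervised validation of the cluster structure: random-forest feature
# ranking, a feed-forward softmax classifier evaluated by stratified
# cross-validation and an independent hold-out split, and permutation
# feature importance.

#' FFNN validator configuration
#'
#' @param hidden_widths Hidden layer widths, default \code{c(64, 32)}.
#' @param dropout_rate Dropout for the cross-validation models (default 0.5).
#' @param holdout_dropout_rate Dropout for the final hold-out model
#'   (default 0.6).
#' @param l1_penalty L1 weight penalty for the hold-out model (default 1e-4).
#' @param epochs,batch_size Training schedule (default 100 / 32).
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param early_stopping_patience Epochs without validation-loss improvement
#'   before stopping (default 10; must not exceed \code{epochs}).
#' @param cv_folds Stratified cross-validation folds (default 5).
#' @param holdout_fraction Fraction reserved as the independent test set
#'   (default 0.2).
#' @param n_features Number of top-ranked features kept after random-forest
#'   ranking; \code{Inf} keeps all.
#' @param seed Integer seed.
#' @return List of class \code{validator_config}.
#' @export
validator_config <- function(hidden_widths = c(64, 32), dropout_rate = 0.5,
                             holdout_dropout_rate = 0.6, l1_penalty = 1e-4,
                             epochs = 100, batch_size = 32,
                             learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                             early_stopping_patience = 10, cv_folds = 5,
                             holdout_fraction = 0.2, n_features = Inf,
                             seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            early_stopping_patience <= epochs, cv_folds >= 2)
  structure(list(hidden_widths = hidden_widths, dropout_rate = dropout_rate,
                 holdout_dropout_rate = holdout_dropout_rate,
                 l1_penalty = l1_penalty, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 early_stopping_patience = early_stopping_patience,
                 cv_folds = cv_folds, holdout_fraction = holdout_fraction,
                 n_features = n_features, seed = as.integer(seed)),
            class = "validator_config")
}

one_hot <- function(labels, levels) {
  y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  y[cbind(seq_along(labels), match(as.character(labels), levels))] <- 1
  y
}

# Stratified fold assignment: within each class, rows are shuffled and dealt
# round-robin across folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

train_ffnn <- function(x, labels, levels, config, dropout, l1, seed) {
  set.seed(seed)
  n <- nrow(x)
  n_val <- max(1, floor(0.1 * n))
  val_idx <- sample.int(n, n_val)
  widths <- c(ncol(x), config$hidden_widths, length(levels))
  trained <- net_train(widths, x[-val_idx, , drop = FALSE],
                       one_hot(labels[-val_idx], levels),
                       output = "softmax", epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate, beta1 = config$beta1,
                       beta2 = config$beta2, l1 = l1, dropout = dropout,
                       val = list(x = x[val_idx, , drop = FALSE],
                                  y = one_hot(labels[val_idx], levels)),
                       patience = config$early_stopping_patience, seed = seed)
  structure(list(trained = trained, levels = levels,
                 features = colnames(x)), class = "ffnn_model")
}

#' Predict from a fitted FFNN validator model
#'
#' @param object An \code{ffnn_model}.
#' @param newdata Feature matrix with the model's feature columns.
#' @param type \code{"class"} for labels, \code{"prob"} for the softmax
#'   probability matrix.
#' @param ... Unused.
#' @return Labels or probability matrix.
#' @export
predict.ffnn_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  p <- net_predict(object$trained, newdata)
  colnames(p) <- object$levels
  if (type == "prob") p else object$levels[max.col(p, ties.method = "first")]
}

macro_metrics <- function(truth, pred, levels) {
  prec <- rec <- f1 <- numeric(length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    tp <- sum(pred == cl & truth == cl)
    prec[i] <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec[i] <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  c(accuracy = mean(pred == truth), precision = mean(prec),
    recall = mean(rec), f1 = mean(f1))
}

#' Validate cluster assignments with a feed-forward network
#'
#' Reproduces the supervised validation of the unsupervised stratification:
#' features are first ranked by a random forest, the top-ranked set is fed to
#' a two-hidden-layer (64/32) softmax network, and performance is assessed by
#' stratified k-fold cross-validation on 80% of the data plus an independent
#' 20% hold-out model (higher dropout, L1 penalty) trained on the remainder.
#'
#' @param features Numeric feature matrix (named columns).
#' @param labels Cluster labels; at least two classes, each with at least
#'   \code{config$cv_folds} members.
#' @param config A \code{\link{validator_config}}.
#' @return List with \code{feature_ranking} (random-forest importance,
#'   decreasing), \code{fold_metrics} (per-fold accuracy/precision/recall/F1),
#'   \code{cv_accuracy}, \code{auc_by_cluster} (one-vs-rest AUC on the
#'   hold-out set), \code{holdout_accuracy}, \code{holdout_auc} (mean
#'   one-vs-rest), and the fitted hold-out \code{model}.
#' @export
validate_clusters_ffnn <- function(features, labels,
                                   config = validator_config()) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  labels <- as.character(labels)
  levels <- sort(unique(labels))
  if (length(levels) < 2) stop("need at least two classes")
  counts <- table(labels)
  if (any(counts < config$cv_folds))
    stop("every class needs at least ", config$cv_folds, " members")
  set.seed(config$seed)
  # Random-forest feature ranking precedes network training.
  rf <- randomForest::randomForest(x = features, y = factor(labels),
                                   ntree = 200, importance = TRUE)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  ranking <- sort(imp, decreasing = TRUE)
  keep <- names(ranking)[seq_len(min(config$n_features, length(ranking)))]
  x <- features[, keep, drop = FALSE]

  # Independent stratified hold-out split.
  holdout <- unlist(lapply(levels, function(cl) {
    idx <- sample(which(labels == cl))
    idx[seq_len(max(1, round(config$holdout_fraction * length(idx))))]
  }))
  train_idx <- setdiff(seq_len(nrow(x)), holdout)

  # Stratified cross-validation on the training portion.
  fold <- stratified_folds(labels[train_idx], config$cv_folds)
  fold_metrics <- matrix(NA_real_, config$cv_folds, 4,
                         dimnames = list(NULL, c("accuracy", "precision",
                                                 "recall", "f1")))
  for (f in seq_len(config$cv_folds)) {
    tr <- train_idx[fold != f]
    te <- train_idx[fold == f]
    model <- train_ffnn(x[tr, , drop = FALSE], labels[tr], levels, config,
                        dropout = config$dropout_rate, l1 = 0,
                        seed = config$seed + f)
    pred <- predict(model, x[te, , drop = FALSE])
    fold_metrics[f, ] <- macro_metrics(labels[te], pred, levels)
  }

  # Final model on the full training portion, scored on the hold-out.
  model <- train_ffnn(x[train_idx, , drop = FALSE], labels[train_idx], levels,
                      config, dropout = config$holdout_dropout_rate,
                      l1 = config$l1_penalty, seed = config$seed)
  prob <- predict(model, x[holdout, , drop = FALSE], type = "prob")
  pred <- levels[max.col(prob, ties.method = "first")]
  truth <- labels[holdout]
  auc_by_cluster <- vapply(levels, function(cl) {
    pos <- as.integer(truth == cl)
    if (length(unique(pos)) < 2) return(NA_real_)
    auc_mann_whitney(prob[, cl], pos)
  }, numeric(1))
  list(
    feature_ranking = ranking,
    fold_metrics = as.data.frame(fold_metrics),
    cv_accuracy = mean(fold_metrics[, "accuracy"]),
    auc_by_cluster = auc_by_cluster,
    holdout_accuracy = mean(pred == truth),
    holdout_auc = mean(auc_by_cluster, na.rm = TRUE),
    model = model
  )
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean drop in accuracy over \code{n_repeats}
#' random permutations of each feature column, evaluated with the fitted
#' model on the supplied data. Deterministic given \code{seed}.
#'
#' @param model A fitted model with a \code{predict(model, x)} method
#'   returning class labels (e.g. an \code{ffnn_model}).
#' @param features Numeric feature matrix.
#' @param labels True labels.
#' @param n_repeats Number of permutations per feature (>= 1).
#' @param seed Integer seed.
#' @return Named numeric vector of mean accuracy drops, decreasing.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 10,
                                   seed = 1L) {
  if (is.null(model)) stop("'model' must be a fitted model")
  if (n_repeats < 1) stop("'n_repeats' must be at least 1")
  features <- as.matrix(features)
  labels <- as.character(labels)
  baseline <- mean(predict(model, features) == labels)
  set.seed(as.integer(seed))
  drops <- vapply(colnames(features), function(v) {
    mean(vapply(seq_len(n_repeats), function(r) {
      xp <- features
      xp[, v] <- xp[sample.int(nrow(xp)), v]
      baseline - mean(predict(model, xp) == labels)
    }, numeric(1)))
  }, numeric(1))
  sort(drops, decreasing = TRUE)
}
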