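# Shared test fixtures and independent oracles.

# The four published worked cases (inputs and expected complex totals).
worked_cases <- function() {
  data.frame(
    age = c(62, 55, 62, 57),
    fit_value = c(1200, 150, 2158, 89),
    education = c(2, 3, 2, 6),
    environment = c("rural", "urban", "rural", "urban"),
    comorbidity_count = c(2, 0, 3, 0),
    antiplatelet = c(1, 0, 1, 0),
    anticoagulant = c(0, 0, 1, 0),
    sex = c("male", "female", "male", "female"),
    expected_total = c(9, 2, 12, 1),
    stringsAsFactors = FALSE
  )
}

# Brute-force AUC: explicit enumeration of all case-control pairs, ties
# counting one half.
auc_brute_force <- function(values, labels) {
  x <- values[labels == 1]
  y <- values[labels == 0]
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Brute-force mean silhouette width from the textbook definition.
silhouette_brute_force <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Five well-separated Gaussian blobs with distinct random centres.
make_blobs <- function(n_per = 60, d = 8, k = 5, sep = 4, seed = 5) {
  set.seed(seed)
  ctr <- matrix(stats::rnorm(k * d, sd = sep), k, d)
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    sweep(matrix(stats::rnorm(n_per * d), n_per, d), 2, ctr[c, ], "+")))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, labels = rep(seq_len(k) - 1L, each = n_per))
}

# Standardized clustering feature matrix for a participant table.
cohort_features <- function(cohort) clustering_features(cohort)
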