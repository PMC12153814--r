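# Multiple imputation by chained equations (fully conditional specification)
# and Rubin's rules for pooling per-imputation estimates.

impute_initial <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (is.numeric(x)) {
    x[miss] <- mean(x[!miss])
  } else {
    tab <- table(x[!miss])
    x[miss] <- names(tab)[which.max(tab)]
  }
  x
}

# One conditional draw for the missing cells of `target` given the other
# variables: stochastic linear regression for continuous targets, logistic
# for two-level and multinomial for multi-level categorical targets.
impute_one_variable <- function(data, target, miss) {
  predictors <- setdiff(names(data), target)
  form <- stats::reformulate(predictors, response = target)
  y <- data[[target]]
  if (is.numeric(y)) {
    fit <- stats::lm(form, data = data[!miss, , drop = FALSE])
    mu <- stats::predict(fit, newdata = data[miss, , drop = FALSE])
    sigma <- sqrt(sum(stats::residuals(fit)^2) / max(fit$df.residual, 1))
    mu + stats::rnorm(sum(miss), 0, sigma)
  } else {
    yf <- factor(y)
    if (nlevels(yf) < 2) return(rep(levels(yf)[1], sum(miss)))
    if (nlevels(yf) == 2) {
      df <- data; df[[target]] <- yf
      fit <- stats::glm(form, data = df[!miss, , drop = FALSE],
                        family = stats::binomial())
      p <- stats::predict(fit, newdata = df[miss, , drop = FALSE],
                          type = "response")
      levels(yf)[1L + (stats::runif(sum(miss)) < p)]
    } else {
      df <- data; df[[target]] <- yf
      fit <- nnet::multinom(form, data = df[!miss, , drop = FALSE],
                            trace = FALSE)
      p <- stats::predict(fit, newdata = df[miss, , drop = FALSE],
                          type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = sum(miss), byrow = FALSE,
                                       ncol = nlevels(yf))
      apply(p, 1, function(pr) sample(levels(yf), 1, prob = pr))
    }
  }
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells by fully conditional specification: each incomplete
#' variable is visited in turn and its missing cells are redrawn from a
#' conditional model given all other variables (stochastic linear regression
#' for continuous variables, logistic or multinomial regression for
#' categorical ones), iterated for a fixed number of sweeps. Five completed
#' datasets are generated by default, each from an independent chain seeded
#' from \code{seed}; observed cells are never modified. Variables missing in
#' more than 5% of rows are rejected, mirroring the analysis rule that such
#' variables are excluded rather than imputed.
#'
#' @param table Data frame with missing values confined to variables with
#'   missingness at or below 5%.
#' @param n_imputations Number of completed datasets (default 5).
#' @param seed Integer seed; chain \code{i} uses \code{seed + i - 1}.
#' @param sweeps Chained-equation sweeps per imputation (default 10).
#' @param columns Variables usable as predictors and imputation targets;
#'   defaults to every column of \code{table}.
#' @return List of \code{n_imputations} completed data frames.
#' @export
mice_impute <- function(table, n_imputations = 5, seed = 1L, sweeps = 10,
                        columns = names(table)) {
  stopifnot(n_imputations >= 1, sweeps >= 1)
  data0 <- table[, columns, drop = FALSE]
  miss_frac <- vapply(data0, function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac > 0.05))
    stop("variable(s) above 5% missingness: ",
         paste(names(miss_frac)[miss_frac > 0.05], collapse = ", "),
         " (excluded from analysis, not imputed)")
  incomplete <- names(miss_frac)[miss_frac > 0]
  if (length(incomplete) == 0)
    return(replicate(n_imputations, table, simplify = FALSE))
  miss_idx <- lapply(data0[incomplete], is.na)
  lapply(seq_len(n_imputations), function(m) {
    set.seed(as.integer(seed) + m - 1L)
    data <- as.data.frame(lapply(data0, impute_initial),
                          stringsAsFactors = FALSE)
    for (s in seq_len(sweeps)) {
      for (v in incomplete) {
        drawn <- impute_one_variable(data, v, miss_idx[[v]])
        data[[v]][miss_idx[[v]]] <- drawn
      }
    }
    out <- table
    for (v in incomplete) out[[v]][miss_idx[[v]]] <- data[[v]][miss_idx[[v]]]
    out
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation points; the
#' pooled variance is the mean within-imputation variance plus
#' \code{(1 + 1/m)} times the between-imputation variance of the points.
#'
#' @param estimates List of length >= 2; each element a numeric vector or
#'   list with elements \code{point} and \code{variance} (or an unnamed pair
#'   in that order).
#' @return List with \code{point} and \code{variance}.
#' @examples
#' pool_rubin(list(c(0, 1), c(2, 1)))  # point 1, variance 4
#' @export
pool_rubin <- function(estimates) {
  if (length(estimates) < 2)
    stop("at least two imputation estimates are required")
  pt <- vapply(estimates, function(e)
    if (!is.null(names(e)) && "point" %in% names(e)) e[["point"]] else e[[1]],
    numeric(1))
  vr <- vapply(estimates, function(e)
    if (!is.null(names(e)) && "variance" %in% names(e)) e[["variance"]] else e[[2]],
    numeric(1))
  m <- length(pt)
  between <- stats::var(pt)
  list(point = mean(pt), variance = mean(vr) + (1 + 1 / m) * between)
}
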