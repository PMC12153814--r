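test_that("AUC equals the exhaustive concordant-pair count", {
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                       n_boot = 0)$auc, 1)
  # six scores with a tied case-control pair
  vals <- c(3, 5, 5, 1, 2, 4)
  labs <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(vals, labs, n_boot = 0)$auc,
               auc_brute_force(vals, labs))
  # random instances up to n = 30, including heavy ties
  set.seed(51)
  for (r in 1:10) {
    n <- sample(6:30, 1)
    v <- sample(1:5, n, replace = TRUE)
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(roc_auc(v, l, n_boot = 0)$auc, auc_brute_force(v, l))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("ROC curves are monotone and bootstrap intervals bracket the AUC", {
  set.seed(52)
  x <- rnorm(120)
  y <- rbinom(120, 1, plogis(1.5 * x))
  r <- roc_auc(x, y, n_boot = 400, seed = 5)
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  # agreement with an independent implementation
  skip_if_not_installed("pROC")
  pr <- pROC::roc(y, x, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(53)
  v <- rnorm(2000)
  l <- rbinom(2000, 1, 0.3)
  expect_lt(abs(roc_auc(v, l, n_boot = 0)$auc - 0.5), 0.05)
})

test_that("DeLong comparison matches the independent implementation and a jackknife", {
  set.seed(7)
  y <- rep(c(1, 0), each = 10)
  a <- rnorm(20) + y
  b <- rnorm(20) + 0.8 * y
  d <- delong_compare(a, b, y)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(d$p_value, rt$p.value, tolerance = 1e-9)
  # leave-one-out jackknife of the AUC difference as a variance oracle
  th <- vapply(1:20, function(i) {
    ix <- setdiff(1:20, i)
    auc_brute_force(a[ix], y[ix]) - auc_brute_force(b[ix], y[ix])
  }, numeric(1))
  v_jack <- (20 - 1) / 20 * sum((th - mean(th))^2)
  expect_lt(abs(d$variance / v_jack - 1), 0.10)
})

test_that("identical and anti-concordant scores give the expected DeLong limits", {
  y <- c(1, 1, 0, 0, 1, 0)
  v <- c(4, 5, 1, 2, 6, 3)
  same <- delong_compare(v, v, y)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  anti <- delong_compare(v, -v, y)
  expect_equal(anti$delta_auc,
               auc_brute_force(v, y) - auc_brute_force(-v, y))
  expect_error(delong_compare(v[-1], v, y), "equal length")
})

test_that("average precision follows the step-wise definition", {
  expect_equal(pr_curve_ap(c(4, 3, 2, 1), c(1, 1, 0, 0))$average_precision, 1)
  # ranking (+, -, +, -): AP = (1 + 2/3) / 2
  expect_equal(pr_curve_ap(c(4, 3, 2, 1), c(1, 0, 1, 0))$average_precision,
               (1 + 2 / 3) / 2)
  expect_error(pr_curve_ap(1:4, rep(0, 4)), "no positive")
})

test_that("fairness metrics hit their closed-form anchors", {
  # identical behaviour in both groups: spd = eod = 0, dir = 1
  rec <- data.frame(environment = rep(c("rural", "urban"), each = 50),
                    education = rep(3, 100))
  high <- rep(c(TRUE, FALSE, TRUE, FALSE), 25)
  mal <- rep(c(1, 0), 50)
  f <- fairness_audit(rec, high, mal, "environment")
  expect_equal(f$spd, 0)
  expect_equal(f$eod, 0)
  expect_equal(f$dir, 1)
  expect_true(f$dir_within_band)
  # favorable rates 0.4 rural vs 0.5 urban: dir = 0.8, the band edge
  rec2 <- data.frame(environment = rep(c("rural", "urban"), each = 10))
  high2 <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 5), rep(FALSE, 5))
  mal2 <- rep(1, 20)
  f2 <- fairness_audit(rec2, high2, mal2, "environment")
  expect_equal(f2$dir, 0.8)
  expect_true(f2$dir_within_band)
  # the published ratios 0.96 and 1.04 sit inside the accepted band
  expect_true(0.96 >= 0.8 && 0.96 <= 1.25)
  expect_true(1.04 >= 0.8 && 1.04 <= 1.25)
  # a group without malignant cases leaves the TPR difference undefined
  mal3 <- c(rep(0, 10), rep(1, 10))
  f3 <- fairness_audit(rec2, high2, mal3, "environment")
  expect_true(is.na(f3$eod))
})

test_that("fairness education split supports both conventions and reports group AUCs", {
  co <- generate_cohort(cohort_config(seed = 55))
  cx <- score_cohort(co, "complex")$total
  f_low2 <- fairness_audit(co, cx >= 7, co$malignant, "education_band",
                           scores = cx)
  f_low3 <- fairness_audit(co, cx >= 7, co$malignant, "education_band",
                           scores = cx, low_isced_max = 3)
  expect_gt(f_low3$group_sizes["unprivileged"],
            f_low2$group_sizes["unprivileged"])
  expect_true(all(f_low2$auc_by_group > 0.5))
  expect_equal(unname(f_low2$max_auc_gap),
               unname(abs(diff(f_low2$auc_by_group))))
})

test_that("completer comparison reproduces the closed-form tests", {
  co <- generate_cohort(cohort_config(seed = 56))
  self <- completer_comparison(co, co)
  cont <- self[self$test == "welch_t", ]
  expect_equal(cont$statistic, c(0, 0))
  expect_equal(cont$p_value, c(1, 1))
  # chi-square on the published sex 2x2 (840/710 vs 647/628) by hand
  a <- 840; b <- 710; c <- 647; d <- 628
  n <- a + b + c + d
  hand <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  tab <- rbind(c(a, b), c(c, d))
  expect_equal(unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic), hand)
  nc <- generate_noncompleters(1275, seed = 57)
  cmp <- completer_comparison(co, nc)
  expect_equal(nrow(cmp), 7)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_error(completer_comparison(co[0, ], nc), "non-empty")
})

test_that("completion weights recover a known selection model", {
  set.seed(58)
  n <- 5000
  rec <- data.frame(
    age = round(runif(n, 50, 74)),
    sex = sample(c("male", "female"), n, TRUE),
    fit_value = exp(rnorm(n, 5, 1)) + 20,
    environment = sample(c("rural", "urban"), n, TRUE),
    comorbidity_count = sample(0:3, n, TRUE)
  )
  eta <- -0.5 + 0.04 * (rec$age - 62) - 0.3 * (rec$sex == "male") +
    0.25 * (rec$environment == "urban") - 0.15 * rec$comorbidity_count +
    0.001 * (rec$fit_value - 200)
  rec$completed_colonoscopy <- runif(n) < plogis(eta)
  w <- iptw_weights(rec)
  sm <- summary(w$model)$coefficients
  truth <- c(0.04, -0.3, 0.001, 0.25, -0.15)
  est <- sm[c("age", "sexmale", "fit_value", "environmenturban",
              "comorbidity_count"), ]
  expect_true(all(abs(est[, "Estimate"] - truth) < 3 * est[, "Std. Error"]))
  expect_true(all(w$weights > 0))
  # stabilized pseudo-population close to the cohort size
  expect_lt(abs(sum(w$stabilized_weights) / n - 1), 0.1)
})

test_that("independent completion gives unit stabilized weights and unchanged estimates", {
  set.seed(59)
  n <- 2000
  rec <- data.frame(
    age = round(runif(n, 50, 74)),
    sex = sample(c("male", "female"), n, TRUE),
    fit_value = exp(rnorm(n, 5, 1)) + 20,
    environment = sample(c("rural", "urban"), n, TRUE),
    comorbidity_count = sample(0:3, n, TRUE),
    completed_colonoscopy = runif(n) < 0.5
  )
  w <- iptw_weights(rec)
  expect_lt(mean(abs(w$stabilized_weights - 1)), 0.1)
  expect_lt(max(abs(w$stabilized_weights - 1)), 0.6)
  # weighted and unweighted association agree under independent completion
  comp <- rec[rec$completed_colonoscopy, ]
  mal <- rbinom(nrow(comp), 1, plogis(-3 + 0.002 * comp$fit_value))
  if (length(unique(mal)) > 1) {
    wc <- w$stabilized_weights[rec$completed_colonoscopy]
    unw <- glm(mal ~ comp$fit_value, family = binomial())
    wei <- suppressWarnings(glm(mal ~ comp$fit_value, family = binomial(),
                                weights = wc))
    expect_lt(abs(coef(unw)[2] - coef(wei)[2]), 0.002)
  }
  rec$completed_colonoscopy <- TRUE
  expect_error(iptw_weights(rec), "vary")
})
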