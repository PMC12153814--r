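test_that("cohort generation honours cluster sizes, bounds and reproducibility", {
  cfg <- cohort_config(seed = 42)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 1550)
  expect_equal(as.integer(table(co$cluster)), c(55, 242, 677, 423, 153))
  expect_true(all(co$age >= 50 & co$age <= 74))
  expect_true(all(co$age == floor(co$age)))
  expect_true(all(co$fit_value >= 20 & co$fit_value <= 9999.99))
  expect_true(all(co$completed_colonoscopy))
  expect_identical(co, generate_cohort(cohort_config(seed = 42)))
  expect_false(identical(co$fit_value,
                         generate_cohort(cohort_config(seed = 43))$fit_value))
})

test_that("all-empty cluster sizes yield an empty table", {
  specs <- lapply(default_cluster_specs(), function(s) { s$size <- 0L; s })
  co <- generate_cohort(cohort_config(cluster_specs = specs, seed = 1))
  expect_equal(nrow(co), 0)
  expect_true(all(c("age", "fit_value", "diagnosis", "cluster") %in% names(co)))
})

test_that("serrated-adenoma clusters never carry malignant lesions", {
  for (s in c(11, 12, 13)) {
    co <- generate_cohort(cohort_config(seed = s))
    expect_true(all(co$malignant[co$cluster %in% c(1, 4)] == 0))
    expect_true(all(co$diagnosis[co$cluster %in% c(1, 4)] == "serrated_adenoma"))
  }
})

test_that("cluster 0 malignancy rate matches its specification over replicates", {
  rates <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(seed = 500 + s))
    mean(co$malignant[co$cluster == 0])
  }, numeric(1))
  # binomial sampling error oracle: sd of a single replicate is
  # sqrt(.5091 * .4909 / 55) ~ 0.067, so the 20-replicate mean has se ~ 0.015
  expect_lt(abs(mean(rates) - 28 / 55), 0.10)
})

test_that("empirical age and FIT means converge to the cluster moments", {
  specs20 <- lapply(default_cluster_specs(), function(s) {
    s$size <- s$size * 20L
    s
  })
  sums <- Reduce(`+`, lapply(1:5, function(r) {
    co <- generate_cohort(cohort_config(cluster_specs = specs20,
                                        seed = 42 + r))
    cbind(fit = tapply(co$fit_value, co$cluster, mean),
          age = tapply(co$age, co$cluster, mean))
  })) / 5
  targets <- cbind(
    fit = vapply(default_cluster_specs(), `[[`, numeric(1), "fit_mean"),
    age = vapply(default_cluster_specs(), `[[`, numeric(1), "age_mean"))
  expect_true(all(abs(sums - targets) / targets < 0.02))
})

test_that("invalid cluster specifications are rejected", {
  s <- default_cluster_specs()[[1]]
  expect_error(
    cluster_spec(0, 55, s$age_mean, s$age_sd, s$fit_mean, s$fit_sd,
                 s$sex_male_prob, s$rural_prob,
                 s$education_probs * 2,  # does not sum to 1
                 s$comorbidity_probs, s$diagnosis_probs, s$malignancy_rate),
    "sum to 1")
  expect_error(
    cluster_spec(0, 55, s$age_mean, s$age_sd, s$fit_mean, s$fit_sd,
                 s$sex_male_prob, s$rural_prob, s$education_probs,
                 s$comorbidity_probs, s$diagnosis_probs,
                 malignancy_rate = 0.9),  # inconsistent with diagnosis mass
    "inconsistent")
})

test_that("missingness injection hits its target rates and enforces the 5% rule", {
  co <- generate_cohort(cohort_config(seed = 2))
  expect_identical(inject_missingness(co, numeric(0)), co)
  rates <- c(age = 0.021, fit_value = 0.034, education = 0.018,
             environment = 0.009, comorbidity_category = 0.027)
  mis <- inject_missingness(co, rates, seed = 9)
  for (v in names(rates)) {
    n_miss <- sum(is.na(mis[[v]]))
    expected <- 1550 * rates[[v]]
    sd3 <- 3 * sqrt(1550 * rates[[v]] * (1 - rates[[v]]))
    expect_lt(abs(n_miss - expected), sd3)
  }
  expect_gt(sum(is.na(mis$age)), 0)
  expect_error(inject_missingness(co, c(age = 0.06)), "5%")
  expect_error(inject_missingness(co, c(nonexistent = 0.01)), "unknown")
})

test_that("non-completer generation matches the reported profile", {
  expect_error(generate_noncompleters(-1), "non-negative")
  expect_equal(nrow(generate_noncompleters(0)), 0)
  nc <- generate_noncompleters(1275, seed = 4)
  expect_equal(nrow(nc), 1275)
  expect_true(all(!nc$completed_colonoscopy))
  expect_true(all(is.na(nc$diagnosis)))
  # oracle: analytic mean of a normal(63.4, 7) truncated to [50, 74]
  a <- (50 - 63.4) / 7; b <- (74 - 63.4) / 7
  z <- pnorm(b) - pnorm(a)
  mu_trunc <- 63.4 - 7 * (dnorm(b) - dnorm(a)) / z
  se <- 7 / sqrt(1275)
  expect_lt(abs(mean(nc$age) - mu_trunc), 3 * se)
  expect_lt(abs(mean(nc$age) - 63.4), 1.0)  # close to the reported mean
  expect_lt(abs(mean(nc$sex == "male") - 0.508), 3 * sqrt(0.5 * 0.5 / 1275))
})

test_that("non-completers drawn from the completer profile are exchangeable", {
  co <- generate_cohort(cohort_config(seed = 6))
  nc <- generate_noncompleters(800, completer_table = co, seed = 7)
  tt <- t.test(co$age, nc$age)
  expect_gt(tt$p.value, 0.001)
})

test_that("band fixtures difference the cumulative tables exactly", {
  bands <- published_band_fixture("complex")
  expect_equal(bands$n_patients[bands$score_value == 12], 3)
  expect_equal(bands$n_cancers[bands$score_value == 12], 3)
  expect_equal(bands$n_patients[bands$score_value == 10], 8)
  expect_equal(bands$n_cancers[bands$score_value == 10], 7)
  expect_equal(sum(bands$n_patients), 1550)
  expect_equal(sum(bands$n_cancers), 111)
  for (kind in c("simplified", "fit_only")) {
    b <- published_band_fixture(kind)
    expect_equal(sum(b$n_patients), 1550)
    expect_equal(sum(b$n_cancers), 111)
    expect_true(all(b$n_cancers >= 0 & b$n_cancers <= b$n_patients))
  }
  expect_error(published_band_fixture("unknown"), "unknown")
})

test_that("expanded pseudo-records re-cumulate to the fixture", {
  bands <- published_band_fixture("simplified")
  fx <- expand_band_fixture(bands)
  expect_equal(nrow(fx), 1550)
  expect_equal(sum(fx$malignant), 111)
  for (t in bands$score_value) {
    expect_equal(sum(fx$value >= t),
                 sum(bands$n_patients[bands$score_value >= t]))
    expect_equal(sum(fx$malignant[fx$value >= t]),
                 sum(bands$n_cancers[bands$score_value >= t]))
  }
})
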