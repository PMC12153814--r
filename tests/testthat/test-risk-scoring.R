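test_that("the published worked cases score exactly", {
  wc <- worked_cases()
  got <- score_complex(wc$age, wc$fit_value, wc$education, wc$environment,
                       wc$comorbidity_count, wc$antiplatelet,
                       wc$anticoagulant, wc$sex)
  expect_equal(got$total, wc$expected_total)
  # component breakdown of the first case: 4 + 2 + 1 + 1 + 1
  expect_equal(unlist(got[1, 1:5], use.names = FALSE), c(4, 2, 1, 1, 1))
  # minimum attainable with sex included is 1 (the Age+FIT floor)
  expect_equal(score_complex(55, 30, 6, "urban", 0, 0, 0, "female")$total, 1)
})

test_that("score domains enforce their preconditions", {
  expect_error(score_complex(62, 15, 2, "rural", 2, 1, 0, "male"), "FIT below 20")
  expect_error(score_complex(NA, 1200, 2, "rural", 2, 1, 0, "male"), "age")
  expect_error(score_complex(62, 1200, 9, "rural", 2, 1, 0, "male"), "ISCED")
  expect_error(score_complex(62, 1200, 2, "suburban", 2, 1, 0, "male"),
               "rural or urban")
  expect_error(score_simplified(62, NA, 2), "fit_value")
})

test_that("the simplified score follows its three-domain bands", {
  expect_equal(score_simplified(55, 150, 0)$total, 0)   # minimum
  expect_equal(score_simplified(72, 2500, 3)$total, 7)  # maximum
  # the worked high-risk case under the simplified bands: 2 + 1 + 1
  s <- score_simplified(62, 1200, 2)
  expect_equal(unlist(s[1, ], use.names = FALSE), c(2, 1, 1, 4))
})

test_that("band enumeration covers the full range without gaps", {
  grid <- expand.grid(
    age = c(55, 65, 72),
    fit_value = c(100, 500, 1500, 3000),
    education = c(1, 3, 6),
    environment = c("rural", "urban"),
    comorbidity_count = c(0, 2, 3),
    antiplatelet = 0:1,
    anticoagulant = 0:1,
    sex = c("male", "female"),
    stringsAsFactors = FALSE
  )
  cx <- score_complex(grid$age, grid$fit_value, grid$education,
                      grid$environment, grid$comorbidity_count,
                      grid$antiplatelet, grid$anticoagulant, grid$sex)
  expect_true(all(cx$total >= 1 & cx$total <= 12))
  expect_setequal(unique(cx$total), 1:12)  # every total attainable, no gaps
  expect_equal(cx$total,
               rowSums(cx[, c("age_fit_points", "education_env_points",
                              "comorbidity_points", "medication_points",
                              "sex_points")]))
  nosex <- score_complex(grid$age, grid$fit_value, grid$education,
                         grid$environment, grid$comorbidity_count,
                         grid$antiplatelet, grid$anticoagulant, grid$sex,
                         include_sex = FALSE)
  expect_true(all(nosex$total >= 1 & nosex$total <= 11))
  expect_true(all(nosex$sex_points == 0))
  sp <- score_simplified(grid$age, grid$fit_value, grid$comorbidity_count)
  expect_true(all(sp$total >= 0 & sp$total <= 7))
  expect_setequal(unique(sp$total), 0:7)
})

test_that("both scores are monotone in every risk factor", {
  base <- list(age = 55, fit = 100, edu = 6, env = "urban", com = 0,
               ap = 0, ac = 0, sex = "female")
  total_cx <- function(b) score_complex(b$age, b$fit, b$edu, b$env, b$com,
                                        b$ap, b$ac, b$sex)$total
  total_sp <- function(b) score_simplified(b$age, b$fit, b$com)$total
  bump <- function(b, field, value) { b[[field]] <- value; b }
  # FIT escalation
  for (fits in list(c(100, 500), c(500, 1500), c(1500, 3000))) {
    expect_lte(total_cx(bump(base, "fit", fits[1])),
               total_cx(bump(base, "fit", fits[2])))
    expect_lte(total_sp(bump(base, "fit", fits[1])),
               total_sp(bump(base, "fit", fits[2])))
  }
  # age, comorbidity, medication, education, environment, sex
  expect_lte(total_cx(base), total_cx(bump(base, "age", 65)))
  expect_lte(total_sp(bump(base, "age", 65)), total_sp(bump(base, "age", 72)))
  expect_lte(total_cx(base), total_cx(bump(base, "com", 2)))
  expect_lte(total_cx(bump(base, "com", 2)), total_cx(bump(base, "com", 4)))
  expect_lte(total_cx(base), total_cx(bump(base, "ap", 1)))
  expect_lte(total_cx(bump(base, "ap", 1)), total_cx(bump(base, "ac", 1)))
  expect_lte(total_cx(base), total_cx(bump(base, "edu", 3)))
  expect_lte(total_cx(bump(base, "edu", 3)), total_cx(bump(base, "edu", 1)))
  expect_lte(total_cx(base), total_cx(bump(base, "env", "rural")))
  expect_lte(total_cx(base), total_cx(bump(base, "sex", "male")))
})

test_that("triage maps totals onto the three-tier grid", {
  expect_equal(triage(9)$category, "high")
  expect_equal(triage(2)$category, "low")
  expect_equal(triage(5)$category, "moderate")
  got <- triage(0:12)
  expect_equal(got$category,
               c(rep("low", 4), rep("moderate", 3), rep("high", 6)))
  expect_equal(unique(got$recommendation[got$category == "high"]),
               "immediate colonoscopy")
  expect_error(triage(13), "0-12")
  expect_error(triage(-1), "0-12")
})

test_that("Youden thresholds match exhaustive enumeration", {
  # perfect separation: J = 1 at the lowest integer above the controls
  out <- youden_threshold(c(10, 10, 10, 1, 1, 1), c(1, 1, 1, 0, 0, 0))
  expect_equal(out$J, 1)
  expect_equal(out$threshold, 2)
  # toy set with overlap, against a brute-force sweep
  scores <- c(5, 6, 7, 1, 2, 5)
  flags <- c(1, 1, 1, 0, 0, 0)
  oracle <- local({
    cand <- 1:7
    js <- sapply(cand, function(t)
      mean(scores[flags == 1] >= t) + mean(scores[flags == 0] < t) - 1)
    list(threshold = cand[which.max(js)], J = max(js))
  })
  got <- youden_threshold(scores, flags)
  expect_equal(got$J, oracle$J)
  expect_equal(got$threshold, oracle$threshold)
  expect_error(youden_threshold(c(1, 2, 3), c(1, 1, 1)), "both classes")
})

test_that("cohort scoring applies row-wise and respects the no-sex switch", {
  co <- generate_cohort(cohort_config(seed = 8))
  cx <- score_cohort(co, "complex")
  expect_equal(nrow(cx), nrow(co))
  expect_true(all(cx$total >= 1 & cx$total <= 12))
  nosex <- score_cohort(co, "complex", include_sex = FALSE)
  expect_equal(cx$total - nosex$total, as.integer(co$sex == "male"))
  sp <- score_cohort(co, "simplified")
  expect_true(all(sp$total >= 0 & sp$total <= 7))
})
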