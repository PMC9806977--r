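test_that("score_phq9 sums items and flags depression at the cutoff", {
  expect_equal(score_phq9(rep(3, 9))$total, 27)
  expect_true(score_phq9(rep(3, 9))$depression)
  s <- score_phq9(c(1, 1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(s$total, 3)
  expect_false(s$depression)
  # cutoff boundary: 10 is indicative of depression
  expect_true(score_phq9(c(2, 2, 2, 2, 2, 0, 0, 0, 0))$depression)
  expect_false(score_phq9(c(2, 2, 2, 2, 1, 0, 0, 0, 0))$depression)
})

test_that("score_phq9 validates items instead of silently imputing", {
  expect_error(score_phq9(c(rep(1, 8), NA)), class = "trialcea_validation_error")
  expect_error(score_phq9(rep(1, 8)), class = "trialcea_validation_error")
  expect_error(score_phq9(c(rep(1, 8), 4)), class = "trialcea_validation_error")
  expect_error(score_phq9(c(rep(1, 8), 1.5)), class = "trialcea_validation_error")
})

test_that("score_phq9 is permutation-invariant and additive", {
  withr::with_seed(42, {
    for (i in 1:25) {
      items <- sample(0:3, 9, replace = TRUE)
      expect_equal(score_phq9(sample(items))$total, score_phq9(items)$total)
      expect_equal(score_phq9(items)$total, sum(items))
    }
  })
})

test_that("phq_change is followup minus baseline with range validation", {
  expect_equal(phq_change(20, 20), 0)
  expect_equal(phq_change(15, 9), -6)
  expect_error(phq_change(-1, 5), class = "trialcea_validation_error")
  expect_error(phq_change(5, 28), class = "trialcea_validation_error")
  # linearity: arm total change equals n times the arm mean change
  withr::with_seed(7, {
    b <- sample(5:27, 60, replace = TRUE)
    f <- pmax(b - sample(0:10, 60, replace = TRUE), 0)
    expect_equal(sum(phq_change(b, f)), 60 * mean(phq_change(b, f)))
  })
})

test_that("map_disability is the clamped linear predictor with clamp accounting", {
  co <- mapping_coefficients(intercept = 0.1,
                             item_weights = stats::setNames(rep(0.05, 8), paste0("d", 1:8)),
                             covariate_weights = numeric(0))
  items0 <- as.data.frame(as.list(stats::setNames(rep(0, 12), paste0("d", 1:12))))
  expect_equal(as.numeric(map_disability(items0, coeffs = co)), 0.1)
  items2 <- items0 + 2
  expect_equal(as.numeric(map_disability(items2, coeffs = co)), 0.1 + 0.05 * 16)
  # linear predictor 0.1 + 0.05*8*3 = 1.3 -> clamped to 1, clamp counted
  items3 <- items0 + 3
  d <- map_disability(items3, coeffs = co)
  expect_equal(as.numeric(d), 1)
  expect_equal(attr(d, "n_clamped"), 1L)
  expect_equal(attr(map_disability(items2, coeffs = co), "n_clamped"), 0L)
})

test_that("map_disability rejects references to absent items or covariates", {
  co <- mapping_coefficients()
  expect_error(map_disability(data.frame(d1 = 1), coeffs = co),
               class = "trialcea_config_error")
  items <- as.data.frame(as.list(stats::setNames(rep(1, 12), paste0("d", 1:12))))
  expect_error(map_disability(items, covariates = data.frame(age = 30), coeffs = co),
               class = "trialcea_config_error")
  expect_silent(map_disability(items, covariates = data.frame(female = 1), coeffs = co))
})

test_that("disability is monotone in items with nonnegative weights", {
  co <- mapping_coefficients()
  withr::with_seed(13, {
    for (i in 1:20) {
      items <- as.data.frame(as.list(stats::setNames(sample(0:3, 12, TRUE), paste0("d", 1:12))))
      cov <- data.frame(female = 1)
      base <- as.numeric(map_disability(items, cov, co))
      j <- sample(names(co$item_weights), 1)
      items[[j]] <- items[[j]] + 1
      expect_gte(as.numeric(map_disability(items, cov, co)), base)
    }
  })
})

test_that("health_status is one minus disability on [0,1]", {
  expect_equal(health_status(0), 1)
  expect_equal(health_status(1), 0)
  expect_equal(health_status(0.3), 0.7)
  expect_error(health_status(1.2), class = "trialcea_validation_error")
  expect_error(health_status(-0.1), class = "trialcea_validation_error")
})

test_that("qaly_auc is the trapezoid AUC over the 12-month horizon", {
  expect_equal(qaly_auc(c(0, 3, 12), c(1, 1, 1)), 1)
  expect_equal(qaly_auc(c(0, 3, 12), c(0.5, 0.5, 0.5)), 0.5)
  # hand-computed trapezoid: (0.5*(0.6+0.8)*3 + 0.5*(0.8+0.8)*9)/12
  expect_equal(qaly_auc(c(0, 3, 12), c(0.6, 0.8, 0.8)), 0.775)
})

test_that("qaly_auc validates its trajectory", {
  expect_error(qaly_auc(0, 1), class = "trialcea_validation_error")
  expect_error(qaly_auc(c(0, 13), c(1, 1)), class = "trialcea_validation_error")
  expect_error(qaly_auc(c(3, 0), c(1, 1)), class = "trialcea_validation_error")
  expect_error(qaly_auc(c(0, 12), c(1, 1.1)), class = "trialcea_validation_error")
})

test_that("qaly_auc equals the closed form for any linear trajectory", {
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- stats::runif(1, 0.2, 0.8)
      b <- stats::runif(1, -0.01, 0.01)
      times <- sort(c(0, stats::runif(3, 1, 11), 12))
      statuses <- a + b * times
      # AUC/12 of a linear function equals its value at the midpoint month 6
      expect_equal(qaly_auc(times, statuses), a + 6 * b, tolerance = 1e-12)
    }
  })
})
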