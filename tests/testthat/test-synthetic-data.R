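test_that("generate_trial produces the configured counts, ranges and schema", {
  cfg <- small_config(n_per_arm = 60)
  ds <- generate_trial(cfg)
  expect_s3_class(ds, "trial_data")
  expect_equal(nrow(ds$roster), 120)
  expect_equal(as.integer(table(ds$roster$arm)[cfg$arm_labels]), c(60L, 60L))
  # every participant has item vectors at all three timepoints
  expect_equal(nrow(ds$phq), 360)
  expect_equal(nrow(ds$whodas), 360)
  p <- as.matrix(ds$phq[paste0("p", 1:9)])
  w <- as.matrix(ds$whodas[paste0("d", 1:12)])
  expect_true(all(p %in% 0:3))
  expect_true(all(w %in% 0:4))
  expect_true(all(ds$service_use$quantity >= 0))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(n_per_arm = 10, seed = 99L)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  # different seed changes the data
  cfg2 <- small_config(n_per_arm = 10, seed = 100L)
  expect_false(identical(generate_trial(cfg)$phq, generate_trial(cfg2)$phq))
})

test_that("invalid configurations are rejected as configuration errors", {
  expect_error(trial_config(n_per_arm = 0), class = "trialcea_config_error")
  expect_error(trial_config(cost_shape = -1), class = "trialcea_config_error")
  expect_error(trial_config(dropout_prob = c(ST = -0.1, `T+P` = 0.2)),
               class = "trialcea_config_error")
  expect_error(trial_config(whodas_item_means = rbind(rep(5, 3), rep(1, 3))),
               class = "trialcea_config_error")
})

test_that("zero arm effect yields no systematic 12-month PHQ arm difference", {
  # Monte-Carlo check across >= 200 seeds on the null world
  diffs <- vapply(1:200, function(s) {
    ds <- generate_trial(null_config(n_per_arm = 15, seed = s))
    tot <- rowSums(ds$phq[paste0("p", 1:9)])
    m12 <- ds$phq$timepoint == 12
    arm <- ds$roster$arm[match(ds$phq$participant_id[m12], ds$roster$participant_id)]
    mean(tot[m12][arm == "T+P"]) - mean(tot[m12][arm == "ST"])
  }, numeric(1))
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se)
})

test_that("dropout is monotone, MAR-calibrated, and leaves baseline intact", {
  cfg <- small_config(n_per_arm = 40, seed = 3L)
  ds <- apply_missingness(generate_trial(cfg), cfg)
  tab <- build_analysis_table(ds)
  expect_false(anyNA(tab$phq_0))
  expect_false(anyNA(tab$status_0))
  # monotone: missing at 3 months implies missing at 12 months
  expect_true(all(is.na(tab$phq_12[is.na(tab$phq_3)])))
  expect_true(all(is.na(tab$status_12[is.na(tab$status_3)])))

  # dropout_prob = 0 in both arms: nothing missing
  cfg0 <- small_config(n_per_arm = 10, dropout_prob = c(ST = 0, `T+P` = 0))
  expect_false(anyNA(build_analysis_table(apply_missingness(generate_trial(cfg0), cfg0))))

  # dropout_prob = 1: all follow up missing, baseline intact
  cfg1 <- small_config(n_per_arm = 10, dropout_prob = c(ST = 1, `T+P` = 1))
  t1 <- build_analysis_table(apply_missingness(generate_trial(cfg1), cfg1))
  expect_false(anyNA(t1$phq_0))
  expect_true(all(is.na(t1$phq_12)))
  expect_true(all(is.na(t1$status_12)))
})

test_that("realized dropout matches configured probabilities across seeds", {
  # 100 generated trials x 5 missingness streams each = 500 seeds
  rates <- matrix(NA_real_, 500, 2)
  k <- 0
  for (g in 1:100) {
    cfg <- small_config(n_per_arm = 60, seed = 1000L + g)
    ds <- generate_trial(cfg)
    for (r in 1:5) {
      cfg2 <- cfg
      cfg2$seed <- 1000L * r + g
      dm <- apply_missingness(ds, cfg2)
      k <- k + 1
      rates[k, ] <- tapply(dm$roster$last_seen < 12, dm$roster$arm, mean)[cfg$arm_labels]
    }
  }
  expect_lt(abs(mean(rates[, 1]) - 0.15), 0.02)
  expect_lt(abs(mean(rates[, 2]) - 0.23), 0.02)
})

test_that("ground truth is analytic, linear in cost shifts, and null under no effect", {
  gt0 <- ground_truth(null_config())
  expect_equal(gt0$true_delta_phq, 0)
  expect_equal(gt0$true_delta_qaly, 0, tolerance = 1e-12)
  expect_equal(gt0$true_delta_cost, 0)

  # +200 Int$ mean cost in T+P only (400 extra participant-time hours at 0.5)
  cfg <- small_config(n_per_arm = 60)
  qm <- cfg$quantity_means
  qm[["T+P"]]["mental_time_hours"] <- qm[["T+P"]]["mental_time_hours"] + 400
  cfg2 <- small_config(n_per_arm = 60, quantity_means = qm)
  expect_equal(ground_truth(cfg2)$true_delta_cost,
               ground_truth(cfg)$true_delta_cost + 200 * 60)

  # configured PHQ effects: closed-form difference of configured means
  eff <- cfg$phq_time_effects
  expect_equal(ground_truth(cfg)$true_delta_phq,
               60 * ((eff[2, 3] - eff[2, 1]) - (eff[1, 3] - eff[1, 1])))
  expect_equal(ground_truth(cfg)$implied_icer,
               ground_truth(cfg)$true_delta_cost / ground_truth(cfg)$true_delta_qaly)
})

test_that("generated instrument means hit the configured trajectories in expectation", {
  # the discretization inversion makes configured means exact; check by MC
  cfg <- small_config(n_per_arm = 300, seed = 11L)
  ds <- generate_trial(cfg)
  tot <- rowSums(ds$phq[paste0("p", 1:9)])
  arm <- ds$roster$arm[match(ds$phq$participant_id, ds$roster$participant_id)]
  for (a in 1:2) {
    sel <- arm == cfg$arm_labels[a] & ds$phq$timepoint == 12
    target <- cfg$phq_baseline_mean + cfg$phq_time_effects[a, 3]
    se <- stats::sd(tot[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(tot[sel]) - target), 4 * se)
  }
})

test_that("YAML configuration overrides merge into defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_per_arm: 12",
    "seed: 77",
    "dropout_prob: {ST: 0.1, T+P: 0.3}",
    "mapping:",
    "  intercept: 0.2",
    "  item_weights: {d1: 0.01, d2: 0.01, d3: 0.01, d4: 0.01, d5: 0.01, d6: 0.01, d7: 0.01, d8: 0.01}",
    "  population_tag: test-set"
  ), path)
  cfg <- read_trial_config(path)
  expect_equal(cfg$n_per_arm, 12L)
  expect_equal(cfg$seed, 77L)
  expect_equal(unname(cfg$dropout_prob), c(0.1, 0.3))
  expect_equal(cfg$mapping$intercept, 0.2)
  expect_equal(cfg$mapping$population_tag, "test-set")
  expect_equal(cfg$phq_baseline_mean, 16) # untouched default
})

test_that("write_trial_data round-trips the CSV schemas", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_per_arm = 5)
  ds <- apply_missingness(generate_trial(cfg), cfg)
  paths <- write_trial_data(ds, dir)
  expect_true(all(file.exists(paths)))
  roster <- utils::read.csv(paths[["roster"]])
  expect_equal(nrow(roster), 10)
  gt <- jsonlite::read_json(paths[["ground_truth"]])
  expect_equal(gt$implied_icer, ground_truth(cfg)$implied_icer, tolerance = 1e-9)
})
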