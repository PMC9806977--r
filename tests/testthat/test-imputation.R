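# A small complete analysis-table-like frame for controlled deletion tests.
make_complete <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    arm <- rep(c("ST", "T+P"), each = n / 2)
    x <- stats::rnorm(n, 10, 2)
    data.frame(participant_id = sprintf("P%03d", 1:n), arm = arm,
               x = x,
               y = 5 + 0.8 * x + (arm == "T+P") * 2 + stats::rnorm(n),
               z = stats::rgamma(n, 2, 0.1),
               stringsAsFactors = FALSE)
  })
}

test_that("a dataset with no missing cells yields m identical copies", {
  d <- make_complete(40)
  ens <- impute_pmm(d, imputation_spec(n_imputations = 3, seed = 5))
  expect_length(ens$datasets, 3)
  for (k in 1:3) expect_identical(ens$datasets[[k]], d)
  expect_length(ens$targets, 0)
})

test_that("imputed values are observed donor values and observed cells are untouched", {
  d <- make_complete(80)
  dmiss <- d
  withr::with_seed(2, {
    dmiss$y[sample(80, 16)] <- NA
    dmiss$z[sample(80, 20)] <- NA
  })
  ens <- impute_pmm(dmiss, imputation_spec(n_imputations = 4,
                                           max_iterations = 5, seed = 9))
  for (k in seq_along(ens$datasets)) {
    comp <- ens$datasets[[k]]
    expect_false(anyNA(comp))
    for (v in c("y", "z")) {
      obs_idx <- !is.na(dmiss[[v]])
      # observed cells bit-identical
      expect_identical(comp[[v]][obs_idx], dmiss[[v]][obs_idx])
      # PMM membership: every imputed value is an observed value of v
      expect_true(all(comp[[v]][!obs_idx] %in% dmiss[[v]][obs_idx]))
    }
  }
})

test_that("the ensemble is deterministic under the spec seed", {
  d <- make_complete(60)
  d$y[1:10] <- NA
  s <- imputation_spec(n_imputations = 3, max_iterations = 3, seed = 31)
  expect_identical(impute_pmm(d, s)$datasets, impute_pmm(d, s)$datasets)
  s2 <- imputation_spec(n_imputations = 3, max_iterations = 3, seed = 32)
  expect_false(identical(impute_pmm(d, s)$datasets, impute_pmm(d, s2)$datasets))
})

test_that("degenerate inputs are rejected", {
  d <- make_complete(30)
  d$y <- NA_real_
  expect_error(impute_pmm(d, imputation_spec(seed = 1)),
               class = "trialcea_config_error")
  d2 <- make_complete(30)
  d2$arm[3] <- NA
  d2$y[5] <- NA
  expect_error(impute_pmm(d2, imputation_spec(seed = 1)),
               class = "trialcea_config_error")
  expect_error(imputation_spec(n_imputations = 1), class = "trialcea_config_error")
  expect_error(imputation_spec(donors = 0), class = "trialcea_config_error")
})

test_that("MCAR deletion is recovered without bias (Monte Carlo)", {
  # >= 100 repetitions: pooled mean of the deleted variable vs complete mean
  errs <- vapply(1:100, function(r) {
    d <- make_complete(60, seed = 100 + r)
    dm <- d
    withr::with_seed(200 + r, dm$y[sample(60, 12)] <- NA)
    ens <- impute_pmm(dm, imputation_spec(n_imputations = 3,
                                          max_iterations = 3, seed = 300 + r))
    mean(vapply(ens$datasets, function(k) mean(k$y), numeric(1))) - mean(d$y)
  }, numeric(1))
  mc_se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * mc_se)
})

test_that("pool_cea_inputs pools per-dataset totals with variance decomposition", {
  cfg <- small_config(n_per_arm = 15, seed = 21,
                      dropout_prob = c(ST = 0, `T+P` = 0))
  ds <- generate_trial(cfg)
  tab <- build_analysis_table(ds)
  ens <- impute_pmm(tab, imputation_spec(n_imputations = 3, seed = 4))
  pooled <- pool_cea_inputs(ens, cfg$ledger)
  # complete data: all m datasets identical, between-imputation variance 0
  expect_true(all(pooled$pooled$between_var == 0))
  pp <- pooled$per_participant
  st_cost <- pooled$pooled$pooled[pooled$pooled$arm == "ST" &
                                    pooled$pooled$quantity == "cost"]
  expect_equal(st_cost, sum(pp$cost[pp$arm == "ST"]))
  # QALYs agree with qaly_auc applied row by row
  q1 <- qaly_auc(c(0, 3, 12),
                 unlist(tab[1, c("status_0", "status_3", "status_12")]))
  expect_equal(pp$qaly[1], unname(q1))
})

test_that("pooling two hand-built datasets averages their totals", {
  base <- data.frame(participant_id = c("a", "b"), arm = c("ST", "T+P"),
                     status_0 = 0.5, status_3 = 0.5, status_12 = 0.5,
                     phq_0 = 10, phq_12 = c(8, 6), phq_3 = 9,
                     cost_mental_w1 = 0, cost_mental_w2 = 0,
                     cost_physical_w1 = 0, cost_physical_w2 = 0,
                     stringsAsFactors = FALSE)
  d2 <- base
  d2$cost_mental_w1 <- c(2, 2)
  ens <- structure(list(datasets = list(base, d2),
                        spec = imputation_spec(seed = 1),
                        targets = "cost_mental_w1", diagnostics = NULL),
                   class = "imputed_ensemble")
  led <- implementation_ledger(
    data.frame(activity = "none", total_cost = 0, share_ST = 0, share_TP = 0))
  pooled <- pool_cea_inputs(ens, led)$pooled
  st <- pooled[pooled$arm == "ST" & pooled$quantity == "cost", ]
  expect_equal(st$pooled, mean(c(0, 2))) # totals 0 and 2 pool to 1
})
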