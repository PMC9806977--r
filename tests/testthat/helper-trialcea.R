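# Shared fixtures: everything is generated in code, nothing is read from disk.

# A small, fast trial configuration for structural tests.
small_config <- function(n_per_arm = 20, seed = 1L, ...) {
  trial_config(n_per_arm = n_per_arm, seed = seed, ...)
}

# A configuration with no arm differences at all (null world).
null_config <- function(n_per_arm = 20, seed = 1L) {
  qm <- default_quantity_means()
  qm[["T+P"]] <- qm[["ST"]]
  trial_config(
    n_per_arm = n_per_arm, seed = seed,
    phq_time_effects = rbind(c(0, -4, -5.54), c(0, -4, -5.54)),
    whodas_item_means = rbind(c(1.8, 0.95, 0.88), c(1.8, 0.95, 0.88)),
    quantity_means = qm,
    dropout_prob = c(ST = 0, `T+P` = 0),
    p_female = c(0.85, 0.85),
    # symmetric implementation costs so the null world has zero delta cost
    ledger = implementation_ledger(
      data.frame(activity = "training", total_cost = 329000,
                 share_ST = 0.5, share_TP = 0.5),
      horizon_years = 5, users_per_year = c(ST = 100, `T+P` = 100))
  )
}

# Wrap raw (delta_cost, delta_effect) replicates as a bootstrap_set so the
# uncertainty operations can be tested against hand-built replicate lists.
fake_bootstrap_set <- function(delta_cost, delta_effect) {
  structure(list(
    replicates = data.frame(delta_cost = delta_cost,
                            delta_effect = delta_effect,
                            icer = ifelse(delta_effect == 0, NA_real_,
                                          delta_cost / delta_effect)),
    B = length(delta_cost), seed = 0L,
    arm_sizes = c(A = 1L, B = 1L),
    point = list(delta_cost = mean(delta_cost),
                 delta_effect = mean(delta_effect)),
    pairing_checksum = "fixture"
  ), class = "bootstrap_set")
}

# Per-participant cost/QALY/PHQ-change values from a complete trial, without
# going through imputation (complete data only).
complete_per_participant <- function(dataset) {
  tab <- build_analysis_table(dataset)
  stopifnot(!anyNA(tab))
  impl <- vapply(tab$arm,
                 function(a) amortize_implementation(dataset$config$ledger, a),
                 numeric(1))
  data.frame(
    participant_id = tab$participant_id, arm = tab$arm,
    cost = tab$cost_mental_w1 + tab$cost_mental_w2 +
      tab$cost_physical_w1 + tab$cost_physical_w2 + impl,
    qaly = (1.5 * tab$status_0 + 6 * tab$status_3 + 4.5 * tab$status_12) / 12,
    phq_change = tab$phq_12 - tab$phq_0,
    stringsAsFactors = FALSE)
}
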