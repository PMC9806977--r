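#' Generate a complete synthetic two-arm trial
#'
#' Draws a full trial dataset (before any dropout) under the generative model
#' described in [trial_config()]: each participant carries latent person
#' effects for depression (PHQ-9) and disability (WHODAS-12); item responses
#' are the latent arm-by-time mean plus person effect plus item noise,
#' rounded and clamped to the instrument range; service-use quantities are
#' gamma draws (right-skewed) optionally coupled to the disability latent.
#'
#' All randomness derives from `config$seed` through per-participant
#' sub-streams, so regenerating any participant is reproducible and the full
#' dataset is byte-identical under a fixed seed.
#'
#' @param config A [trial_config()].
#' @return An object of class `trial_data`: a list with data.frames
#'   `roster` (participant_id, arm, age, female), `phq` (long over
#'   timepoints, items `p1`..`p9`), `whodas` (items `d1`..`d12`),
#'   `service_use` (participant_id, window, category, quantity), plus the
#'   `unit_costs` table and the generating `config`.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "trial_config")) stop_config("config must be a trial_config")
  n <- config$n_per_arm
  arms <- rep(config$arm_labels, each = n)
  ids <- sprintf("P%04d", seq_len(2L * n))
  tps <- config$timepoints

  roster <- data.frame(participant_id = ids, arm = arms,
                       age = NA_real_, female = NA_integer_,
                       stringsAsFactors = FALSE)
  lat <- latent_trajectories(config)
  phq_rows <- vector("list", 2L * n)
  who_rows <- vector("list", 2L * n)
  use_rows <- vector("list", 2L * n)

  cats <- config$unit_costs$category
  window_share <- c(`0-3` = 3 / 12, `3-12` = 9 / 12)

  for (i in seq_len(2L * n)) {
    a <- if (i <= n) 1L else 2L
    withr::with_seed(derive_seed(config$seed, i), {
      roster$age[i] <- stats::rnorm(1, config$age_mean[a], config$age_sd[a])
      roster$female[i] <- stats::rbinom(1, 1, config$p_female[a])
      u_p <- stats::rnorm(1, 0, config$phq_person_sd)
      u_w <- stats::rnorm(1, 0, config$whodas_person_sd)

      pv <- matrix(NA_integer_, 3, 9)
      wv <- matrix(NA_integer_, 3, 12)
      for (t in 1:3) {
        pv[t, ] <- pmin(pmax(round(lat$phq[a, t] + u_p +
                                     stats::rnorm(9, 0, config$phq_item_sd)), 0L), 3L)
        wv[t, ] <- pmin(pmax(round(lat$whodas[a, t] + u_w +
                                     stats::rnorm(12, 0, config$whodas_item_sd)), 0L), 4L)
      }
      phq_rows[[i]] <- data.frame(participant_id = ids[i], timepoint = tps,
                                  pv, stringsAsFactors = FALSE)
      who_rows[[i]] <- data.frame(participant_id = ids[i], timepoint = tps,
                                  wv, stringsAsFactors = FALSE)

      # severity-cost coupling: mean-one lognormal in the disability z-score
      cc <- config$cost_severity_corr
      mult <- exp(cc * u_w / config$whodas_person_sd - cc^2 / 2)
      mu_q <- config$quantity_means[[a]][cats]
      mu_q[is.na(mu_q)] <- 0
      qs <- lapply(names(window_share), function(w) {
        m <- mu_q * window_share[[w]] * mult
        q <- ifelse(m > 0,
                    stats::rgamma(length(m), shape = config$cost_shape,
                                  scale = m / config$cost_shape), 0)
        data.frame(participant_id = ids[i], window = w, category = cats,
                   quantity = unname(q), stringsAsFactors = FALSE)
      })
      use_rows[[i]] <- do.call(rbind, qs)
    })
  }

  phq <- do.call(rbind, phq_rows)
  names(phq)[3:11] <- paste0("p", 1:9)
  whodas <- do.call(rbind, who_rows)
  names(whodas)[3:14] <- paste0("d", 1:12)

  structure(list(roster = roster, phq = phq, whodas = whodas,
                 service_use = do.call(rbind, use_rows),
                 unit_costs = config$unit_costs, config = config),
            class = "trial_data")
}

#' Apply missing-at-random monotone dropout to a complete trial
#'
#' Each participant's dropout probability is `plogis(a_arm + b * (phq0 -
#' mean(phq0)))` where `b` is `config$dropout_phq_slope` and the arm
#' intercept `a_arm` is calibrated so the mean probability over the realized
#' baseline sample equals `config$dropout_prob[arm]` (MAR: dependence only on
#' arm and observed baseline severity). Dropout is monotone: a participant
#' lost before 3 months is also missing at 12 months; baseline is never
#' missing. Follow-up PHQ/WHODAS items are set to `NA` and service-use rows
#' in unobserved windows are dropped.
#'
#' @param dataset A complete `trial_data` from [generate_trial()].
#' @param config The generating [trial_config()].
#' @return A `trial_data` whose roster gains a `last_seen` column (12, 3 or 0
#'   months) and whose follow-up records reflect the dropout pattern.
#' @export
apply_missingness <- function(dataset, config = dataset$config) {
  stopifnot(inherits(dataset, "trial_data"))
  roster <- dataset$roster
  phq0 <- phq_totals_wide(dataset)$phq_0
  last_seen <- rep(12, nrow(roster))

  withr::with_seed(derive_seed(config$seed, 0L), {
    for (a in seq_along(config$arm_labels)) {
      arm <- config$arm_labels[a]
      idx <- which(roster$arm == arm)
      target <- config$dropout_prob[[arm]]
      if (target <= 0) next
      b <- config$dropout_phq_slope
      x <- phq0[idx] - mean(phq0[idx])
      a_int <- if (target >= 1) Inf else if (b == 0) stats::qlogis(target) else {
        stats::uniroot(function(v) mean(stats::plogis(v + b * x)) - target,
                       lower = -30, upper = 30)$root
      }
      p <- stats::plogis(a_int + b * x)
      dropped <- stats::runif(length(idx)) < p
      early <- stats::runif(length(idx)) < config$dropout_early_fraction
      last_seen[idx[dropped & early]] <- 0
      last_seen[idx[dropped & !early]] <- 3
    }
  })

  roster$last_seen <- last_seen
  miss3 <- roster$participant_id[last_seen < 3]
  miss12 <- roster$participant_id[last_seen < 12]
  blank <- function(df, cols) {
    df[df$timepoint == 3 & df$participant_id %in% miss3, cols] <- NA
    df[df$timepoint == 12 & df$participant_id %in% miss12, cols] <- NA
    df
  }
  dataset$phq <- blank(dataset$phq, paste0("p", 1:9))
  dataset$whodas <- blank(dataset$whodas, paste0("d", 1:12))
  su <- dataset$service_use
  keep <- !(su$window == "0-3" & su$participant_id %in% miss3) &
    !(su$window == "3-12" & su$participant_id %in% miss12)
  dataset$service_use <- su[keep, , drop = FALSE]
  dataset$roster <- roster
  dataset
}

# Latent per-item means (arm x time) solved so that the rounded, clamped
# responses hit the configured observed-scale means exactly in expectation.
latent_trajectories <- function(config) {
  sd_p <- sqrt(config$phq_person_sd^2 + config$phq_item_sd^2)
  sd_w <- sqrt(config$whodas_person_sd^2 + config$whodas_item_sd^2)
  phq <- whodas <- matrix(NA_real_, 2, 3)
  for (a in 1:2) {
    for (t in 1:3) {
      target_p <- (config$phq_baseline_mean + config$phq_time_effects[a, t]) / 9
      phq[a, t] <- latent_from_item_mean(target_p, sd_p, 0, 3)
      whodas[a, t] <- latent_from_item_mean(config$whodas_item_means[a, t],
                                            sd_w, 0, 4)
    }
  }
  list(phq = phq, whodas = whodas)
}

#' Analytic ground truth for a synthetic trial configuration
#'
#' Computes the expected incremental cost, QALYs and PHQ change implied by a
#' [trial_config()] in closed form (no simulation). Because the generator
#' inverts the discretization (latent means are solved so rounded, clamped
#' responses hit the configured observed-scale means exactly in expectation),
#' expected instrument means equal the configured trajectories; expected
#' service costs are gamma means times unit costs (the severity multiplier
#' has mean one); implementation costs come from the amortization rule.
#' Deltas are on the program-total scale (per-participant difference times
#' `n_per_arm`).
#'
#' The disability-index clamp to \[0,1\] is ignored here; with the default
#' world the linear predictor stays interior so clamping is a negligible
#' rare-event correction (see the methods vignette).
#'
#' @param config A [trial_config()].
#' @return Object of class `ground_truth`: list with per-arm expected
#'   trajectories and `true_delta_cost`, `true_delta_qaly`, `true_delta_phq`,
#'   `implied_icer`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  map <- config$mapping

  e_phq <- matrix(NA_real_, 2, 3)
  e_status <- matrix(NA_real_, 2, 3)
  e_qaly <- numeric(2)
  e_cost <- numeric(2)
  for (a in 1:2) {
    for (t in 1:3) {
      e_phq[a, t] <- config$phq_baseline_mean + config$phq_time_effects[a, t]
      lin <- map$intercept +
        sum(map$item_weights) * config$whodas_item_means[a, t]
      if ("female" %in% names(map$covariate_weights)) {
        lin <- lin + map$covariate_weights[["female"]] * config$p_female[a]
      }
      e_status[a, t] <- 1 - lin
    }
    e_qaly[a] <- (1.5 * e_status[a, 1] + 6 * e_status[a, 2] +
                    4.5 * e_status[a, 3]) / 12
    arm <- config$arm_labels[a]
    q <- config$quantity_means[[a]]
    uc <- stats::setNames(config$unit_costs$unit_cost, config$unit_costs$category)
    e_cost[a] <- sum(q * uc[names(q)]) +
      amortize_implementation(config$ledger, arm)
  }

  n <- config$n_per_arm
  d_cost <- n * (e_cost[2] - e_cost[1])
  d_qaly <- n * (e_qaly[2] - e_qaly[1])
  d_phq <- n * ((e_phq[2, 3] - e_phq[2, 1]) - (e_phq[1, 3] - e_phq[1, 1]))
  structure(list(
    expected_phq = e_phq, expected_status = e_status,
    expected_qaly_per_participant = e_qaly,
    expected_cost_per_participant = e_cost,
    true_delta_cost = d_cost, true_delta_qaly = d_qaly,
    true_delta_phq = d_phq,
    implied_icer = if (d_qaly != 0) d_cost / d_qaly else NA_real_
  ), class = "ground_truth")
}

# Wide per-participant PHQ totals (phq_0, phq_3, phq_12); NA where a whole
# timepoint is missing.
phq_totals_wide <- function(dataset) {
  tot <- rowSums(dataset$phq[paste0("p", 1:9)])
  out <- data.frame(participant_id = unique(dataset$phq$participant_id),
                    stringsAsFactors = FALSE)
  for (t in c(0, 3, 12)) {
    m <- dataset$phq$timepoint == t
    out[[paste0("phq_", t)]] <-
      tot[m][match(out$participant_id, dataset$phq$participant_id[m])]
  }
  out
}

#' Write a synthetic trial to CSV files plus ground truth JSON
#'
#' Emits `roster.csv`, `phq_long.csv`, `whodas_long.csv`, `service_use.csv`,
#' `unit_costs.csv` and `ground_truth.json` into `dir`.
#'
#' @param dataset A `trial_data`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of written paths.
#' @export
write_trial_data <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(roster = file.path(dir, "roster.csv"),
             phq = file.path(dir, "phq_long.csv"),
             whodas = file.path(dir, "whodas_long.csv"),
             service_use = file.path(dir, "service_use.csv"),
             unit_costs = file.path(dir, "unit_costs.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  for (nm in c("roster", "phq", "whodas", "service_use", "unit_costs")) {
    utils::write.csv(dataset[[nm]], paths[[nm]], row.names = FALSE)
  }
  gt <- ground_truth(dataset$config)
  jsonlite::write_json(gt[c("true_delta_cost", "true_delta_qaly",
                            "true_delta_phq", "implied_icer")],
                       paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
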