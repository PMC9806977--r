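#' Average an imputed ensemble into one completed analysis table
#'
#' Cell-wise mean of the numeric analysis variables across the m completed
#' datasets (observed cells are identical across datasets, so they are
#' returned unchanged).
#'
#' @param ensemble An [impute_pmm()] result.
#' @return A single data.frame with the ensemble-averaged values.
#' @export
ensemble_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "imputed_ensemble"))
  out <- ensemble$datasets[[1]]
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  for (d in ensemble$datasets[-1]) {
    for (v in num) out[[v]] <- out[[v]] + d[[v]]
  }
  for (v in num) out[[v]] <- out[[v]] / length(ensemble$datasets)
  out
}

#' Run the full economic evaluation on one (possibly incomplete) trial
#'
#' Sequences the analysis stages: analysis-table construction, chained-
#' equation imputation with predictive mean matching (skipped implicitly
#' when nothing is missing), pooling, cost profiling, incremental
#' cost-effectiveness under the program-total and per-participant
#' approaches for both effect measures, and paired bootstrap uncertainty
#' (percentile CI, threshold fractions, acceptability curve).
#'
#' @param dataset A `trial_data` (typically from [generate_trial()] +
#'   [apply_missingness()], or assembled from CSV inputs).
#' @param B Bootstrap replicates (default 1000).
#' @param n_imputations Imputations m (default 20).
#' @param seed Seed for imputation and bootstrap sub-streams.
#' @param thresholds A [threshold_config()].
#' @param mapping Optional [mapping_coefficients()] override.
#' @return Object of class `cea_analysis`: list with `analysis_table`,
#'   `ensemble_mean`, `inputs` (pooled totals), `profile`, `results`
#'   (cea_result objects `qaly_total`, `phq_total`, `qaly_per_participant`,
#'   `phq_per_participant`), `bootstrap` (QALY scale), `bootstrap_phq`,
#'   `ci_qaly`, `ci_phq`, `threshold_fractions`, `ceac`.
#' @export
analyze_trial <- function(dataset, B = 1000, n_imputations = 20, seed = 1L,
                          thresholds = threshold_config(),
                          mapping = dataset$config$mapping) {
  stopifnot(inherits(dataset, "trial_data"))
  arms <- dataset$config$arm_labels
  tab <- build_analysis_table(dataset, mapping)
  spec <- imputation_spec(n_imputations = n_imputations,
                          seed = derive_seed(seed, 101L))
  ens <- impute_pmm(tab, spec)
  inputs <- pool_cea_inputs(ens, dataset$config$ledger)
  avg <- ensemble_average(ens)

  delivery <- data.frame(
    participant_id = avg$participant_id,
    cost_mental = avg$cost_mental_w1 + avg$cost_mental_w2,
    cost_physical = avg$cost_physical_w1 + avg$cost_physical_w2,
    stringsAsFactors = FALSE)
  profile <- cost_profile(delivery, dataset$roster, dataset$config$ledger)

  pooled <- inputs$pooled
  tot <- function(a, q) pooled$pooled[pooled$arm == a & pooled$quantity == q]
  arm_totals <- function(q) data.frame(
    arm = arms, cost = c(tot(arms[1], "cost"), tot(arms[2], "cost")),
    effect = c(tot(arms[1], q), tot(arms[2], q)), stringsAsFactors = FALSE)

  inc_q <- incremental(arm_totals("qaly"))
  inc_p <- incremental(arm_totals("phq_change"))
  pp <- inputs$per_participant
  results <- list(
    qaly_total = icer(inc_q$delta_cost, inc_q$delta_effect, "QALY"),
    phq_total = icer(inc_p$delta_cost, inc_p$delta_effect, "PHQ"),
    qaly_per_participant = per_participant_icer(
      pp$cost, pp$qaly, pp$arm, arm_order = arms, effect_measure = "QALY"),
    phq_per_participant = per_participant_icer(
      pp$cost, pp$phq_change, pp$arm, arm_order = arms, effect_measure = "PHQ")
  )

  boot_in <- data.frame(arm = pp$arm, cost = pp$cost, effect = pp$qaly)
  bs <- boot_cea(boot_in, B = B, seed = derive_seed(seed, 202L), arm_order = arms)
  boot_in_p <- data.frame(arm = pp$arm, cost = pp$cost, effect = pp$phq_change)
  bs_p <- boot_cea(boot_in_p, B = B, seed = derive_seed(seed, 203L), arm_order = arms)
  safe_ci <- function(b) tryCatch(percentile_ci(b), error = function(e) {
    c(lower = NA_real_, upper = NA_real_)
  })

  structure(list(
    analysis_table = tab, ensemble_mean = avg, inputs = inputs,
    profile = profile, results = results,
    bootstrap = bs, bootstrap_phq = bs_p,
    ci_qaly = safe_ci(bs), ci_phq = safe_ci(bs_p),
    threshold_fractions = threshold_fraction(bs, thresholds),
    ceac = ceac(bs, thresholds$lambda_grid),
    thresholds = thresholds, seed = as.integer(seed)
  ), class = "cea_analysis")
}

#' Render paper-shaped tables and figures
#'
#' Writes the cost-profile table (arm x block medians/means), the
#' incremental cost-effectiveness table (full precision alongside values
#' rounded in the conventional reporting style: costs to whole Int$, QALYs
#' to 2 decimals, ICERs to whole Int$ per QALY and cents per PHQ point),
#' the mean outcome trajectories, the cost-effectiveness plane with rays at
#' the configured thresholds, and the acceptability curve.
#'
#' @param analysis A [analyze_trial()] result.
#' @param out_dir Output directory.
#' @return Invisibly, named vector of written file paths.
#' @export
render_tables_figures <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "cea_analysis"))
  if (nrow(analysis$bootstrap$replicates) == 0L) {
    stop_validation("empty bootstrap set: nothing to render")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cost_profile = file.path(out_dir, "cost_profile.csv"),
             incremental = file.path(out_dir, "incremental_table.csv"),
             trajectories = file.path(out_dir, "trajectories.csv"),
             fig_trajectories = file.path(out_dir, "fig_trajectories.svg"),
             fig_ce_plane = file.path(out_dir, "fig_ce_plane.svg"),
             fig_ceac = file.path(out_dir, "fig_ceac.svg"))

  utils::write.csv(as.data.frame(analysis$profile), paths[["cost_profile"]],
                   row.names = FALSE)

  res <- analysis$results
  inc <- data.frame(
    effect_measure = c("QALY", "PHQ"),
    approach = "program-total",
    delta_cost = c(res$qaly_total$delta_cost, res$phq_total$delta_cost),
    delta_effect = c(res$qaly_total$delta_effect, res$phq_total$delta_effect),
    icer = c(res$qaly_total$icer, res$phq_total$icer),
    ci_lower = c(analysis$ci_qaly[["lower"]], analysis$ci_phq[["lower"]]),
    ci_upper = c(analysis$ci_qaly[["upper"]], analysis$ci_phq[["upper"]]),
    stringsAsFactors = FALSE)
  inc$delta_cost_rounded <- round(inc$delta_cost)
  inc$delta_effect_rounded <- round(inc$delta_effect, 2)
  inc$icer_rounded <- c(round(inc$icer[1]), round(inc$icer[2], 2))
  utils::write.csv(inc, paths[["incremental"]], row.names = FALSE)

  avg <- analysis$ensemble_mean
  tr <- do.call(rbind, lapply(unique(avg$arm), function(a) {
    s <- avg[avg$arm == a, ]
    data.frame(arm = a, timepoint = c(0, 3, 12),
               mean_status = c(mean(s$status_0), mean(s$status_3), mean(s$status_12)),
               mean_phq = c(mean(s$phq_0), mean(s$phq_3), mean(s$phq_12)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tr, paths[["trajectories"]], row.names = FALSE)

  grDevices::svg(paths[["fig_trajectories"]], width = 9, height = 4.5)
  graphics::par(mfrow = c(1, 2))
  cols <- c("#1b6ca8", "#c44536")
  for (panel in c("mean_status", "mean_phq")) {
    ylab <- if (panel == "mean_status") "Mean health status" else "Mean PHQ-9 total"
    graphics::plot(NA, xlim = c(0, 12), ylim = range(tr[[panel]]),
                   xlab = "Months", ylab = ylab, xaxt = "n")
    graphics::axis(1, at = c(0, 3, 12))
    for (k in seq_along(unique(tr$arm))) {
      s <- tr[tr$arm == unique(tr$arm)[k], ]
      graphics::lines(s$timepoint, s[[panel]], type = "b", col = cols[k], pch = 16)
    }
    graphics::legend("topright", legend = unique(tr$arm), col = cols, lty = 1, pch = 16)
  }
  grDevices::dev.off()

  reps <- analysis$bootstrap$replicates
  grDevices::svg(paths[["fig_ce_plane"]], width = 6, height = 5)
  graphics::plot(reps$delta_effect, reps$delta_cost, pch = 16,
                 col = grDevices::adjustcolor("#1b6ca8", 0.35),
                 xlab = "Incremental effect (QALYs)",
                 ylab = "Incremental cost (Int$2020)",
                 main = "Cost-effectiveness plane")
  graphics::abline(h = 0, v = 0, col = "grey60")
  for (l in analysis$thresholds$thresholds) {
    graphics::abline(a = 0, b = l, lty = 2, col = "grey30")
  }
  grDevices::dev.off()

  grDevices::svg(paths[["fig_ceac"]], width = 6, height = 4.5)
  graphics::plot(analysis$ceac$lambda, analysis$ceac$p_cost_effective,
                 type = "l", ylim = c(0, 1), lwd = 2, col = "#1b6ca8",
                 xlab = "Willingness to pay (Int$ per QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve")
  graphics::abline(v = analysis$thresholds$thresholds, lty = 2, col = "grey30")
  grDevices::dev.off()

  invisible(paths)
}

#' Run the end-to-end pipeline and write all artifacts
#'
#' Simulates a trial (or uses a supplied one), applies dropout, runs
#' [analyze_trial()], renders tables and figures, and writes a run manifest
#' recording the configuration hash, seeds, package version and a digest of
#' every output file, so any output is traceable and reproducible from the
#' manifest alone.
#'
#' @param config A [trial_config()].
#' @param out_dir Output directory.
#' @param dataset Optional pre-built `trial_data`; when `NULL` the trial is
#'   simulated from `config` and dropout applied.
#' @param B,n_imputations,seed,thresholds Passed to [analyze_trial()];
#'   `seed` defaults to the config seed.
#' @return The `cea_analysis`, invisibly, with the manifest path in
#'   attribute `manifest`.
#' @export
run_pipeline <- function(config = trial_config(), out_dir,
                         dataset = NULL, B = 1000, n_imputations = 20,
                         seed = config$seed, thresholds = threshold_config()) {
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(dataset)) {
      dataset <- apply_missingness(generate_trial(config), config)
    }
    stage <- "analyze"
    analysis <- analyze_trial(dataset, B = B, n_imputations = n_imputations,
                              seed = seed, thresholds = thresholds)
    stage <- "render"
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data_paths <- write_trial_data(dataset, file.path(out_dir, "inputs"))
    fig_paths <- render_tables_figures(analysis, out_dir)
    stage <- "manifest"
    outputs <- c(data_paths, fig_paths)
    digests <- vapply(outputs, function(p) fnv1a32(readBin(p, "raw", file.size(p))),
                      character(1))
    manifest <- list(
      config_hash = fnv1a32(config),
      seeds = list(config = config$seed, analysis = seed),
      package_version = as.character(utils::packageVersion("trialcea")),
      timestamp = format(Sys.time(), tz = "UTC"),
      outputs = as.list(stats::setNames(unname(digests), unname(outputs))))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    attr(analysis, "manifest") <- manifest_path
    analysis
  }, error = function(e) {
    stop(errorCondition(sprintf("pipeline failed at stage '%s': %s",
                                stage, conditionMessage(e)),
                        class = c("trialcea_pipeline_error", "error")))
  })
  invisible(res)
}
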