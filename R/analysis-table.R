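#' Build the per-participant analysis table
#'
#' Reduces item-level trial data to the analysis variables the evaluation
#' operates on (and the imputation model imputes): per-timepoint health
#' status and PHQ-9 total, and per-window delivery costs by block. A
#' timepoint whose items are missing (dropout) yields `NA` in the
#' corresponding analysis cells; baseline is always observed.
#'
#' @param dataset A `trial_data` (complete or after [apply_missingness()]).
#' @param mapping A [mapping_coefficients()]; defaults to the one in the
#'   dataset's config.
#' @return data.frame with one row per participant: `participant_id`, `arm`,
#'   `age`, `female`, `phq_0`, `phq_3`, `phq_12`, `status_0`, `status_3`,
#'   `status_12`, `cost_mental_w1`, `cost_mental_w2`, `cost_physical_w1`,
#'   `cost_physical_w2` (w1 = months 0-3, w2 = months 3-12).
#' @export
build_analysis_table <- function(dataset, mapping = dataset$config$mapping) {
  stopifnot(inherits(dataset, "trial_data"))
  roster <- dataset$roster
  out <- roster[c("participant_id", "arm", "age", "female")]

  phq <- phq_totals_wide(dataset)
  out <- merge(out, phq, by = "participant_id", sort = FALSE)

  for (t in c(0, 3, 12)) {
    rows <- dataset$whodas[dataset$whodas$timepoint == t, , drop = FALSE]
    rows <- rows[match(out$participant_id, rows$participant_id), , drop = FALSE]
    ok <- stats::complete.cases(rows[paste0("d", 1:12)])
    st <- rep(NA_real_, nrow(out))
    if (any(ok)) {
      cov <- out[ok, , drop = FALSE]
      d <- map_disability(rows[ok, , drop = FALSE], cov, mapping)
      st[ok] <- health_status(as.numeric(d))
    }
    out[[paste0("status_", t)]] <- st
  }

  windows <- c(`0-3` = "w1", `3-12` = "w2")
  for (w in names(windows)) {
    su <- dataset$service_use[dataset$service_use$window == w, , drop = FALSE]
    costs <- service_cost(su, dataset$unit_costs, participants = out$participant_id)
    observed <- out$participant_id %in% unique(su$participant_id)
    for (b in c("mental", "physical")) {
      v <- costs[[paste0("cost_", b)]]
      v[!observed] <- NA_real_
      out[[paste0("cost_", b, "_", windows[[w]])]] <- v
    }
  }
  out
}
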