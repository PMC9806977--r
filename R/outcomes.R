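#' Score the PHQ-9
#'
#' Sums the nine item responses (each 0-3) to the 0-27 severity total and
#' flags probable depression at the validated cutoff (total >= 10).
#'
#' @param items Numeric vector of length 9, or an n x 9 matrix/data.frame of
#'   item responses, each value an integer in 0-3. Missing values are a
#'   validation error: imputation happens upstream, never silently here.
#' @param cutoff Depression cutoff on the total score (default 10).
#' @return A list with `total` (length n) and `depression` (logical).
#' @export
score_phq9 <- function(items, cutoff = 10) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (ncol(m) != 9L) stop_validation("PHQ-9 requires exactly 9 items")
  if (anyNA(m)) stop_validation("PHQ-9 items contain missing values")
  if (any(m < 0 | m > 3 | m != round(m))) {
    stop_validation("PHQ-9 items must be integers in 0-3")
  }
  total <- rowSums(m)
  list(total = total, depression = total >= cutoff)
}

#' Change in PHQ-9 total between two timepoints
#'
#' @param baseline,followup Totals in 0-27 (vectors recycle as usual).
#' @return `followup - baseline`; negative values indicate improvement.
#' @export
phq_change <- function(baseline, followup) {
  if (any(stats::na.omit(c(baseline, followup)) < 0) ||
      any(stats::na.omit(c(baseline, followup)) > 27)) {
    stop_validation("PHQ-9 totals must be in [0, 27]")
  }
  followup - baseline
}

#' Map WHODAS items and covariates to a disability index
#'
#' Linear predictor `intercept + sum(w_j * item_j) + sum(v_k * covariate_k)`
#' clamped to \[0,1\]. The number of clamping events is recorded in the
#' `n_clamped` attribute of the result so heavy clamping is visible.
#'
#' @param items A data.frame/matrix with the WHODAS item columns named
#'   `d1`..`d12` (only the 8 referenced by `coeffs` are used), one row per
#'   observation.
#' @param covariates A data.frame with the covariate columns referenced by
#'   `coeffs$covariate_weights` (may be zero-column if none).
#' @param coeffs A [mapping_coefficients()].
#' @return Numeric vector of disability indices in \[0,1\], with attribute
#'   `n_clamped`.
#' @export
map_disability <- function(items, covariates = NULL, coeffs = mapping_coefficients()) {
  items <- as.data.frame(items)
  miss <- setdiff(names(coeffs$item_weights), names(items))
  if (length(miss)) stop_config("mapping references absent items: ",
                                paste(miss, collapse = ", "))
  lin <- coeffs$intercept +
    as.matrix(items[names(coeffs$item_weights)]) %*% coeffs$item_weights
  lin <- as.numeric(lin)
  if (length(coeffs$covariate_weights)) {
    covariates <- as.data.frame(covariates)
    missc <- setdiff(names(coeffs$covariate_weights), names(covariates))
    if (length(missc)) stop_config("mapping references absent covariates: ",
                                   paste(missc, collapse = ", "))
    lin <- lin + as.numeric(
      as.matrix(covariates[names(coeffs$covariate_weights)]) %*%
        coeffs$covariate_weights)
  }
  out <- pmin(pmax(lin, 0), 1)
  attr(out, "n_clamped") <- sum(lin < 0 | lin > 1)
  out
}

#' Health status from disability
#'
#' `status = 1 - disability`: one is full health, zero is death.
#'
#' @param disability Disability index values in \[0,1\].
#' @return Health status values in \[0,1\].
#' @export
health_status <- function(disability) {
  d <- as.numeric(disability)
  if (anyNA(d) || any(d < 0) || any(d > 1)) {
    stop_validation("disability index must be in [0, 1]")
  }
  1 - d
}

#' QALYs by area under the health-status curve
#'
#' Trapezoidal integral of health status over the follow-up horizon, divided
#' by the horizon length, so a constant status of 1 over 12 months yields
#' exactly 1 QALY.
#'
#' @param times Measurement times in months, strictly increasing, within
#'   \[0, horizon_months\].
#' @param statuses Health statuses in \[0,1\] at those times.
#' @param horizon_months Follow-up horizon (default 12).
#' @return QALYs accrued over the horizon, in \[0, horizon_months/12\].
#' @export
qaly_auc <- function(times, statuses, horizon_months = 12) {
  if (length(times) < 2L) stop_validation("need at least 2 trajectory points")
  if (length(times) != length(statuses)) stop_validation("times/statuses length mismatch")
  if (is.unsorted(times, strictly = TRUE)) stop_validation("times must be strictly increasing")
  if (any(times < 0) || any(times > horizon_months)) {
    stop_validation("times must lie within [0, horizon_months]")
  }
  if (anyNA(statuses) || any(statuses < 0) || any(statuses > 1)) {
    stop_validation("statuses must be in [0, 1]")
  }
  auc <- sum(diff(times) * (utils::head(statuses, -1) + utils::tail(statuses, -1)) / 2)
  auc / 12
}
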