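#' Incremental cost and effect between arms
#'
#' Deltas are intervention minus comparator (second arm minus first).
#'
#' @param arm_totals data.frame with columns `arm`, `cost`, `effect` and one
#'   row per arm (comparator first), e.g. pooled program totals.
#' @return list with `delta_cost` and `delta_effect`.
#' @export
incremental <- function(arm_totals) {
  if (nrow(arm_totals) != 2L) stop_config("arm_totals must have exactly 2 rows")
  list(delta_cost = arm_totals$cost[2] - arm_totals$cost[1],
       delta_effect = arm_totals$effect[2] - arm_totals$effect[1])
}

ce_quadrant <- function(delta_cost, delta_effect) {
  if (delta_effect > 0 && delta_cost >= 0) "NE"
  else if (delta_effect > 0 && delta_cost < 0) "SE"
  else if (delta_effect < 0 && delta_cost < 0) "SW"
  else if (delta_effect < 0 && delta_cost >= 0) "NW"
  else NA_character_
}

#' Incremental cost-effectiveness ratio
#'
#' `icer = delta_cost / delta_effect`, reported at full precision with the
#' cost-effectiveness-plane quadrant (effect on x, cost on y). A zero
#' incremental effect yields an explicit undefined status rather than a
#' number. The native sign convention is kept: an improvement measured as a
#' negative PHQ change yields a negative ICER (cost per point of change),
#' restated positively "per point decrease" in reports.
#'
#' @param delta_cost Incremental cost (Int$2020).
#' @param delta_effect Incremental effect (QALYs or PHQ points).
#' @param effect_measure Label, e.g. `"QALY"` or `"PHQ"`.
#' @param approach `"program-total"` or `"per-participant"`.
#' @return Object of class `cea_result`: list with `delta_cost`,
#'   `delta_effect`, `icer` (NA when undefined), `status` (`"defined"` or
#'   `"undefined"`), `quadrant`, `effect_measure`, `approach`.
#' @export
icer <- function(delta_cost, delta_effect, effect_measure = "QALY",
                 approach = "program-total") {
  undefined <- !is.finite(delta_effect) || delta_effect == 0
  structure(list(
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = if (undefined) NA_real_ else delta_cost / delta_effect,
    status = if (undefined) "undefined" else "defined",
    quadrant = if (undefined) NA_character_ else ce_quadrant(delta_cost, delta_effect),
    dominant = if (undefined) NA else (delta_effect > 0 && delta_cost < 0),
    effect_measure = effect_measure, approach = approach
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA result (%s, %s)\n", x$approach, x$effect_measure))
  cat(sprintf("  delta cost:   %.2f Int$\n", x$delta_cost))
  cat(sprintf("  delta effect: %.4f %s\n", x$delta_effect, x$effect_measure))
  if (x$status == "defined") {
    cat(sprintf("  ICER:         %.2f Int$ per %s (quadrant %s%s)\n",
                x$icer, x$effect_measure, x$quadrant,
                if (isTRUE(x$dominant)) ", dominant" else ""))
  } else {
    cat("  ICER:         undefined (zero incremental effect)\n")
  }
  invisible(x)
}

#' Per-participant ("average approach") ICER
#'
#' Supplementary approach: the numerator is the difference in *median*
#' per-participant costs and the denominator the difference in *mean*
#' per-participant effects, intervention minus comparator.
#'
#' @param costs,effects Numeric vectors of per-participant values.
#' @param arm Arm label per participant (two levels; comparator must sort or
#'   be supplied first in `arm_order`).
#' @param arm_order Optional length-2 character vector fixing which arm is
#'   the comparator.
#' @param effect_measure Label for the effect units.
#' @return A `cea_result` with approach `"per-participant"`.
#' @export
per_participant_icer <- function(costs, effects, arm, arm_order = NULL,
                                 effect_measure = "QALY") {
  arms <- arm_order %||% unique(arm)
  if (length(arms) != 2L) stop_config("exactly two arms required")
  dc <- stats::median(costs[arm == arms[2]]) - stats::median(costs[arm == arms[1]])
  de <- mean(effects[arm == arms[2]]) - mean(effects[arm == arms[1]])
  icer(dc, de, effect_measure = effect_measure, approach = "per-participant")
}
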