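#' Per-participant service-delivery costs by block
#'
#' Multiplies reported service-use quantities by unit costs and sums within
#' each service block (mental / physical). Every category present in the use
#' records must be priced; an unpriced category is an error naming it.
#'
#' @param records data.frame of service-use records with columns
#'   `participant_id`, `category`, `quantity` (and optionally `window`).
#' @param unit_costs data.frame with columns `category`, `block`, `unit_cost`.
#' @param participants Optional character vector of participant ids to report
#'   (participants with no records get zero cost).
#' @return data.frame `participant_id` x one column per block (`cost_mental`,
#'   `cost_physical`, ...), plus `cost_delivery_total`.
#' @export
service_cost <- function(records, unit_costs, participants = NULL) {
  unpriced <- setdiff(unique(records$category), unit_costs$category)
  if (length(unpriced)) {
    stop_config("unpriced service categories: ", paste(unpriced, collapse = ", "))
  }
  if (any(records$quantity < 0, na.rm = TRUE)) {
    stop_validation("service-use quantities must be >= 0")
  }
  i <- match(records$category, unit_costs$category)
  cost <- records$quantity * unit_costs$unit_cost[i]
  block <- unit_costs$block[i]
  participants <- participants %||% unique(records$participant_id)
  blocks <- unique(unit_costs$block)
  out <- data.frame(participant_id = participants, stringsAsFactors = FALSE)
  for (b in blocks) {
    agg <- tapply(cost[block == b], records$participant_id[block == b], sum)
    v <- as.vector(agg[match(participants, names(agg))])
    v[is.na(v)] <- 0
    out[[paste0("cost_", b)]] <- v
  }
  out$cost_delivery_total <- rowSums(out[paste0("cost_", blocks)], na.rm = TRUE)
  out
}

#' Per-user implementation cost by straight-line amortization
#'
#' Each ledger line item contributes `total_cost * share_arm /
#' (horizon_years * users_per_year[arm])` to the per-user cost of `arm`:
#' total costs are allocated by the configured arm shares, then spread evenly
#' over the horizon's projected users (no interest; annuitization rate 0).
#'
#' @param ledger An [implementation_ledger()].
#' @param arm Arm label; matched against `names(ledger$users_per_year)`, with
#'   `share_ST` applying to the first arm and `share_TP` to the second.
#' @return Per-user implementation cost in Int$2020.
#' @export
amortize_implementation <- function(ledger, arm) {
  stopifnot(inherits(ledger, "implementation_ledger"))
  arms <- names(ledger$users_per_year)
  a <- match(arm, arms)
  if (is.na(a)) stop_config("unknown arm: ", arm)
  share <- if (a == 1L) ledger$items$share_ST else ledger$items$share_TP
  users <- ledger$users_per_year[[a]]
  if (any(share > 0) && users <= 0) {
    stop_config("arm ", arm, " has allocated costs but zero projected users")
  }
  if (users <= 0) return(0)
  sum(ledger$items$total_cost * share) / (ledger$horizon_years * users)
}

#' Convert an amount to 2020 international dollars
#'
#' Applies the configured factor chain: multiply by the cumulative inflation
#' factor, divide by the purchasing-power-parity conversion factor. With all
#' factors 1 the amount is unchanged.
#'
#' @param amount Amount(s) in the source currency-year.
#' @param factors Named list/vector with `inflation` (multiplier to the
#'   target year) and `ppp` (local-currency-units per international dollar,
#'   a divisor). Both default to 1 when present but unnamed entries are a
#'   configuration error.
#' @return Amount(s) in Int$2020.
#' @export
convert_currency <- function(amount, factors = list(inflation = 1, ppp = 1)) {
  factors <- as.list(factors)
  for (f in c("inflation", "ppp")) {
    if (is.null(factors[[f]]) || !is.finite(factors[[f]])) {
      stop_config("missing currency conversion factor: ", f)
    }
  }
  if (factors$ppp <= 0) stop_config("ppp factor must be positive")
  amount * factors$inflation / factors$ppp
}

#' Arm-level cost profile (implementation and delivery blocks)
#'
#' Summarizes per-participant costs into the per-arm median and mean per
#' user by block — implementation, mental health service delivery, physical
#' health service delivery — plus arm program totals.
#'
#' @param delivery data.frame from [service_cost()] with columns
#'   `participant_id`, `cost_mental`, `cost_physical`.
#' @param roster data.frame with `participant_id` and `arm`.
#' @param ledger An [implementation_ledger()]; per-user implementation cost
#'   is constant within arm.
#' @return Object of class `cost_profile`: data.frame with one row per
#'   (arm, block) holding `median`, `mean`, `total`, plus an `arm_totals`
#'   attribute with overall per-arm totals.
#' @export
cost_profile <- function(delivery, roster, ledger) {
  arm <- roster$arm[match(delivery$participant_id, roster$participant_id)]
  if (anyNA(arm)) stop_config("delivery costs include participants not in roster")
  arms <- names(ledger$users_per_year)
  rows <- list()
  arm_totals <- stats::setNames(numeric(length(arms)), arms)
  for (a in arms) {
    sel <- arm == a
    impl <- amortize_implementation(ledger, a)
    blocks <- list(
      implementation = rep(impl, sum(sel)),
      mental_health_delivery = delivery$cost_mental[sel],
      physical_health_delivery = delivery$cost_physical[sel]
    )
    for (b in names(blocks)) {
      v <- blocks[[b]]
      rows[[paste(a, b)]] <- data.frame(
        arm = a, block = b, median = stats::median(v), mean = mean(v),
        total = sum(v), stringsAsFactors = FALSE)
    }
    arm_totals[[a]] <- sum(vapply(blocks, sum, numeric(1)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, arm_totals = arm_totals, class = c("cost_profile", "data.frame"))
}
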