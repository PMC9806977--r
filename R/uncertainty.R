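#' Nonparametric paired bootstrap of incremental cost and effect
#'
#' Resamples participants *within each arm* with replacement at the original
#' arm sizes, keeping each participant's (cost, effect) pair intact — the
#' resampling never separates a participant's costs from their effects. Each
#' replicate records the incremental cost, incremental effect (program-total
#' scale) and their ratio.
#'
#' Replicate r consumes the r-th block of random draws from a single seeded
#' stream, so enlarging B extends the replicate list without changing
#' earlier replicates.
#'
#' @param per_participant data.frame with columns `arm`, `cost`, `effect`
#'   (per-participant values; one row per participant).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param arm_order Optional length-2 vector fixing the comparator (first).
#' @return Object of class `bootstrap_set`: list with `replicates`
#'   (data.frame `delta_cost`, `delta_effect`, `icer`), `B`, `seed`,
#'   `arm_sizes`, `point` (the sample estimate) and `pairing_checksum`
#'   (a digest of the original (cost, effect) pairing, carried so tests can
#'   verify resampling itself never reshuffles pairs).
#' @export
boot_cea <- function(per_participant, B = 1000, seed = 1L, arm_order = NULL) {
  arms <- arm_order %||% unique(per_participant$arm)
  if (length(arms) != 2L) stop_config("exactly two arms required")
  i1 <- which(per_participant$arm == arms[1])
  i2 <- which(per_participant$arm == arms[2])
  if (!length(i1) || !length(i2)) stop_config("empty arm in bootstrap input")
  c1 <- per_participant$cost[i1]; e1 <- per_participant$effect[i1]
  c2 <- per_participant$cost[i2]; e2 <- per_participant$effect[i2]
  n1 <- length(i1); n2 <- length(i2)

  dc <- de <- numeric(B)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(B)) { # draw block r: n1 + n2 index draws
      s1 <- sample.int(n1, n1, replace = TRUE)
      s2 <- sample.int(n2, n2, replace = TRUE)
      dc[r] <- sum(c2[s2]) - sum(c1[s1])
      de[r] <- sum(e2[s2]) - sum(e1[s1])
    }
  })
  reps <- data.frame(delta_cost = dc, delta_effect = de,
                     icer = ifelse(de == 0, NA_real_, dc / de))
  structure(list(
    replicates = reps, B = B, seed = as.integer(seed),
    arm_sizes = stats::setNames(c(n1, n2), arms),
    point = list(delta_cost = sum(c2) - sum(c1),
                 delta_effect = sum(e2) - sum(e1)),
    pairing_checksum = fnv1a32(list(c1, e1, c2, e2))
  ), class = "bootstrap_set")
}

#' Percentile confidence interval for the ICER
#'
#' Takes the middle `level` share of the replicate ICER distribution: the
#' (1-level)/2 and (1+level)/2 quantiles of the replicate ICERs by linear
#' interpolation between order statistics (R quantile type 7).
#'
#' Ratio percentiles are only order-meaningful when every replicate lies on
#' the same side of zero incremental effect; if replicates straddle
#' `delta_effect = 0` this function refuses and directs the caller to the
#' acceptability curve, which is well defined in all quadrants.
#'
#' @param bootstrap_set A [boot_cea()] result.
#' @param level Coverage level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(bootstrap_set, level = 0.95) {
  stopifnot(inherits(bootstrap_set, "bootstrap_set"))
  de <- bootstrap_set$replicates$delta_effect
  if (any(de <= 0) && any(de >= 0) && !(all(de > 0) || all(de < 0))) {
    stop_validation(
      "replicates straddle delta_effect = 0; an ICER percentile interval is ",
      "not order-meaningful across quadrants - use ceac() instead")
  }
  q <- stats::quantile(bootstrap_set$replicates$icer,
                       probs = c((1 - level) / 2, (1 + level) / 2),
                       type = 7, names = FALSE)
  stats::setNames(q, c("lower", "upper"))
}

#' Fraction of bootstrap replicates cost-effective at given thresholds
#'
#' A replicate is cost-effective at willingness-to-pay `lambda` when its net
#' monetary benefit `lambda * delta_effect - delta_cost` is positive; for
#' replicates with positive incremental effect this is exactly `icer <
#' lambda`, but the net-benefit form stays well defined in every quadrant.
#'
#' @param bootstrap_set A [boot_cea()] result (QALY effect scale).
#' @param thresholds A [threshold_config()] or a numeric vector of lambdas
#'   (Int$ per effect unit, on the same scale as the replicates).
#' @return Named numeric vector of fractions in \[0,1\], one per threshold.
#' @export
threshold_fraction <- function(bootstrap_set, thresholds = threshold_config()) {
  stopifnot(inherits(bootstrap_set, "bootstrap_set"))
  lambdas <- if (inherits(thresholds, "threshold_config")) {
    thresholds$thresholds
  } else as.numeric(thresholds)
  reps <- bootstrap_set$replicates
  out <- vapply(lambdas,
                function(l) mean(l * reps$delta_effect - reps$delta_cost > 0),
                numeric(1))
  stats::setNames(out, format(lambdas, trim = TRUE, scientific = FALSE))
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective — the fraction of
#' bootstrap replicates with positive net monetary benefit — as a function
#' of the willingness-to-pay threshold.
#'
#' @param bootstrap_set A [boot_cea()] result.
#' @param lambda_grid Ascending numeric vector of thresholds.
#' @return data.frame with columns `lambda` and `p_cost_effective`.
#' @export
ceac <- function(bootstrap_set, lambda_grid = threshold_config()$lambda_grid) {
  p <- threshold_fraction(bootstrap_set, as.numeric(lambda_grid))
  data.frame(lambda = as.numeric(lambda_grid), p_cost_effective = unname(p))
}
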