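#' Default WHODAS-to-disability mapping coefficients (synthetic placeholder)
#'
#' The disability index is a linear map of eight WHODAS-12 items plus
#' sociodemographic covariates. The published population-specific coefficient
#' sets are not redistributed here; this constructor ships a clearly labelled
#' synthetic placeholder (equal item weights) and accepts any real coefficient
#' set with the same shape via its arguments or a YAML config.
#'
#' @param intercept Intercept of the linear predictor (unitless).
#' @param item_weights Named numeric vector of exactly 8 weights, names among
#'   `d1`..`d12` (WHODAS item ids).
#' @param covariate_weights Named numeric vector of weights on roster
#'   covariates (may be empty).
#' @param population_tag Label describing the provenance of the coefficients.
#' @return An object of class `mapping_coefficients`.
#' @export
mapping_coefficients <- function(intercept = 0.05,
                                 item_weights = stats::setNames(
                                   rep(0.02, 8),
                                   paste0("d", c(1, 2, 3, 5, 6, 8, 9, 11))
                                 ),
                                 covariate_weights = c(female = 0.01),
                                 population_tag = "synthetic-placeholder") {
  if (length(item_weights) != 8L) {
    stop_config("mapping requires exactly 8 WHODAS item weights, got ",
                length(item_weights))
  }
  ids <- names(item_weights)
  if (is.null(ids) || !all(ids %in% paste0("d", 1:12)) || anyDuplicated(ids)) {
    stop_config("item weight names must be 8 distinct ids among d1..d12")
  }
  structure(
    list(intercept = intercept,
         item_weights = item_weights,
         covariate_weights = covariate_weights %||% numeric(0),
         population_tag = population_tag),
    class = "mapping_coefficients"
  )
}

#' Default unit-cost table (synthetic)
#'
#' Categories follow the structure of a client service receipt inventory:
#' formal outpatient care, medication, traditional healers, transport, and
#' participant time (societal perspective), each assigned to the mental or
#' physical service-delivery block. Unit costs are Int$2020 per unit and are
#' synthetic defaults, replaceable via CSV/config.
#'
#' @return A data.frame with columns `category`, `block`, `unit_cost`.
#' @export
default_unit_costs <- function() {
  data.frame(
    category = c("mental_outpatient_visit", "psychotropic_medication",
                 "counseling_session", "mental_transport", "mental_time_hours",
                 "physical_outpatient_visit", "traditional_healer",
                 "physical_transport", "physical_time_hours"),
    block = c(rep("mental", 5), rep("physical", 4)),
    unit_cost = c(2.5, 0.10, 3.0, 0.80, 0.50,
                  3.0, 5.0, 0.80, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Default implementation-cost ledger (synthetic round-trip fixture)
#'
#' Line items amortized straight-line over a five-year horizon across
#' projected annual users per arm. The totals are reverse-engineered so that
#' the default per-user implementation costs come out at Int$329 (ST) and
#' Int$617 (T+P); the underlying administrative ledger is not public, so this
#' is a synthetic fixture exercising the amortization rule, not source data.
#'
#' @param horizon_years Amortization horizon in years (> 0).
#' @param users_per_year Named vector of projected annual users per arm.
#' @return An object of class `implementation_ledger`.
#' @export
default_ledger <- function(horizon_years = 5,
                           users_per_year = c(ST = 100, `T+P` = 100)) {
  items <- data.frame(
    activity = c("mhGAP training and supervision (shared)",
                 "HAP training and supervision (T+P only)"),
    total_cost = c(329000, 144000),
    share_ST = c(0.5, 0),
    share_TP = c(0.5, 1),
    stringsAsFactors = FALSE
  )
  implementation_ledger(items, horizon_years, users_per_year)
}

#' Construct an implementation-cost ledger
#'
#' @param items data.frame with columns `activity`, `total_cost` (Int$2020),
#'   `share_ST`, `share_TP` (allocation shares in \[0,1\]).
#' @param horizon_years Amortization horizon (> 0).
#' @param users_per_year Named vector `c(ST = , "T+P" = )` of projected users.
#' @return Object of class `implementation_ledger`.
#' @export
implementation_ledger <- function(items, horizon_years = 5,
                                  users_per_year = c(ST = 100, `T+P` = 100)) {
  need <- c("activity", "total_cost", "share_ST", "share_TP")
  if (!all(need %in% names(items))) {
    stop_config("ledger items need columns: ", paste(need, collapse = ", "))
  }
  assert_prob(items$share_ST, "ledger share_ST")
  assert_prob(items$share_TP, "ledger share_TP")
  if (horizon_years <= 0) stop_config("ledger horizon_years must be > 0")
  structure(list(items = items, horizon_years = horizon_years,
                 users_per_year = users_per_year),
            class = "implementation_ledger")
}

#' Willingness-to-pay threshold configuration
#'
#' @param gdp_per_capita GDP per capita in Int$ (default 4009, Nepal 2020).
#' @param multipliers Multipliers applied to GDP per capita (default 1 and 3,
#'   the historical highly-cost-effective / cost-effective thresholds).
#' @param lambda_grid Grid of thresholds (Int$/QALY) for the acceptability
#'   curve; default 0 to 20000 in steps of 100, with the GDP thresholds
#'   spliced in so the curve is evaluated exactly at them.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(gdp_per_capita = 4009,
                             multipliers = c(1, 3),
                             lambda_grid = NULL) {
  if (any(gdp_per_capita * multipliers <= 0)) {
    stop_config("thresholds must be positive")
  }
  lambda_grid <- lambda_grid %||%
    sort(unique(c(seq(0, 20000, by = 100), gdp_per_capita * multipliers)))
  if (is.unsorted(lambda_grid)) stop_config("lambda_grid must be ascending")
  structure(list(gdp_per_capita = gdp_per_capita,
                 multipliers = multipliers,
                 thresholds = gdp_per_capita * multipliers,
                 lambda_grid = lambda_grid),
            class = "threshold_config")
}

#' Synthetic trial configuration
#'
#' Describes the generative world for a two-arm depression-services trial:
#' arm-differential PHQ-9 and WHODAS-12 trajectories discretized from latent
#' normal severities, right-skewed (gamma) service-use quantities with an
#' optional severity-cost coupling, amortized implementation costs, and
#' missing-at-random monotone dropout whose probability depends on arm and
#' baseline depression severity.
#'
#' Defaults encode the trial conditions this pipeline was built around:
#' 60 participants per arm; dropout 15% (ST) and 23% (T+P); arm-mean PHQ-9
#' changes of about -5.5 and -9.6 points over 12 months; mean per-participant
#' QALYs near 0.78 and 0.83; implementation costs of Int$329/617 per user and
#' delivery costs of roughly Int$19/22 (mental) and Int$30/15 (physical).
#'
#' @param n_per_arm Participants per arm (>= 1).
#' @param arm_labels Two arm labels; the second is the intervention arm.
#' @param phq_baseline_mean Mean baseline PHQ-9 total (0-27 scale).
#' @param phq_time_effects 2x3 matrix (arm x time 0/3/12) of additive changes
#'   to the mean PHQ-9 total at each timepoint.
#' @param phq_person_sd,phq_item_sd Latent person-level and item-level SDs on
#'   the per-item (0-3) scale.
#' @param whodas_item_means 2x3 matrix (arm x time) of mean WHODAS item score
#'   (0-4 scale), shared by all 12 items.
#' @param whodas_person_sd,whodas_item_sd Latent SDs on the per-item scale.
#' @param mapping `mapping_coefficients` used both to generate ground truth
#'   and (by default) to analyse the synthetic data.
#' @param unit_costs Unit-cost table (see [default_unit_costs()]).
#' @param quantity_means 2-row data.frame-free named list: per-arm named
#'   vectors of mean total quantity per category over 12 months.
#' @param cost_shape Gamma shape for quantity draws (< 1 gives strong right
#'   skew, medians well below means).
#' @param cost_severity_corr Coupling c >= 0: quantities are multiplied by a
#'   mean-one lognormal exp(c*z - c^2/2) of the person's latent disability
#'   z-score, so sicker participants cost more without changing means.
#' @param ledger Implementation-cost ledger.
#' @param dropout_prob Named per-arm probabilities of loss to follow up.
#' @param dropout_phq_slope Log-odds increase in dropout per baseline PHQ
#'   point above the sample mean (MAR dependence on observed baseline).
#' @param dropout_early_fraction Fraction of dropouts lost before 3 months
#'   (the rest are lost between 3 and 12 months; dropout is monotone).
#' @param age_mean,age_sd,p_female Per-arm sociodemographic parameters.
#' @param seed Master RNG seed; all generator randomness derives from it.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 60,
                         arm_labels = c("ST", "T+P"),
                         phq_baseline_mean = 16,
                         phq_time_effects = rbind(c(0, -4.0, -5.54),
                                                  c(0, -7.0, -9.60)),
                         phq_person_sd = 0.30,
                         phq_item_sd = 1.40,
                         whodas_item_means = rbind(c(1.80, 0.947, 0.884),
                                                   c(1.80, 0.572, 0.572)),
                         whodas_person_sd = 0.35,
                         whodas_item_sd = 0.70,
                         mapping = mapping_coefficients(),
                         unit_costs = default_unit_costs(),
                         quantity_means = default_quantity_means(),
                         cost_shape = 0.8,
                         cost_severity_corr = 0.3,
                         ledger = default_ledger(),
                         dropout_prob = c(ST = 0.15, `T+P` = 0.23),
                         dropout_phq_slope = 0.08,
                         dropout_early_fraction = 0.5,
                         age_mean = c(43.5, 39.0),
                         age_sd = c(13.4, 14.1),
                         p_female = c(0.88, 0.82),
                         seed = 2025L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1) {
    stop_config("n_per_arm must be >= 1")
  }
  if (length(arm_labels) != 2L) stop_config("exactly two arm labels required")
  if (!all(dim(phq_time_effects) == c(2, 3)) ||
      !all(dim(whodas_item_means) == c(2, 3))) {
    stop_config("trajectory matrices must be 2 arms x 3 timepoints")
  }
  if (any(whodas_item_means < 0) || any(whodas_item_means > 4)) {
    stop_config("WHODAS item means must lie in [0, 4]")
  }
  if (any(c(phq_person_sd, phq_item_sd, whodas_person_sd, whodas_item_sd) <= 0)) {
    stop_config("latent SDs must be positive")
  }
  if (cost_shape <= 0) stop_config("cost_shape must be positive")
  if (cost_severity_corr < 0) stop_config("cost_severity_corr must be >= 0")
  assert_prob(dropout_prob, "dropout_prob")
  assert_prob(dropout_early_fraction, "dropout_early_fraction")
  names(dropout_prob) <- arm_labels
  for (arm in seq_along(quantity_means)) {
    q <- quantity_means[[arm]]
    if (any(q < 0)) stop_config("quantity means must be >= 0")
    missing_cat <- setdiff(names(q), unit_costs$category)
    if (length(missing_cat)) {
      stop_config("quantity categories not in unit-cost table: ",
                  paste(missing_cat, collapse = ", "))
    }
  }
  structure(
    list(n_per_arm = as.integer(n_per_arm), arm_labels = arm_labels,
         phq_baseline_mean = phq_baseline_mean,
         phq_time_effects = phq_time_effects,
         phq_person_sd = phq_person_sd, phq_item_sd = phq_item_sd,
         whodas_item_means = whodas_item_means,
         whodas_person_sd = whodas_person_sd, whodas_item_sd = whodas_item_sd,
         mapping = mapping, unit_costs = unit_costs,
         quantity_means = quantity_means,
         cost_shape = cost_shape, cost_severity_corr = cost_severity_corr,
         ledger = ledger, dropout_prob = dropout_prob,
         dropout_phq_slope = dropout_phq_slope,
         dropout_early_fraction = dropout_early_fraction,
         age_mean = age_mean, age_sd = age_sd, p_female = p_female,
         timepoints = c(0, 3, 12), seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' Default per-arm mean service-use quantities
#'
#' Mean total quantity per category over the 12-month follow up, tuned so the
#' implied mean delivery costs are Int$18.7 (ST) / 22.4 (T+P) for the mental
#' block and Int$90.5 (ST) / 15 (T+P) for the physical block (ST relies far
#' more on traditional healers and physical care), which together with the
#' default ledger puts the expected incremental program cost at Int$12,973
#' for 60 participants per arm.
#'
#' @return Named list of two named numeric vectors (one per arm).
#' @export
default_quantity_means <- function() {
  list(
    ST = c(mental_outpatient_visit = 3.0, psychotropic_medication = 60,
           counseling_session = 0, mental_transport = 3.0,
           mental_time_hours = 5.6,
           physical_outpatient_visit = 8.0, traditional_healer = 9.0,
           physical_transport = 12.0, physical_time_hours = 23.76),
    `T+P` = c(mental_outpatient_visit = 3.0, psychotropic_medication = 40,
              counseling_session = 1.0, mental_transport = 2.5,
              mental_time_hours = 11.8,
              physical_outpatient_visit = 2.6, traditional_healer = 0.7,
              physical_transport = 2.5, physical_time_hours = 3.4)
  )
}

#' Read a trial/pipeline configuration from YAML or JSON
#'
#' Scalar fields in the file override `trial_config()` defaults; absent
#' fields keep their defaults. Mapping coefficients may be supplied under a
#' `mapping:` key with `intercept`, `item_weights`, `covariate_weights`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `trial_config`.
#' @export
read_trial_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  scalar_fields <- c("n_per_arm", "phq_baseline_mean", "phq_person_sd",
                     "phq_item_sd", "whodas_person_sd", "whodas_item_sd",
                     "cost_shape", "cost_severity_corr", "dropout_phq_slope",
                     "dropout_early_fraction", "seed")
  for (f in scalar_fields) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$arm_labels)) args$arm_labels <- raw$arm_labels
  if (!is.null(raw$dropout_prob)) args$dropout_prob <- unlist(raw$dropout_prob)
  if (!is.null(raw$phq_time_effects)) {
    args$phq_time_effects <- do.call(rbind, raw$phq_time_effects)
  }
  if (!is.null(raw$whodas_item_means)) {
    args$whodas_item_means <- do.call(rbind, raw$whodas_item_means)
  }
  if (!is.null(raw$mapping)) {
    m <- raw$mapping
    args$mapping <- mapping_coefficients(
      intercept = m$intercept %||% 0.05,
      item_weights = unlist(m$item_weights),
      covariate_weights = unlist(m$covariate_weights) %||% numeric(0),
      population_tag = m$population_tag %||% "config"
    )
  }
  do.call(trial_config, args)
}
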