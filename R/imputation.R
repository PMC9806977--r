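#' Imputation specification
#'
#' @param n_imputations Number of completed datasets m (default 20).
#' @param donors Predictive-mean-matching donor pool size (default 5).
#' @param max_iterations Chained-equation sweeps before each draw (default 10).
#' @param seed RNG seed controlling the whole ensemble.
#' @param predictor_matrix Optional logical matrix (targets x predictors) by
#'   variable name; default: every analysis variable predicts every other.
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(n_imputations = 20, donors = 5,
                            max_iterations = 10, seed = 1L,
                            predictor_matrix = NULL) {
  if (n_imputations < 2) stop_config("n_imputations must be >= 2")
  if (donors < 1) stop_config("donor pool size must be >= 1")
  structure(list(n_imputations = as.integer(n_imputations),
                 donors = as.integer(donors),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 predictor_matrix = predictor_matrix),
            class = "imputation_spec")
}

# One Bayesian-draw PMM update of variable y given design matrix X.
# Returns imputed values for the missing rows: each is an observed y value
# donated by one of the `donors` observed rows whose predicted mean (under
# the posterior-drawn coefficients) is closest to the missing row's.
pmm_draw <- function(y, X, miss, donors) {
  obs <- !miss
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(1e-6, p)
  XtX_inv <- chol2inv(chol(XtX))
  beta_hat <- XtX_inv %*% crossprod(Xo, yo)
  resid <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- beta_hat +
    t(chol(XtX_inv)) %*% stats::rnorm(p) * sqrt(sigma2_star)
  yhat_obs <- as.numeric(Xo %*% beta_hat)
  yhat_mis <- as.numeric(X[miss, , drop = FALSE] %*% beta_star)
  k <- min(donors, length(yo))
  vapply(yhat_mis, function(mu) {
    d <- abs(yhat_obs - mu)
    pool <- order(d)[seq_len(k)]
    yo[pool[sample.int(k, 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing cells in the numeric analysis variables of `data` using
#' fully conditional specification: each incomplete variable is regressed on
#' all other analysis variables (plus fully observed covariates such as the
#' arm indicator), coefficients are drawn from their approximate posterior,
#' and each missing value borrows the observed value of one of the `donors`
#' closest predicted-mean neighbours. Because every imputed value is an
#' observed donor value, imputations automatically respect the support of
#' the data (PHQ totals stay in 0-27, statuses in \[0,1\]).
#'
#' @param data data.frame; numeric columns containing `NA` are imputed, all
#'   other columns (including character/factor columns such as `arm`, which
#'   must be fully observed) act as predictors. Columns named in `id_cols`
#'   are carried through untouched.
#' @param spec An [imputation_spec()].
#' @param id_cols Identifier columns excluded from the model (default
#'   `"participant_id"`).
#' @return Object of class `imputed_ensemble`: list with `datasets` (list of
#'   m completed data.frames), `spec`, `targets` (imputed variable names)
#'   and `diagnostics` (per-chain, per-iteration means of imputed values).
#' @export
impute_pmm <- function(data, spec = imputation_spec(), id_cols = "participant_id") {
  stopifnot(is.data.frame(data))
  model_cols <- setdiff(names(data), id_cols)
  numeric_cols <- model_cols[vapply(data[model_cols], is.numeric, logical(1))]
  other_cols <- setdiff(model_cols, numeric_cols)
  for (v in other_cols) {
    if (anyNA(data[[v]])) {
      stop_config("non-numeric variable with missing values and no declared handling: ", v)
    }
  }
  targets <- numeric_cols[vapply(data[numeric_cols], anyNA, logical(1))]
  for (v in targets) {
    n_obs <- sum(!is.na(data[[v]]))
    if (n_obs == 0) stop_config("variable is fully missing: ", v)
    if (n_obs < spec$donors) {
      stop_config("variable ", v, " has fewer observed values than the donor pool")
    }
  }
  miss_idx <- lapply(data[targets], function(x) which(is.na(x)))
  # deterministic sweep order: fewest missing first, ties by name
  targets <- targets[order(lengths(miss_idx[targets]), targets)]

  if (!length(targets)) {
    ens <- replicate(spec$n_imputations, data, simplify = FALSE)
    return(structure(list(datasets = ens, spec = spec, targets = character(0),
                          diagnostics = NULL), class = "imputed_ensemble"))
  }

  design <- function(df, exclude) {
    rhs <- setdiff(c(numeric_cols, other_cols), exclude)
    stats::model.matrix(~ ., data = df[rhs])
  }

  datasets <- vector("list", spec$n_imputations)
  diag_rows <- list()
  withr::with_seed(spec$seed, {
    for (m in seq_len(spec$n_imputations)) {
      cur <- data
      for (v in targets) { # random starting fill from the observed margin
        obs_vals <- cur[[v]][!is.na(cur[[v]])]
        cur[[v]][miss_idx[[v]]] <- sample(obs_vals, length(miss_idx[[v]]),
                                          replace = TRUE)
      }
      for (it in seq_len(spec$max_iterations)) {
        for (v in targets) {
          mi <- miss_idx[[v]]
          y <- cur[[v]]
          y[mi] <- NA # re-impute this variable given the others
          X <- design(cur, exclude = v)
          cur[[v]][mi] <- pmm_draw(ifelse(is.na(y), 0, y), X, is.na(y), spec$donors)
          diag_rows[[length(diag_rows) + 1L]] <- data.frame(
            chain = m, iteration = it, variable = v,
            mean_imputed = mean(cur[[v]][mi]), stringsAsFactors = FALSE)
        }
      }
      datasets[[m]] <- cur
    }
  })
  structure(list(datasets = datasets, spec = spec, targets = targets,
                 diagnostics = do.call(rbind, diag_rows)),
            class = "imputed_ensemble")
}

#' Pool cost-effectiveness inputs across an imputed ensemble
#'
#' For each completed dataset computes the per-arm program totals the
#' evaluation needs — total cost (delivery blocks plus amortized
#' implementation), total QALYs (trapezoid over statuses at months 0/3/12),
#' and total PHQ-9 change (12 months minus baseline) — then pools each
#' quantity as the mean across the m datasets, reporting within- and
#' between-imputation variances. Also returns ensemble-averaged
#' per-participant (cost, QALY, PHQ-change) values, the unit resampled by
#' the bootstrap.
#'
#' @param ensemble An [impute_pmm()] result whose datasets follow the
#'   [build_analysis_table()] schema.
#' @param ledger An [implementation_ledger()] supplying per-user
#'   implementation costs by arm.
#' @return Object of class `cea_inputs`: list with `pooled` (data.frame arm x
#'   quantity with pooled value, within/between variance), `per_participant`
#'   (data.frame participant_id, arm, cost, qaly, phq_change) and `m`.
#' @export
pool_cea_inputs <- function(ensemble, ledger) {
  stopifnot(inherits(ensemble, "imputed_ensemble"))
  m <- length(ensemble$datasets)
  per_dataset <- vector("list", m)
  pp_acc <- NULL
  for (k in seq_len(m)) {
    d <- ensemble$datasets[[k]]
    impl <- vapply(d$arm, function(a) amortize_implementation(ledger, a),
                   numeric(1))
    cost <- d$cost_mental_w1 + d$cost_mental_w2 +
      d$cost_physical_w1 + d$cost_physical_w2 + impl
    qaly <- (1.5 * d$status_0 + 6 * d$status_3 + 4.5 * d$status_12) / 12
    dphq <- d$phq_12 - d$phq_0
    pp <- data.frame(participant_id = d$participant_id, arm = d$arm,
                     cost = cost, qaly = qaly, phq_change = dphq,
                     stringsAsFactors = FALSE)
    if (is.null(pp_acc)) {
      pp_acc <- pp
    } else {
      pp_acc$cost <- pp_acc$cost + pp$cost
      pp_acc$qaly <- pp_acc$qaly + pp$qaly
      pp_acc$phq_change <- pp_acc$phq_change + pp$phq_change
    }
    rows <- list()
    for (a in unique(d$arm)) {
      sel <- d$arm == a
      n_a <- sum(sel)
      for (q in c("cost", "qaly", "phq_change")) {
        v <- pp[[q]][sel]
        rows[[paste(a, q)]] <- data.frame(
          arm = a, quantity = q, total = sum(v),
          var_total = n_a * stats::var(v), stringsAsFactors = FALSE)
      }
    }
    per_dataset[[k]] <- do.call(rbind, rows)
  }
  pp_acc$cost <- pp_acc$cost / m
  pp_acc$qaly <- pp_acc$qaly / m
  pp_acc$phq_change <- pp_acc$phq_change / m

  all <- do.call(rbind, per_dataset)
  key <- paste(all$arm, all$quantity)
  pooled <- do.call(rbind, lapply(unique(key), function(k2) {
    s <- all[key == k2, , drop = FALSE]
    data.frame(arm = s$arm[1], quantity = s$quantity[1],
               pooled = mean(s$total),
               within_var = mean(s$var_total),
               between_var = if (nrow(s) > 1) stats::var(s$total) else 0,
               stringsAsFactors = FALSE)
  }))
  pooled$total_var <- pooled$within_var + (1 + 1 / m) * pooled$between_var
  structure(list(pooled = pooled, per_participant = pp_acc, m = m),
            class = "cea_inputs")
}
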