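#' Strategy-level calibration targets
#'
#' The published strategy-level summaries the calibration matches: mean and
#' SD of total cost (USD) and of effectiveness (QALYs) per strategy.
#'
#' @param targets Data.frame with columns `strategy`, `mean_cost`, `sd_cost`,
#'   `mean_qaly`, `sd_qaly`.
#' @return The validated data.frame.
#' @export
calibration_targets <- function(targets) {
  need <- c("strategy", "mean_cost", "sd_cost", "mean_qaly", "sd_qaly")
  stopifnot(is.data.frame(targets), all(need %in% names(targets)))
  num <- as.matrix(targets[, need[-1]])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("calibration targets must be finite and non-negative", call. = FALSE)
  }
  targets[, need]
}

#' Base-case calibration targets
#'
#' The published strategy-level cost and effectiveness summaries from the
#' 10,000-run base-case simulation: DAPT cost 22,022 +/- 18,192 USD and
#' 11.4 +/- 2.1 QALYs; TAPT cost 49,290 +/- 26,588 USD and 10.4 +/- 3.1
#' QALYs.
#'
#' @return A [calibration_targets()] data.frame.
#' @export
base_case_targets <- function() {
  calibration_targets(data.frame(
    strategy = c("DAPT", "TAPT"),
    mean_cost = c(22022, 49290),
    sd_cost = c(18192, 26588),
    mean_qaly = c(11.4, 10.4),
    sd_qaly = c(2.1, 3.1)
  ))
}

#' Per-intervention expected QALYs for one strategy
#'
#' The conditional expectation of QALYs given each intervention:
#' `sum_o P(o | strategy, i) * qaly(i, o)`. These three values bound the
#' achievable strategy-level expected QALY for any intervention mix.
#'
#' @param probabilities Outcome probability array.
#' @param life_years Named life-years vector.
#' @param utilities Utility coefficient matrix.
#' @param strategy Strategy label.
#' @param qaly_override Optional per-outcome QALY override vector.
#' @return Named numeric vector over interventions.
#' @export
intervention_expected_qaly <- function(probabilities, life_years, utilities,
                                       strategy, qaly_override = NULL) {
  strategy <- match_strategy(strategy)
  vapply(interventions(), function(i) {
    q <- outcome_qaly(outcomes(), i, life_years, utilities, qaly_override)
    sum(probabilities[strategy, i, outcomes()] * q)
  }, numeric(1))
}

#' Calibrate the intervention mix to a target expected QALY
#'
#' Finds simplex weights over the three interventions whose analytic expected
#' QALY equals the target. One linear constraint on three weights is
#' underdetermined, so among all exact solutions the maximum-entropy (most
#' uniform) one is returned, computed by exponential tilting of the uniform
#' distribution: `w_i` proportional to `exp(lambda * q_i)` with `lambda`
#' solved so the weighted mean hits the target. Deterministic.
#'
#' @inheritParams intervention_expected_qaly
#' @param target_mean_qaly Target expected QALY (years). Must lie within the
#'   achievable envelope `[min_i q_i, max_i q_i]`.
#' @param tol Acceptable absolute residual for interior targets (default
#'   1e-11 years).
#' @return Named simplex weight vector over interventions.
#' @export
calibrate_mix <- function(probabilities, life_years, utilities,
                          target_mean_qaly, strategy,
                          qaly_override = NULL, tol = 1e-11) {
  q <- intervention_expected_qaly(probabilities, life_years, utilities,
                                  strategy, qaly_override)
  lo <- min(q)
  hi <- max(q)
  if (target_mean_qaly < lo - 1e-9 || target_mean_qaly > hi + 1e-9) {
    stop(sprintf(
      "target QALY %.6f outside the achievable envelope [%.6f, %.6f] for %s",
      target_mean_qaly, lo, hi, strategy), call. = FALSE)
  }
  w <- stats::setNames(numeric(3L), interventions())
  if (hi - lo < 1e-12) {
    # all interventions equivalent: uniform is the max-entropy solution
    w[] <- 1 / 3
    return(w)
  }
  if (target_mean_qaly >= hi - 1e-12) {
    at <- abs(q - hi) < 1e-12
    w[at] <- 1 / sum(at)
    return(w)
  }
  if (target_mean_qaly <= lo + 1e-12) {
    at <- abs(q - lo) < 1e-12
    w[at] <- 1 / sum(at)
    return(w)
  }
  qc <- q - mean(q)  # center for numerical stability of exp()
  tilted_mean <- function(lambda) {
    z <- exp(lambda * qc - max(lambda * qc))
    sum(z * q) / sum(z)
  }
  f <- function(lambda) tilted_mean(lambda) - target_mean_qaly
  bound <- 1
  while (sign(f(-bound)) == sign(f(bound)) && bound < 2^40) bound <- bound * 2
  root <- stats::uniroot(f, c(-bound, bound), tol = .Machine$double.eps^0.75)
  z <- exp(root$root * qc - max(root$root * qc))
  w[] <- z / sum(z)
  resid <- abs(sum(w * q) - target_mean_qaly)
  if (resid > tol) {
    stop(sprintf("mix calibration did not converge: residual %.3g", resid),
         call. = FALSE)
  }
  w
}

#' Default pathway cost severity multipliers
#'
#' Ordinal structure for pathway cost means before moment matching: CABG is
#' the most expensive intervention, PCI intermediate, medical management
#' least; complication pathways cost more than an uneventful course. The
#' absolute scale cancels in the moment-matching constraint — only the
#' ratios matter — and the ratios are kept modest so that the implied
#' between-pathway spread stays below typical strategy-level cost SDs
#' (otherwise no within-pathway variance could reconcile them; see
#' [calibrate_costs()]).
#'
#' @return A list with named numeric vectors `intervention` and `outcome`.
#' @export
default_cost_severity <- function() {
  list(
    intervention = c(PCI = 1.5, CABG = 2.5, MEDICAL = 1),
    outcome = c(NO_EVENT = 1, BLEEDING = 1.5, VASCULAR = 1.8, DEATH = 1.3)
  )
}

#' Calibrate pathway cost distributions to a strategy-level cost summary
#'
#' Assigns each of the 12 pathways a gamma (mean, SD) pair so that the
#' analytic mixture mean equals `target_mean_cost` exactly and the analytic
#' mixture SD equals `target_sd_cost` exactly (law of total variance:
#' between-pathway variance is fixed by the means; the remaining
#' within-pathway variance is spread over pathways at a common coefficient of
#' variation). Pathway means are the severity multipliers rescaled to the
#' target mean.
#'
#' @param path_probs 12-row data.frame with columns `intervention`, `outcome`,
#'   `path_probability` (e.g. from [enumerate_pathways()] or internal pathway
#'   enumeration), probabilities summing to 1.
#' @param target_mean_cost,target_sd_cost Strategy-level cost mean and SD
#'   (USD), mean > 0.
#' @param strategy Strategy label the entries are for.
#' @param severity Severity multipliers, as [default_cost_severity()].
#' @return A 12-row [cost_model()]-style data.frame for the strategy.
#' @export
calibrate_costs <- function(path_probs, target_mean_cost, target_sd_cost,
                            strategy, severity = default_cost_severity()) {
  strategy <- match_strategy(strategy)
  stopifnot(is.data.frame(path_probs),
            all(c("intervention", "outcome", "path_probability") %in%
                  names(path_probs)))
  if (target_mean_cost <= 0 || target_sd_cost < 0) {
    stop("cost targets must have mean > 0 and sd >= 0", call. = FALSE)
  }
  pw <- path_probs
  pi_ <- pw$path_probability
  if (abs(sum(pi_) - 1) > 1e-9) {
    stop("pathway probabilities must sum to 1", call. = FALSE)
  }
  m <- severity$intervention[pw$intervention] * severity$outcome[pw$outcome]
  mu <- m * target_mean_cost / sum(pi_ * m)
  v_between <- sum(pi_ * mu^2) - target_mean_cost^2
  v_target <- target_sd_cost^2
  if (v_target < v_between - 1e-9) {
    stop(sprintf(
      "target SD %.1f infeasible: between-pathway spread alone gives SD %.1f; feasible SDs are [%.1f, Inf)",
      target_sd_cost, sqrt(v_between), sqrt(v_between)), call. = FALSE)
  }
  k2 <- max(v_target - v_between, 0) / sum(pi_ * mu^2)
  sds <- sqrt(k2) * mu
  cost_rows <- data.frame(
    strategy = strategy, intervention = pw$intervention,
    outcome = pw$outcome,
    family = ifelse(sds > 0, "GAMMA", "FIXED"),
    mean = mu, sd = sds
  )
  rownames(cost_rows) <- NULL
  cost_rows
}

#' Gamma shape and scale from mean and SD
#'
#' Moment parameterization used for all pathway cost distributions:
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean,sd Positive mean and SD.
#' @return Named vector with `shape` and `scale`.
#' @export
gamma_shape_scale <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

# Analytic mixture cost moments implied by a calibrated parameter set.
analytic_cost_moments <- function(params, strategy) {
  pw <- enumerate_pathways(params, strategy)
  costs <- params$costs[params$costs$strategy == strategy, ]
  key <- paste(costs$intervention, costs$outcome)
  sds <- costs$sd[match(paste(pw$intervention, pw$outcome), key)]
  m <- sum(pw$path_probability * pw$cost_mean)
  v <- sum(pw$path_probability * (sds^2 + pw$cost_mean^2)) - m^2
  c(mean = m, sd = sqrt(v))
}

# Analytic QALY moments (categorical over pathways, QALY deterministic
# within a pathway).
analytic_qaly_moments <- function(params, strategy) {
  pw <- enumerate_pathways(params, strategy)
  m <- sum(pw$path_probability * pw$qaly)
  v <- sum(pw$path_probability * pw$qaly^2) - m^2
  c(mean = m, sd = sqrt(v))
}

#' Calibrate the full model to strategy-level targets
#'
#' For each strategy: calibrates the intervention mix to the target mean QALY
#' with [calibrate_mix()], then the pathway cost distributions to the target
#' cost mean and SD with [calibrate_costs()]. The QALY SD is not a free
#' parameter — once the mix matches the mean QALY, the QALY spread is fully
#' determined by the outcome distributions — so it is reported in the
#' residuals but not matched.
#'
#' @param params A `model_parameters` object (mix/costs may be unset).
#' @param targets A [calibration_targets()] data.frame for both strategies.
#' @param severity Cost severity multipliers.
#' @return An object of class `calibration_result` with fields `params` (the
#'   completed parameter set), `mix`, `costs`, `residuals` (per strategy and
#'   moment: target, achieved, absolute error) and `converged`.
#' @export
calibrate_parameters <- function(params, targets = base_case_targets(),
                                 severity = default_cost_severity()) {
  targets <- calibration_targets(targets)
  mix <- matrix(NA_real_, 2L, 3L,
                dimnames = list(strategies(), interventions()))
  cost_rows <- list()
  for (s in strategies()) {
    tg <- targets[targets$strategy == s, ]
    if (nrow(tg) != 1L) {
      stop(sprintf("calibration targets missing for strategy %s", s),
           call. = FALSE)
    }
    mix[s, ] <- calibrate_mix(params$probabilities, params$life_years,
                              params$utilities, tg$mean_qaly, s,
                              params$qaly_override)
  }
  tmp <- params
  tmp$mix <- intervention_mix(mix)
  for (s in strategies()) {
    tg <- targets[targets$strategy == s, ]
    pw <- pathway_probabilities(tmp, s)
    cost_rows[[s]] <- calibrate_costs(pw, tg$mean_cost, tg$sd_cost, s,
                                      severity)
  }
  costs <- cost_model(do.call(rbind, cost_rows))
  out <- tmp
  out$costs <- costs
  validate_parameters(out)

  residuals <- do.call(rbind, lapply(strategies(), function(s) {
    tg <- targets[targets$strategy == s, ]
    cm <- analytic_cost_moments(out, s)
    qm <- analytic_qaly_moments(out, s)
    data.frame(
      strategy = s,
      moment = c("mean_cost", "sd_cost", "mean_qaly", "sd_qaly"),
      target = c(tg$mean_cost, tg$sd_cost, tg$mean_qaly, tg$sd_qaly),
      achieved = c(cm[["mean"]], cm[["sd"]], qm[["mean"]], qm[["sd"]]),
      calibrated = c(TRUE, TRUE, TRUE, FALSE)
    )
  }))
  residuals$abs_error <- abs(residuals$achieved - residuals$target)
  converged <- all(
    residuals$abs_error[residuals$moment == "mean_cost"] < 1e-6,
    residuals$abs_error[residuals$moment == "mean_qaly"] < 1e-9,
    residuals$abs_error[residuals$moment == "sd_cost"] /
      residuals$target[residuals$moment == "sd_cost"] < 0.05
  )
  structure(
    list(params = out, mix = out$mix, costs = costs,
         residuals = residuals, converged = converged),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> converged:", x$converged, "\n")
  cat("  mix:\n")
  print(round(x$mix, 4))
  print(x$residuals, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Verify a calibrated model by simulation
#'
#' Runs the Monte Carlo simulator for each strategy and z-scores each sample
#' moment against its calibration target. Standard errors use the sample
#' moments (the SE of the SD uses the fourth central moment, since costs are
#' skewed). The report passes when every calibrated moment (cost mean, cost
#' SD, QALY mean) has `|z| < 3`; the QALY SD is reported but is not a
#' calibrated quantity.
#'
#' @param params A calibrated (fully specified) `model_parameters` object.
#' @param targets Calibration targets.
#' @param n Trials per strategy.
#' @param seed Master seed.
#' @return An object of class `calibration_verification` with a per-moment
#'   data.frame `report` and a logical `passed`.
#' @export
verify_calibration <- function(params, targets = base_case_targets(),
                               n = params$n_trials, seed = params$seed) {
  require_fully_specified(params)
  targets <- calibration_targets(targets)
  ss <- derive_subseeds(seed, 2L)
  rows <- list()
  for (k in seq_along(strategies())) {
    s <- strategies()[k]
    tg <- targets[targets$strategy == s, ]
    sim <- simulate_cohort(params, s, n, ss[k])
    sm <- sim$summary
    rec <- sim$records
    se_of_sd <- function(x, s_) {
      if (length(x) < 2L || s_ == 0) return(NA_real_)
      m4 <- mean((x - mean(x))^4)
      sqrt(max(m4 - s_^4, 0) / (4 * s_^2 * length(x)))
    }
    moments <- data.frame(
      strategy = s,
      moment = c("mean_cost", "sd_cost", "mean_qaly", "sd_qaly"),
      target = c(tg$mean_cost, tg$sd_cost, tg$mean_qaly, tg$sd_qaly),
      simulated = c(sm$mean_cost, sm$sd_cost, sm$mean_qaly, sm$sd_qaly),
      se = c(sm$se_cost, se_of_sd(rec$cost, sm$sd_cost),
             sm$se_qaly, se_of_sd(rec$qaly, sm$sd_qaly)),
      calibrated = c(TRUE, TRUE, TRUE, FALSE)
    )
    moments$z <- (moments$simulated - moments$target) / moments$se
    rows[[s]] <- moments
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  passed <- all(abs(report$z[report$calibrated]) < 3, na.rm = TRUE)
  structure(list(report = report, passed = passed, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "calibration_verification")
}

#' @export
print.calibration_verification <- function(x, ...) {
  cat(sprintf("<calibration_verification> n = %d, passed: %s\n",
              x$n, x$passed))
  print(x$report, row.names = FALSE, digits = 5)
  invisible(x)
}
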