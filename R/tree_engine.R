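#' Quality-adjusted life-years for one outcome under one intervention
#'
#' QALYs are life-years extended for the outcome multiplied by the EQ-5D
#' utility coefficient of the intervention's utility class (PCI and CABG share
#' the procedural coefficients; medical management has its own). With
#' `qaly_override` set, the override value for the outcome is returned
#' verbatim, ignoring the intervention.
#'
#' @param outcome Outcome label (vectorized).
#' @param intervention Intervention label (vectorized, recycled).
#' @param life_years Named life-years vector over outcomes.
#' @param utilities `[utility_class, outcome]` coefficient matrix.
#' @param qaly_override Optional named per-outcome QALY vector.
#' @return QALYs in years.
#' @export
#' @examples
#' outcome_qaly("VASCULAR", "PCI", base_case_life_years(), base_case_utilities())
#' # 5.2 * 0.76 = 3.952
outcome_qaly <- function(outcome, intervention, life_years, utilities,
                         qaly_override = NULL) {
  stopifnot(all(outcome %in% outcomes()),
            all(intervention %in% interventions()))
  if (!is.null(qaly_override)) {
    return(unname(qaly_override[outcome]))
  }
  cl <- utility_class(intervention)
  unname(life_years[outcome] * utilities[cbind(cl, outcome)])
}

# QALY payoff matrix [intervention, outcome] for a parameter set.
qaly_matrix <- function(params) {
  q <- matrix(NA_real_, 3L, 4L,
              dimnames = list(interventions(), outcomes()))
  for (i in interventions()) {
    q[i, ] <- outcome_qaly(outcomes(), i, params$life_years,
                           params$utilities, params$qaly_override)
  }
  q
}

# Pathway probabilities for one strategy without requiring costs: a 12-row
# data.frame used by calibration before the cost model exists.
pathway_probabilities <- function(params, strategy) {
  strategy <- match_strategy(strategy)
  if (is.null(params$mix)) {
    stop("parameter block(s) missing: mix", call. = FALSE)
  }
  grid <- expand.grid(outcome = outcomes(), intervention = interventions(),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("intervention", "outcome")]
  grid$path_probability <- params$mix[strategy, grid$intervention] *
    params$probabilities[cbind(strategy, grid$intervention, grid$outcome)]
  grid
}

#' Enumerate all pathways of the decision tree for one strategy
#'
#' The tree has 12 terminal pathways per strategy (3 interventions x 4
#' outcomes). Each carries its joint probability
#' `mix(strategy, intervention) * P(outcome | strategy, intervention)`, its
#' QALY payoff and its mean cost.
#'
#' @param params A fully specified `model_parameters` object (mix and costs
#'   present).
#' @param strategy `"DAPT"` or `"TAPT"`.
#' @return A 12-row data.frame: `strategy`, `intervention`, `outcome`,
#'   `path_probability`, `qaly`, `cost_mean`. Probabilities sum to 1.
#' @export
enumerate_pathways <- function(params, strategy) {
  strategy <- match_strategy(strategy)
  require_fully_specified(params)
  pw <- pathway_probabilities(params, strategy)
  q <- qaly_matrix(params)
  pw$qaly <- q[cbind(pw$intervention, pw$outcome)]
  costs <- params$costs[params$costs$strategy == strategy, ]
  key <- paste(costs$intervention, costs$outcome)
  pw$cost_mean <- costs$mean[match(paste(pw$intervention, pw$outcome), key)]
  cbind(strategy = strategy, pw)
}

#' Analytic expected values for one strategy
#'
#' Exact rollback of the decision tree: probability-weighted sums of cost
#' means, QALYs and raw life-years over all 12 pathways. This is the
#' closed-form oracle that the Monte Carlo simulator must converge to.
#'
#' @inheritParams enumerate_pathways
#' @return An object of class `expected_values` with fields `strategy`,
#'   `expected_cost`, `expected_qaly`, `expected_life_years`.
#' @export
expected_values <- function(params, strategy) {
  pw <- enumerate_pathways(params, strategy)
  ly <- params$life_years[pw$outcome]
  structure(
    list(strategy = strategy,
         expected_cost = sum(pw$path_probability * pw$cost_mean),
         expected_qaly = sum(pw$path_probability * pw$qaly),
         expected_life_years = sum(pw$path_probability * ly)),
    class = "expected_values"
  )
}

#' @export
print.expected_values <- function(x, ...) {
  cat(sprintf("<expected_values> %s: cost $%.1f, QALY %.3f, life-years %.3f\n",
              x$strategy, x$expected_cost, x$expected_qaly,
              x$expected_life_years))
  invisible(x)
}

#' Cost-effectiveness ratio
#'
#' Expected (or mean) cost divided by expected (or mean) QALYs, in USD per
#' QALY. Undefined for non-positive effectiveness.
#'
#' @param ev An `expected_values` or `cohort_summary` object.
#' @return USD per QALY.
#' @export
cost_effectiveness_ratio <- function(ev) {
  ce <- cost_qaly_of(ev)
  if (!is.finite(ce$qaly) || ce$qaly <= 0) {
    stop("cost-effectiveness ratio undefined: expected QALY must be > 0",
         call. = FALSE)
  }
  ce$cost / ce$qaly
}

cost_qaly_of <- function(x) {
  if (inherits(x, "expected_values")) {
    list(cost = x$expected_cost, qaly = x$expected_qaly)
  } else if (inherits(x, "cohort_summary")) {
    list(cost = x$mean_cost, qaly = x$mean_qaly)
  } else {
    stop("expected an expected_values or cohort_summary object", call. = FALSE)
  }
}

#' Compare the two strategies on cost-effectiveness
#'
#' Computes both cost-effectiveness ratios, their ratio (TAPT CER over DAPT
#' CER, so values above 1 favor DAPT), incremental cost and QALYs
#' (TAPT - DAPT) and, when the incremental QALY is non-zero, the incremental
#' cost-effectiveness ratio. The preferred strategy is the one with the lower
#' CER.
#'
#' @param ev_dapt,ev_tapt `expected_values` or `cohort_summary` objects for
#'   DAPT and TAPT respectively.
#' @return An object of class `strategy_comparison`.
#' @export
compare_strategies <- function(ev_dapt, ev_tapt) {
  d <- cost_qaly_of(ev_dapt)
  t <- cost_qaly_of(ev_tapt)
  cer_dapt <- cost_effectiveness_ratio(ev_dapt)
  cer_tapt <- cost_effectiveness_ratio(ev_tapt)
  inc_cost <- t$cost - d$cost
  inc_qaly <- t$qaly - d$qaly
  icer <- if (abs(inc_qaly) < 1e-12) NA_real_ else inc_cost / inc_qaly
  structure(
    list(cer_dapt = cer_dapt, cer_tapt = cer_tapt,
         cer_ratio = cer_tapt / cer_dapt,
         incremental_cost = inc_cost, incremental_qaly = inc_qaly,
         icer = icer,
         preferred = if (cer_dapt <= cer_tapt) "DAPT" else "TAPT"),
    class = "strategy_comparison"
  )
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  cat(sprintf("  CER DAPT: $%.1f/QALY   CER TAPT: $%.1f/QALY\n",
              x$cer_dapt, x$cer_tapt))
  cat(sprintf("  CER ratio (TAPT/DAPT): %.2f   preferred: %s\n",
              x$cer_ratio, x$preferred))
  cat(sprintf("  incremental cost: $%.1f   incremental QALY: %.3f   ICER: %s\n",
              x$incremental_cost, x$incremental_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("$%.1f/QALY", x$icer)))
  invisible(x)
}
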