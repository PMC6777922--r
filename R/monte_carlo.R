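#' Simulate a patient-level cohort for one strategy
#'
#' Each trial independently draws an intervention from the strategy's mix, a
#' 30-day outcome from the intervention's outcome distribution, and a cost
#' from the pathway's cost distribution (gamma parameterized by
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`; FIXED entries are point
#' masses). The QALY payoff is deterministic given the pathway. Identical
#' `(params, n, seed)` give bit-identical output.
#'
#' @param params A fully specified `model_parameters` object.
#' @param strategy `"DAPT"` or `"TAPT"`.
#' @param n Number of trials (patients), `>= 1`.
#' @param seed Integer RNG seed for this cohort.
#' @return A list with `records` (data.frame: `trial`, `strategy`,
#'   `intervention`, `outcome`, `cost`, `qaly`) and `summary`
#'   (a [cohort_summary][summarize_trials]).
#' @export
simulate_cohort <- function(params, strategy, n, seed) {
  strategy <- match_strategy(strategy)
  require_fully_specified(params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)

  set.seed(as.integer(seed))
  iv <- sample(interventions(), n, replace = TRUE,
               prob = params$mix[strategy, interventions()])

  outcome <- character(n)
  # grouped draws in fixed intervention order keep the RNG stream deterministic
  for (i in interventions()) {
    idx <- which(iv == i)
    if (length(idx)) {
      outcome[idx] <- sample(outcomes(), length(idx), replace = TRUE,
                             prob = params$probabilities[strategy, i, ])
    }
  }

  cost <- numeric(n)
  costs <- params$costs[params$costs$strategy == strategy, ]
  for (i in interventions()) {
    for (o in outcomes()) {
      idx <- which(iv == i & outcome == o)
      if (!length(idx)) next
      e <- costs[costs$intervention == i & costs$outcome == o, ]
      if (e$family == "FIXED" || e$sd == 0) {
        cost[idx] <- e$mean
      } else {
        shape <- (e$mean / e$sd)^2
        scale <- e$sd^2 / e$mean
        cost[idx] <- stats::rgamma(length(idx), shape = shape, scale = scale)
      }
    }
  }

  q <- qaly_matrix(params)
  records <- data.frame(
    trial = seq_len(n), strategy = strategy, intervention = iv,
    outcome = outcome, cost = cost, qaly = q[cbind(iv, outcome)]
  )
  list(records = records, summary = summarize_trials(records))
}

#' Summarize trial records into strategy-level moments
#'
#' Sample mean and SD (denominator `n - 1`) of cost and QALYs, standard
#' errors (`sd / sqrt(n)`), and the cost-effectiveness ratio computed as the
#' ratio of means. With zero mean QALYs the CER is reported as `NA` and
#' flagged undefined.
#'
#' @param records Non-empty data.frame of trial records for one strategy.
#' @return An object of class `cohort_summary`.
#' @export
summarize_trials <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  strat <- unique(records$strategy)
  if (length(strat) != 1L) {
    stop("records must come from a single strategy", call. = FALSE)
  }
  n <- nrow(records)
  mean_cost <- mean(records$cost)
  mean_qaly <- mean(records$qaly)
  sd_cost <- if (n > 1L) stats::sd(records$cost) else 0
  sd_qaly <- if (n > 1L) stats::sd(records$qaly) else 0
  cer_defined <- mean_qaly > 0
  structure(
    list(strategy = strat, n = n,
         mean_cost = mean_cost, sd_cost = sd_cost,
         mean_qaly = mean_qaly, sd_qaly = sd_qaly,
         se_cost = sd_cost / sqrt(n), se_qaly = sd_qaly / sqrt(n),
         cer = if (cer_defined) mean_cost / mean_qaly else NA_real_,
         cer_defined = cer_defined),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n = %d)\n", x$strategy, x$n))
  cat(sprintf("  cost: %s +/- %s   QALY: %.2f +/- %.2f   CER: %s\n",
              formatC(round(x$mean_cost), format = "d", big.mark = ","),
              formatC(round(x$sd_cost), format = "d", big.mark = ","),
              x$mean_qaly, x$sd_qaly,
              if (x$cer_defined) sprintf("$%.1f/QALY", x$cer) else "undefined"))
  invisible(x)
}

# Deterministic per-arm sub-seeds from the master seed: one draw of k seeds
# from the master stream, so arms are decorrelated and reproducible.
derive_subseeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, k)
}

#' Run the full two-strategy Monte Carlo comparison
#'
#' Simulates both strategies with decorrelated sub-seeds derived
#' deterministically from the master seed, summarizes each cohort, compares
#' cost-effectiveness ratios and performs a Welch two-sample comparison of
#' mean QALYs (difference, standard error, 95% interval, p-value).
#'
#' @param params A fully specified `model_parameters` object.
#' @param n Trials per strategy; defaults to `params$n_trials`.
#' @param seed Master seed; defaults to `params$seed`.
#' @return An object of class `comparison_report` with per-strategy summaries
#'   and records, the [compare_strategies()] comparison, and the QALY test.
#' @export
run_comparison <- function(params, n = params$n_trials, seed = params$seed) {
  require_fully_specified(params)
  ss <- derive_subseeds(seed, 2L)
  sim_d <- simulate_cohort(params, "DAPT", n, ss[1])
  sim_t <- simulate_cohort(params, "TAPT", n, ss[2])
  sd_ <- sim_d$summary
  st_ <- sim_t$summary
  comparison <- compare_strategies(sd_, st_)

  diff <- sd_$mean_qaly - st_$mean_qaly
  se <- sqrt(sd_$se_qaly^2 + st_$se_qaly^2)
  df <- if (se > 0) {
    (sd_$se_qaly^2 + st_$se_qaly^2)^2 /
      (sd_$se_qaly^4 / (sd_$n - 1) + st_$se_qaly^4 / (st_$n - 1))
  } else {
    NA_real_
  }
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else NA_real_
  qaly_test <- list(
    difference = diff, se = se, df = df,
    ci95 = if (is.finite(tcrit)) diff + c(-1, 1) * tcrit * se else c(NA, NA),
    t = if (se > 0) diff / se else NA_real_,
    p = if (se > 0 && is.finite(df)) {
      2 * stats::pt(-abs(diff / se), df)
    } else {
      NA_real_
    }
  )

  structure(
    list(summary_dapt = sd_, summary_tapt = st_,
         records_dapt = sim_d$records, records_tapt = sim_t$records,
         comparison = comparison, qaly_test = qaly_test,
         n = as.integer(n), seed = as.integer(seed), subseeds = ss),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> n = %d per strategy, seed = %d\n",
              x$n, x$seed))
  writeLines(paste0("  ", render_summary_table(x$summary_dapt, x$summary_tapt)))
  ci <- x$qaly_test$ci95
  cat(sprintf("  QALY difference (DAPT - TAPT): %.3f [%.3f, %.3f], p = %.3g\n",
              x$qaly_test$difference, ci[1], ci[2], x$qaly_test$p))
  invisible(x)
}

#' Cost-effectiveness plane data
#'
#' Per-trial (QALY, cost) pairs for both strategies — the scatter behind a
#' cost-effectiveness plane plot.
#'
#' @param report A `comparison_report` from [run_comparison()].
#' @return A data.frame: `strategy`, `trial`, `qaly`, `cost`.
#' @export
ce_plane_data <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  rec <- rbind(report$records_dapt, report$records_tapt)
  rec[, c("strategy", "trial", "qaly", "cost")]
}
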