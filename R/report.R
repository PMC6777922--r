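#' Render the strategy comparison as a plain-text table
#'
#' Cost rows show comma-grouped whole dollars as mean +/- SD, effectiveness
#' rows one decimal, cost/QALY ratios one decimal and their ratio two
#' decimals. Pure function of the two summaries.
#'
#' @param summary_dapt,summary_tapt [cohort_summary][summarize_trials]
#'   objects, one per strategy.
#' @return Character vector of table lines.
#' @export
render_summary_table <- function(summary_dapt, summary_tapt) {
  stopifnot(inherits(summary_dapt, "cohort_summary"),
            inherits(summary_tapt, "cohort_summary"),
            summary_dapt$strategy == "DAPT",
            summary_tapt$strategy == "TAPT")
  usd <- function(x) formatC(round(x), format = "d", big.mark = ",")
  pm <- function(m, s, f) paste0(f(m), " +/- ", f(s))
  cer_fmt <- function(s) {
    if (s$cer_defined) formatC(s$cer, format = "f", digits = 1) else "undefined"
  }
  ratio <- if (summary_dapt$cer_defined && summary_tapt$cer_defined) {
    formatC(summary_tapt$cer / summary_dapt$cer, format = "f", digits = 2)
  } else {
    "undefined"
  }
  labels <- c("", "Cost", "Effectiveness (QALY)", "Cost/QALY",
              "CER ratio (TAPT/DAPT)")
  col_d <- c("DAPT",
             pm(summary_dapt$mean_cost, summary_dapt$sd_cost, usd),
             pm(summary_dapt$mean_qaly, summary_dapt$sd_qaly,
                function(x) formatC(x, format = "f", digits = 1)),
             cer_fmt(summary_dapt),
             ratio)
  col_t <- c("TAPT",
             pm(summary_tapt$mean_cost, summary_tapt$sd_cost, usd),
             pm(summary_tapt$mean_qaly, summary_tapt$sd_qaly,
                function(x) formatC(x, format = "f", digits = 1)),
             cer_fmt(summary_tapt),
             "")
  w0 <- max(nchar(labels))
  w1 <- max(nchar(col_d))
  sub("\\s+$", "", sprintf("%-*s  %-*s  %s", w0, labels, w1, col_d, col_t))
}

summary_as_list <- function(s) {
  s[c("strategy", "n", "mean_cost", "sd_cost", "mean_qaly", "sd_qaly",
      "se_cost", "se_qaly", "cer", "cer_defined")]
}

#' Serialize a comparison report to a JSON-ready list
#'
#' @param report A `comparison_report`.
#' @return A nested list mirroring the report's summaries and comparison.
#' @export
report_as_list <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  list(
    n = report$n, seed = report$seed,
    dapt = summary_as_list(report$summary_dapt),
    tapt = summary_as_list(report$summary_tapt),
    comparison = unclass(report$comparison),
    qaly_test = report$qaly_test
  )
}
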