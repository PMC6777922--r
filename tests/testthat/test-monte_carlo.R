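test_that("the simulator is bit-reproducible and respects degenerate inputs", {
  p <- calibrated_base_case()
  a <- simulate_cohort(p, "DAPT", 2000, seed = 101)
  b <- simulate_cohort(p, "DAPT", 2000, seed = 101)
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
  c_ <- simulate_cohort(p, "DAPT", 2000, seed = 102)
  expect_false(identical(a$records$outcome, c_$records$outcome))

  # certain death with fixed costs: zero QALYs, zero spread
  sim <- simulate_cohort(death_certain_params(), "DAPT", 500, seed = 1)
  expect_true(all(sim$records$qaly == 0))
  expect_equal(sim$summary$sd_qaly, 0)
  expect_true(all(sim$records$cost == 100))
  expect_false(sim$summary$cer_defined)
  expect_true(is.na(sim$summary$cer))

  expect_error(simulate_cohort(p, "DAPT", 0, seed = 1), "positive integer")
  expect_error(simulate_cohort(base_case_parameters(), "DAPT", 10, seed = 1),
               "mix, costs")
})

test_that("cohort means converge to the analytic tree expectations", {
  p <- calibrated_base_case()
  p$mix["DAPT", ] <- c(PCI = 1, CABG = 0, MEDICAL = 0)
  sim <- simulate_cohort(p, "DAPT", 200000, seed = 77)
  ev <- expected_values(p, "DAPT")
  expect_lt(abs(sim$summary$mean_qaly - ev$expected_qaly),
            3 * sim$summary$se_qaly)
  expect_equal(ev$expected_qaly, 11.928, tolerance = 1e-3)
  expect_lt(abs(sim$summary$mean_cost - ev$expected_cost),
            3 * sim$summary$se_cost)
})

test_that("summaries use sample moments with the n-1 denominator", {
  rec <- data.frame(trial = 1:2, strategy = "DAPT", intervention = "PCI",
                    outcome = "NO_EVENT", cost = c(0, 200), qaly = c(10, 12))
  s <- summarize_trials(rec)
  expect_equal(s$mean_cost, 100)
  expect_equal(s$sd_cost, sqrt((100^2 + 100^2) / 1))  # 141.42 by hand
  expect_equal(round(s$sd_cost, 2), 141.42)
  expect_equal(s$se_cost, s$sd_cost / sqrt(2))
  expect_equal(s$cer, 100 / 11)

  rec2 <- rec
  rec2$cost <- c(100, 100)
  s2 <- summarize_trials(rec2)
  expect_equal(s2$mean_cost, 100)
  expect_equal(s2$sd_cost, 0)

  expect_error(summarize_trials(rec[0, ]), "non-empty")
  rec$strategy <- c("DAPT", "TAPT")
  expect_error(summarize_trials(rec), "single strategy")
})

test_that("outcome frequencies match the generating probabilities", {
  p <- calibrated_base_case()
  sim <- simulate_cohort(p, "TAPT", 10000, seed = 2024)
  rec <- sim$records
  for (i in interventions()) {
    sub <- rec[rec$intervention == i, ]
    obs <- table(factor(sub$outcome, levels = outcomes()))
    expected_p <- p$probabilities["TAPT", i, outcomes()]
    gof <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("the two-arm comparison is seeded, decorrelated and symmetric", {
  p <- calibrated_base_case()
  r1 <- run_comparison(p, n = 2000, seed = 5)
  r2 <- run_comparison(p, n = 2000, seed = 5)
  expect_identical(r1$summary_dapt, r2$summary_dapt)
  expect_identical(r1$comparison, r2$comparison)
  expect_false(identical(r1$subseeds[1], r1$subseeds[2]))

  # identical parameters in both arms: CER ratio near 1, QALY CI covers 0
  p_same <- p
  p_same$probabilities["TAPT", , ] <- p_same$probabilities["DAPT", , ]
  p_same$mix["TAPT", ] <- p_same$mix["DAPT", ]
  costs_d <- p_same$costs[p_same$costs$strategy == "DAPT", ]
  costs_t <- costs_d
  costs_t$strategy <- "TAPT"
  p_same$costs <- cost_model(rbind(costs_d, costs_t))
  r <- run_comparison(p_same, n = 10000, seed = 31)
  expect_equal(r$comparison$cer_ratio, 1, tolerance = 0.1)
  ci <- r$qaly_test$ci95
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("CERs scale linearly with costs and their ratio is invariant", {
  p <- calibrated_base_case()
  r <- run_comparison(p, n = 4000, seed = 12)

  p2 <- p
  p2$costs$mean <- p2$costs$mean * 2
  p2$costs$sd <- p2$costs$sd * 2
  r2 <- run_comparison(p2, n = 4000, seed = 12)
  expect_equal(r2$comparison$cer_dapt, 2 * r$comparison$cer_dapt,
               tolerance = 1e-10)
  expect_equal(r2$comparison$cer_tapt, 2 * r$comparison$cer_tapt,
               tolerance = 1e-10)
  expect_equal(r2$comparison$cer_ratio, r$comparison$cer_ratio,
               tolerance = 1e-10)

  # doubling only the TAPT costs doubles the CER ratio
  p3 <- p
  tapt_rows <- p3$costs$strategy == "TAPT"
  p3$costs$mean[tapt_rows] <- p3$costs$mean[tapt_rows] * 2
  p3$costs$sd[tapt_rows] <- p3$costs$sd[tapt_rows] * 2
  r3 <- run_comparison(p3, n = 4000, seed = 12)
  expect_equal(r3$comparison$cer_ratio, 2 * r$comparison$cer_ratio,
               tolerance = 1e-10)
})

test_that("cost-effectiveness plane export carries one row per trial", {
  p <- calibrated_base_case()
  r <- run_comparison(p, n = 300, seed = 8)
  plane <- ce_plane_data(r)
  expect_equal(nrow(plane), 600L)
  expect_named(plane, c("strategy", "trial", "qaly", "cost"))
  expect_equal(sum(plane$strategy == "DAPT"), 300L)
})
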