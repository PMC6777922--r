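bp <- base_case_parameters()

test_that("mix calibration hits interior targets with max-entropy weights", {
  q <- intervention_expected_qaly(bp$probabilities, bp$life_years,
                                  bp$utilities, "DAPT")
  # interior target: exact recovery
  target <- 0.6 * q[["PCI"]] + 0.4 * q[["CABG"]]  # between the two largest
  w <- calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                     target, "DAPT")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  expect_lt(abs(sum(w * q) - target), 1e-9)

  # boundary target recovers the vertex
  w_hi <- calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                        max(q), "DAPT")
  expect_equal(w_hi[["PCI"]], 1)
  w_lo <- calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                        min(q), "DAPT")
  expect_equal(w_lo[["MEDICAL"]], 1)

  # outside the envelope: error naming the bounds
  expect_error(
    calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                  max(q) + 1, "DAPT"),
    "envelope"
  )

  # determinism
  w2 <- calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                      target, "DAPT")
  expect_identical(w, w2)
})

test_that("mix calibration recovers targets generated from a known mix", {
  q <- intervention_expected_qaly(bp$probabilities, bp$life_years,
                                  bp$utilities, "TAPT")
  truth <- c(PCI = 0.55, CABG = 0.25, MEDICAL = 0.20)
  target <- sum(truth * q)
  w <- calibrate_mix(bp$probabilities, bp$life_years, bp$utilities,
                     target, "TAPT")
  # the mix itself may differ (underdetermined); the expectation must match
  expect_lt(abs(sum(w * q) - target), 1e-9)
})

test_that("cost calibration moment-matches the strategy-level summary", {
  # single active pathway: the gamma moments are the textbook conversion
  one <- data.frame(intervention = "PCI", outcome = "NO_EVENT",
                    path_probability = 1)
  cm <- calibrate_costs(one, 1000, 300, "DAPT")
  expect_equal(cm$mean, 1000)
  expect_equal(cm$sd, 300)
  gs <- gamma_shape_scale(cm$mean, cm$sd)
  expect_equal(round(gs[["shape"]], 2), 11.11)
  expect_equal(gs[["scale"]], 90)

  # zero target SD degenerates to a point mass
  cm0 <- calibrate_costs(one, 1000, 0, "DAPT")
  expect_identical(cm0$family, "FIXED")
  expect_equal(cm0$sd, 0)

  # full base case: analytic mixture moments equal the targets exactly
  cal <- calibrate_parameters(bp)
  expect_true(cal$converged)
  res <- cal$residuals
  expect_true(all(res$abs_error[res$moment == "mean_cost"] < 1e-6))
  expect_true(all(res$abs_error[res$moment == "mean_qaly"] < 1e-9))
  sd_rows <- res[res$moment == "sd_cost", ]
  expect_true(all(sd_rows$abs_error / sd_rows$target < 0.05))

  # severity ordering survives moment matching
  costs <- cal$params$costs
  by_iv <- tapply(costs$mean, costs$intervention, mean)
  expect_gt(by_iv[["CABG"]], by_iv[["PCI"]])
  expect_gt(by_iv[["PCI"]], by_iv[["MEDICAL"]])
  ne <- costs$mean[costs$outcome == "NO_EVENT"]
  bl <- costs$mean[costs$outcome == "BLEEDING"]
  expect_true(all(bl > ne))
})

test_that("infeasible cost SD targets are rejected with the feasible range", {
  p <- calibrated_base_case()
  pw <- enumerate_pathways(p, "TAPT")
  pw <- pw[, c("intervention", "outcome", "path_probability")]
  expect_error(calibrate_costs(pw, 49290, 100, "TAPT"),
               "feasible SDs")
})

test_that("calibration is deterministic and recovers synthetic ground truth", {
  a <- calibrate_parameters(bp)
  b <- calibrate_parameters(bp)
  expect_identical(a$mix, b$mix)
  expect_identical(a$costs, b$costs)

  # synthetic targets computed from a known parameter set are recovered to
  # numerical precision in expectation space
  truth <- fixed_cost_params()
  truth$costs <- cost_model(do.call(rbind, lapply(strategies(), function(s) {
    pw <- enumerate_pathways(truth, s)
    calibrate_costs(pw[, c("intervention", "outcome", "path_probability")],
                    20000, 15000, s)
  })))
  synth_targets <- do.call(rbind, lapply(strategies(), function(s) {
    ev <- expected_values(truth, s)
    pwq <- enumerate_pathways(truth, s)
    sdq <- sqrt(sum(pwq$path_probability * pwq$qaly^2) - ev$expected_qaly^2)
    data.frame(strategy = s, mean_cost = ev$expected_cost, sd_cost = 15000,
               mean_qaly = ev$expected_qaly, sd_qaly = sdq)
  }))
  recal <- calibrate_parameters(base_case_parameters(), synth_targets)
  for (s in strategies()) {
    ev_truth <- expected_values(truth, s)
    ev_recal <- expected_values(recal$params, s)
    expect_lt(abs(ev_recal$expected_qaly - ev_truth$expected_qaly), 1e-9)
    expect_lt(abs(ev_recal$expected_cost - ev_truth$expected_cost), 1e-9)
  }
})

test_that("verification z-scores separate calibrated from mis-scaled models", {
  p <- calibrated_base_case()
  v <- verify_calibration(p, n = 10000, seed = 19)
  expect_true(v$passed)
  cal_rows <- v$report[v$report$calibrated, ]
  expect_true(all(abs(cal_rows$z) < 3))

  # doubling all cost means is flagged loudly
  p2 <- p
  p2$costs$mean <- p2$costs$mean * 2
  v2 <- verify_calibration(p2, n = 10000, seed = 19)
  expect_false(v2$passed)
  z_mean_cost <- v2$report$z[v2$report$moment == "mean_cost"]
  expect_true(all(abs(z_mean_cost) > 10))

  # n = 1 still produces a report without crashing
  v1 <- verify_calibration(p, n = 1, seed = 3)
  expect_s3_class(v1, "calibration_verification")
  expect_equal(nrow(v1$report), 8L)
})
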