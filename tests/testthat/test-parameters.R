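test_that("no-event probability is the complement of the complication row", {
  # hand-derived from the base-case PCI and CABG rows
  expect_equal(complement_no_event(0.0361, 0.0374, 0.0120), 0.9145)
  expect_equal(complement_no_event(0.30, 0.53, 0.05), 0.12)
  expect_equal(complement_no_event(0, 0, 0), 1)
  expect_error(complement_no_event(0.6, 0.5, 0.1), "sum to")
  expect_error(complement_no_event(-0.1, 0, 0), "\\[0, 1\\]")
  expect_error(complement_no_event(0.2, 1.2, 0), "\\[0, 1\\]")
})

test_that("base-case tables reproduce every transcribed probability cell", {
  p <- base_case_probabilities()
  # all 18 complication cells, percent / 100
  cells <- rbind(
    c("DAPT", "MEDICAL", "VASCULAR", 0.0129),
    c("DAPT", "MEDICAL", "BLEEDING", 0.0859),
    c("DAPT", "MEDICAL", "DEATH", 0.0349),
    c("DAPT", "PCI", "VASCULAR", 0.0361),
    c("DAPT", "PCI", "BLEEDING", 0.0374),
    c("DAPT", "PCI", "DEATH", 0.0120),
    c("DAPT", "CABG", "VASCULAR", 0.0693),
    c("DAPT", "CABG", "BLEEDING", 0.0615),
    c("DAPT", "CABG", "DEATH", 0.0197),
    c("TAPT", "MEDICAL", "VASCULAR", 0.0139),
    c("TAPT", "MEDICAL", "BLEEDING", 0.1287),
    c("TAPT", "MEDICAL", "DEATH", 0.0538),
    c("TAPT", "PCI", "VASCULAR", 0.0557),
    c("TAPT", "PCI", "BLEEDING", 0.0596),
    c("TAPT", "PCI", "DEATH", 0.0115),
    c("TAPT", "CABG", "VASCULAR", 0.30),
    c("TAPT", "CABG", "BLEEDING", 0.53),
    c("TAPT", "CABG", "DEATH", 0.05)
  )
  for (k in seq_len(nrow(cells))) {
    expect_identical(p[cells[k, 1], cells[k, 2], cells[k, 3]],
                     as.numeric(cells[k, 4]))
  }
  # every (strategy, intervention) row is a simplex
  for (s in strategies()) {
    for (i in interventions()) {
      expect_equal(sum(p[s, i, ]), 1, tolerance = 1e-14)
      expect_true(all(p[s, i, ] >= 0 & p[s, i, ] <= 1))
    }
  }
  # payoff tables
  expect_identical(base_case_life_years(),
                   c(NO_EVENT = 14.5, BLEEDING = 12.3, VASCULAR = 5.2,
                     DEATH = 0))
  u <- base_case_utilities()
  expect_identical(u["MEDICAL", "VASCULAR"], 0.41)
  expect_identical(u["PROCEDURAL", "NO_EVENT"], 0.86)
  expect_true(all(u[, "DEATH"] == 0))
})

test_that("parameter validation names the offending key", {
  p <- base_case_parameters()
  p$probabilities["TAPT", "CABG", "DEATH"] <- 1.2
  expect_error(validate_parameters(p), "probabilities.TAPT.CABG")

  p <- base_case_parameters()
  p$life_years["DEATH"] <- 2
  expect_error(validate_parameters(p), "life_years.DEATH")

  p <- base_case_parameters()
  p$utilities["MEDICAL", "BLEEDING"] <- 1.4
  expect_error(validate_parameters(p), "utilities")

  expect_error(
    intervention_mix(matrix(c(0.5, 0.4, 0.2, 0.3, 0.3, 0.4), 2, 3,
                            byrow = TRUE,
                            dimnames = list(strategies(), interventions()))),
    "mix.DAPT"
  )
  expect_error(base_case_parameters(n_trials = 0), "n_trials")
})

test_that("cost model enforces family-specific constraints", {
  grid <- expand.grid(outcome = outcomes(), intervention = interventions(),
                      strategy = strategies(), stringsAsFactors = FALSE)
  base <- data.frame(strategy = grid$strategy,
                     intervention = grid$intervention,
                     outcome = grid$outcome,
                     family = "GAMMA", mean = 1000, sd = 300)
  expect_silent(cost_model(base))

  bad <- base
  bad$family[1] <- "FIXED"   # sd stays 300
  expect_error(cost_model(bad), "FIXED entries must have sd = 0")

  bad <- base
  bad$mean[2] <- 0
  expect_error(cost_model(bad), "GAMMA entries must have mean > 0")

  expect_error(cost_model(base[-1, ]), "missing pathway")
})

test_that("config round-trips bit-exactly and fills defaults", {
  # full calibrated parameter set survives write -> load unchanged
  p <- calibrated_base_case()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  expect_identical(q$probabilities, p$probabilities)
  expect_identical(q$mix, p$mix)
  expect_identical(q$life_years, p$life_years)
  expect_identical(q$utilities, p$utilities)
  expect_identical(q$costs$mean, p$costs$mean)
  expect_identical(q$costs$sd, p$costs$sd)
  expect_identical(q$n_trials, p$n_trials)

  # a config with only simulation settings gets the base-case defaults but
  # cannot be used for simulation without mix/costs
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("simulation:\n  n_trials: 500\n  seed: 3", f2)
  expect_error(load_parameters(f2), "mix, costs")
  q2 <- load_parameters(f2, allow_uncalibrated = TRUE)
  expect_identical(q2$probabilities, base_case_probabilities())
  expect_identical(q2$probabilities["DAPT", "CABG", "VASCULAR"], 0.0693)
  expect_identical(q2$n_trials, 500L)

  # schema violations name the offending key
  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("life_years:\n  NO_EVENT: 14.5", f3)
  expect_error(load_parameters(f3, allow_uncalibrated = TRUE),
               "life_years: missing key")
  f4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bogus_section: 1", f4)
  expect_error(load_parameters(f4, allow_uncalibrated = TRUE),
               "bogus_section")
})

test_that("the bundled base-case config matches the built-in defaults", {
  cfg <- system.file("extdata", "base_case.yaml", package = "aptcea")
  p <- load_parameters(cfg, allow_uncalibrated = TRUE)
  expect_identical(p$probabilities, base_case_probabilities())
  expect_identical(p$life_years, base_case_life_years())
  expect_identical(p$utilities, base_case_utilities())
  cal <- system.file("extdata", "base_case_calibrated.yaml", package = "aptcea")
  expect_true(is_fully_specified(load_parameters(cal)))
})
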