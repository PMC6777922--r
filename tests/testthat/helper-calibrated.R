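# Calibrated base case, computed once per test run.
.calibrated_cache <- new.env(parent = emptyenv())

calibrated_base_case <- function() {
  if (is.null(.calibrated_cache$params)) {
    .calibrated_cache$params <-
      calibrate_parameters(base_case_parameters())$params
  }
  .calibrated_cache$params
}

# A tiny fully specified parameter set with fixed costs, handy for
# deterministic-path tests.
fixed_cost_params <- function(cost = 100) {
  p <- base_case_parameters()
  p$mix <- intervention_mix(matrix(
    c(0.5, 0.3, 0.2, 0.5, 0.3, 0.2), nrow = 2, byrow = TRUE,
    dimnames = list(strategies(), interventions())
  ))
  grid <- expand.grid(outcome = outcomes(), intervention = interventions(),
                      strategy = strategies(), stringsAsFactors = FALSE)
  p$costs <- cost_model(data.frame(
    strategy = grid$strategy, intervention = grid$intervention,
    outcome = grid$outcome, family = "FIXED", mean = cost, sd = 0
  ))
  p
}

# Parameter set where death is certain everywhere.
death_certain_params <- function() {
  p <- fixed_cost_params()
  for (s in strategies()) {
    for (i in interventions()) {
      p$probabilities[s, i, ] <- c(NO_EVENT = 0, BLEEDING = 0,
                                   VASCULAR = 0, DEATH = 1)
    }
  }
  p
}
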