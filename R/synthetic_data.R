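#' Specify a synthetic parameter scenario
#'
#' Controls how far a generated scenario strays from its base parameter set:
#' outcome probability rows are redrawn from a Dirichlet centered on the base
#' row (`alpha = concentration * base`), pathway cost means are jittered with
#' a multiplicative gamma factor of unit mean and the given coefficient of
#' variation, and the intervention mix is redrawn from a Dirichlet around its
#' prior.
#'
#' @param seed Integer RNG seed for the scenario.
#' @param probability_concentration Dirichlet concentration (> 0); larger
#'   means closer to the base probabilities. Default 200 — roughly the
#'   spread of moderately sized clinical trials.
#' @param cost_cv Coefficient of variation of the cost-mean jitter (> 0).
#' @param mix_prior `"uniform"` or a simplex weight vector over
#'   interventions; `"uniform"` uses the base mix when set, else equal
#'   weights.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed, probability_concentration = 200,
                          cost_cv = 0.25, mix_prior = "uniform") {
  if (probability_concentration <= 0) {
    stop("probability_concentration must be > 0", call. = FALSE)
  }
  if (cost_cv <= 0) stop("cost_cv must be > 0", call. = FALSE)
  if (!identical(mix_prior, "uniform")) {
    mix_prior <- mix_prior[interventions()]
    if (anyNA(mix_prior) || any(mix_prior < 0) ||
        abs(sum(mix_prior) - 1) > 1e-12) {
      stop("mix_prior must be 'uniform' or a simplex over interventions",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed),
                 probability_concentration = probability_concentration,
                 cost_cv = cost_cv, mix_prior = mix_prior),
            class = "scenario_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {  # only possible when some alpha are 0 and the rest tiny
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Generate a perturbed parameter scenario
#'
#' Redraws every (strategy, intervention) outcome row from a Dirichlet
#' centered on the base row, redraws the intervention mix, and jitters
#' pathway cost means (when a cost model is present) preserving each
#' pathway's coefficient of variation. Deterministic given the spec seed;
#' the result always passes [validate_parameters()].
#'
#' @param base A valid `model_parameters` object.
#' @param spec A [scenario_spec()].
#' @return A new `model_parameters` object.
#' @export
generate_scenario <- function(base, spec) {
  stopifnot(inherits(base, "model_parameters"),
            inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  out <- base
  conc <- spec$probability_concentration
  for (s in strategies()) {
    for (i in interventions()) {
      p <- base$probabilities[s, i, ]
      out$probabilities[s, i, ] <- rdirichlet1(conc * p)
    }
  }
  prior <- if (identical(spec$mix_prior, "uniform")) {
    if (!is.null(base$mix)) NULL else rep(1 / 3, 3)
  } else {
    spec$mix_prior
  }
  mix <- matrix(NA_real_, 2L, 3L,
                dimnames = list(strategies(), interventions()))
  for (s in strategies()) {
    pr <- if (is.null(prior)) base$mix[s, ] else prior
    mix[s, ] <- rdirichlet1(conc * pr)
  }
  out$mix <- intervention_mix(mix)
  if (!is.null(base$costs)) {
    cv <- spec$cost_cv
    f <- stats::rgamma(nrow(out$costs), shape = 1 / cv^2, scale = cv^2)
    out$costs$mean <- out$costs$mean * f
    out$costs$sd <- out$costs$sd * f   # preserve pathway-level CV
  }
  validate_parameters(out)
}

#' Generate a ground-truth patient cohort
#'
#' Simulates both strategy arms from a known parameter set, recording the
#' generating truth alongside the records, for end-to-end recovery tests
#' (estimate outcome frequencies and cost/QALY moments from the records and
#' compare against the generating analytics).
#'
#' @param params A fully specified `model_parameters` object (the truth).
#' @param n Trials per strategy, `>= 1`.
#' @param seed Master seed.
#' @return An object of class `ground_truth_cohort`: `params`, `records`
#'   (both arms), `n`, `seed`.
#' @export
generate_ground_truth_cohort <- function(params, n, seed) {
  require_fully_specified(params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  ss <- derive_subseeds(seed, 2L)
  rec <- rbind(simulate_cohort(params, "DAPT", n, ss[1])$records,
               simulate_cohort(params, "TAPT", n, ss[2])$records)
  structure(list(params = params, records = rec, n = n,
                 seed = as.integer(seed)),
            class = "ground_truth_cohort")
}

#' @export
print.ground_truth_cohort <- function(x, ...) {
  cat(sprintf("<ground_truth_cohort> %d trials per strategy, seed %d\n",
              x$n, x$seed))
  invisible(x)
}
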