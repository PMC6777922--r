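#' Residual probability of the no-event outcome
#'
#' The 30-day outcome set is exhaustive and mutually exclusive: "no event" is
#' defined as any outcome other than a vascular event, bleeding or death, so
#' its probability is always the complement of the three complication
#' probabilities and is never set directly.
#'
#' @param p_cv Probability of a vascular (cardiovascular) event, in `[0, 1]`.
#' @param p_bleed Probability of major bleeding, in `[0, 1]`.
#' @param p_death Probability of all-cause death, in `[0, 1]`.
#' @return `1 - (p_cv + p_bleed + p_death)`. Vectorized.
#' @export
#' @examples
#' complement_no_event(0.0361, 0.0374, 0.0120)
complement_no_event <- function(p_cv, p_bleed, p_death) {
  p <- cbind(p_cv, p_bleed, p_death)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("complication probabilities must lie in [0, 1]", call. = FALSE)
  }
  s <- p_cv + p_bleed + p_death
  bad <- s > 1 + 1e-12
  if (any(bad)) {
    stop(sprintf(
      "complication probabilities sum to %.6f > 1: not a valid outcome row",
      max(s[bad])
    ), call. = FALSE)
  }
  pmax(1 - s, 0)
}

#' Build an outcome probability array
#'
#' @param complications A data.frame with columns `strategy`, `intervention`,
#'   `outcome` (one of BLEEDING/VASCULAR/DEATH) and `prob` (fractions, not
#'   percents), covering all 2 x 3 x 3 cells. `NO_EVENT` is derived.
#' @return A 3-d numeric array indexed `[strategy, intervention, outcome]`
#'   whose rows over outcomes are simplexes.
#' @export
outcome_probability_table <- function(complications) {
  stopifnot(is.data.frame(complications),
            all(c("strategy", "intervention", "outcome", "prob") %in%
                  names(complications)))
  arr <- array(
    NA_real_, dim = c(2L, 3L, 4L),
    dimnames = list(strategy = strategies(), intervention = interventions(),
                    outcome = outcomes())
  )
  for (k in seq_len(nrow(complications))) {
    row <- complications[k, ]
    if (row$outcome == "NO_EVENT") {
      stop("probabilities.NO_EVENT is derived and cannot be set directly",
           call. = FALSE)
    }
    arr[row$strategy, row$intervention, row$outcome] <- row$prob
  }
  for (s in strategies()) {
    for (i in interventions()) {
      p3 <- arr[s, i, complication_outcomes()]
      if (anyNA(p3)) {
        stop(sprintf("probabilities.%s.%s: missing complication outcome(s)",
                     s, i), call. = FALSE)
      }
      arr[s, i, "NO_EVENT"] <- complement_no_event(
        arr[s, i, "VASCULAR"], arr[s, i, "BLEEDING"], arr[s, i, "DEATH"]
      )
    }
  }
  validate_probability_array(arr)
  arr
}

validate_probability_array <- function(arr) {
  stopifnot(identical(dim(arr), c(2L, 3L, 4L)))
  for (s in strategies()) {
    for (i in interventions()) {
      p <- arr[s, i, ]
      if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
        stop(sprintf("probabilities.%s.%s: values outside [0, 1]", s, i),
             call. = FALSE)
      }
      if (abs(sum(p) - 1) > 1e-12) {
        stop(sprintf("probabilities.%s.%s: outcome probabilities sum to %.15f, not 1",
                     s, i, sum(p)), call. = FALSE)
      }
    }
  }
  invisible(arr)
}

#' Literature-derived base-case inputs
#'
#' The base-case 30-day outcome probabilities per strategy and intervention
#' (pooled from randomized antiplatelet trials; stored as fractions, printed
#' sources give percents), life-years extended per outcome, and EQ-5D-derived
#' utility coefficients per intervention class and outcome.
#'
#' @return `base_case_probabilities()`: a `[strategy, intervention, outcome]`
#'   array; `base_case_life_years()`: named numeric vector over outcomes
#'   (years); `base_case_utilities()`: a `[utility_class, outcome]` matrix of
#'   coefficients in `[0, 1]`.
#' @name base_case_inputs
NULL

#' @rdname base_case_inputs
#' @export
base_case_probabilities <- function() {
  cells <- rbind(
    # strategy, intervention, VASCULAR, BLEEDING, DEATH  (fractions)
    data.frame(strategy = "DAPT", intervention = "MEDICAL",
               VASCULAR = 0.0129, BLEEDING = 0.0859, DEATH = 0.0349),
    data.frame(strategy = "DAPT", intervention = "PCI",
               VASCULAR = 0.0361, BLEEDING = 0.0374, DEATH = 0.0120),
    data.frame(strategy = "DAPT", intervention = "CABG",
               VASCULAR = 0.0693, BLEEDING = 0.0615, DEATH = 0.0197),
    data.frame(strategy = "TAPT", intervention = "MEDICAL",
               VASCULAR = 0.0139, BLEEDING = 0.1287, DEATH = 0.0538),
    data.frame(strategy = "TAPT", intervention = "PCI",
               VASCULAR = 0.0557, BLEEDING = 0.0596, DEATH = 0.0115),
    data.frame(strategy = "TAPT", intervention = "CABG",
               VASCULAR = 0.30, BLEEDING = 0.53, DEATH = 0.05)
  )
  long <- do.call(rbind, lapply(complication_outcomes(), function(o) {
    data.frame(strategy = cells$strategy, intervention = cells$intervention,
               outcome = o, prob = cells[[o]])
  }))
  outcome_probability_table(long)
}

#' @rdname base_case_inputs
#' @export
base_case_life_years <- function() {
  c(NO_EVENT = 14.5, BLEEDING = 12.3, VASCULAR = 5.2, DEATH = 0)
}

#' @rdname base_case_inputs
#' @export
base_case_utilities <- function() {
  m <- rbind(
    PROCEDURAL = c(NO_EVENT = 0.86, BLEEDING = 0.83, VASCULAR = 0.76, DEATH = 0),
    MEDICAL    = c(NO_EVENT = 0.45, BLEEDING = 0.45, VASCULAR = 0.41, DEATH = 0)
  )
  m
}

#' Intervention-mix weights
#'
#' @param weights A `[strategy, intervention]` matrix (or coercible) of
#'   non-negative weights; each strategy row must sum to 1.
#' @return The validated matrix.
#' @export
intervention_mix <- function(weights) {
  weights <- as.matrix(weights)
  weights <- weights[strategies(), interventions(), drop = FALSE]
  for (s in strategies()) {
    w <- weights[s, ]
    if (any(!is.finite(w)) || any(w < 0)) {
      stop(sprintf("mix.%s: weights must be finite and non-negative", s),
           call. = FALSE)
    }
    if (abs(sum(w) - 1) > 1e-12) {
      stop(sprintf("mix.%s: weights sum to %.15f, not 1", s, sum(w)),
           call. = FALSE)
    }
  }
  weights
}

#' Pathway cost model
#'
#' One cost distribution per (strategy, intervention, outcome) pathway:
#' either a gamma with a given mean and SD (positive, right-skewed, the usual
#' choice for healthcare costs) or a fixed point mass.
#'
#' @param entries A data.frame with columns `strategy`, `intervention`,
#'   `outcome`, `family` (`"GAMMA"` or `"FIXED"`), `mean`, `sd` (USD). All 24
#'   pathways must be present.
#' @return The validated data.frame, ordered canonically.
#' @export
cost_model <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("strategy", "intervention", "outcome", "family",
                  "mean", "sd") %in% names(entries)))
  key <- expand.grid(outcome = outcomes(), intervention = interventions(),
                     strategy = strategies(), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  key <- key[, c("strategy", "intervention", "outcome")]
  got <- paste(entries$strategy, entries$intervention, entries$outcome)
  want <- paste(key$strategy, key$intervention, key$outcome)
  if (anyDuplicated(got)) {
    stop("costs: duplicate pathway entries", call. = FALSE)
  }
  missing <- setdiff(want, got)
  if (length(missing)) {
    stop(sprintf("costs: missing pathway entries: %s",
                 paste(missing[seq_len(min(3, length(missing)))], collapse = ", ")),
         call. = FALSE)
  }
  entries <- entries[match(want, got),
                     c("strategy", "intervention", "outcome", "family",
                       "mean", "sd")]
  rownames(entries) <- NULL
  for (k in seq_len(nrow(entries))) {
    e <- entries[k, ]
    id <- sprintf("costs.%s.%s.%s", e$strategy, e$intervention, e$outcome)
    if (!e$family %in% c("GAMMA", "FIXED")) {
      stop(sprintf("%s.family: must be GAMMA or FIXED", id), call. = FALSE)
    }
    if (!is.finite(e$mean) || e$mean < 0 || !is.finite(e$sd) || e$sd < 0) {
      stop(sprintf("%s: mean and sd must be finite and non-negative", id),
           call. = FALSE)
    }
    if (e$family == "FIXED" && e$sd != 0) {
      stop(sprintf("%s: FIXED entries must have sd = 0", id), call. = FALSE)
    }
    if (e$family == "GAMMA" && e$mean <= 0) {
      stop(sprintf("%s: GAMMA entries must have mean > 0", id), call. = FALSE)
    }
  }
  entries
}

#' Assemble and validate the full model parameter set
#'
#' @param probabilities `[strategy, intervention, outcome]` probability array
#'   (see [outcome_probability_table()]).
#' @param life_years Named numeric vector of life-years extended per outcome;
#'   `DEATH` must be 0.
#' @param utilities `[utility_class, outcome]` coefficient matrix in `[0, 1]`;
#'   `DEATH` column must be 0.
#' @param mix Optional `[strategy, intervention]` mix matrix (see
#'   [intervention_mix()]); `NULL` until calibrated or supplied.
#' @param costs Optional pathway cost model (see [cost_model()]); `NULL` until
#'   calibrated or supplied.
#' @param n_trials Number of Monte Carlo trials per strategy (default 10000).
#' @param seed Master RNG seed.
#' @param qaly_override Optional named vector of per-outcome QALYs used
#'   verbatim instead of `life_years * utility` (see
#'   [the vignette][aptcea-package] for when this is useful); `NULL` (the
#'   default) computes QALYs as the product.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(probabilities, life_years, utilities,
                             mix = NULL, costs = NULL,
                             n_trials = 10000L, seed = 42L,
                             qaly_override = NULL) {
  params <- structure(
    list(probabilities = probabilities, life_years = life_years,
         utilities = utilities, mix = mix, costs = costs,
         n_trials = as.integer(n_trials), seed = as.integer(seed),
         qaly_override = qaly_override),
    class = "model_parameters"
  )
  validate_parameters(params)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant: outcome rows are simplexes, life-years
#' non-negative with `DEATH = 0`, utility coefficients in `[0, 1]` with
#' `DEATH = 0`, mix rows sum to 1, cost entries well-formed, `n_trials >= 1`.
#' Errors name the offending key.
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  validate_probability_array(params$probabilities)

  ly <- params$life_years[outcomes()]
  if (anyNA(ly)) stop("life_years: all four outcomes required", call. = FALSE)
  if (any(!is.finite(ly)) || any(ly < 0)) {
    stop("life_years: values must be finite and non-negative", call. = FALSE)
  }
  if (ly[["DEATH"]] != 0) stop("life_years.DEATH: must be 0", call. = FALSE)

  u <- params$utilities
  u <- u[utility_classes(), outcomes(), drop = FALSE]
  if (anyNA(u)) stop("utilities: incomplete coefficient table", call. = FALSE)
  if (any(u < 0) || any(u > 1)) {
    stop("utilities: coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (any(u[, "DEATH"] != 0)) stop("utilities.DEATH: must be 0", call. = FALSE)

  if (!is.null(params$mix)) intervention_mix(params$mix)
  if (!is.null(params$costs)) cost_model(params$costs)

  if (!is.null(params$qaly_override)) {
    qo <- params$qaly_override[outcomes()]
    if (anyNA(qo) || any(!is.finite(qo)) || any(qo < 0)) {
      stop("qaly_override: all four outcomes required, finite and non-negative",
           call. = FALSE)
    }
  }

  if (is.na(params$n_trials) || params$n_trials < 1L) {
    stop("simulation.n_trials: must be a positive integer", call. = FALSE)
  }
  invisible(params)
}

#' Base-case model parameters
#'
#' The transcribed literature inputs: outcome probabilities, life-years and
#' utility coefficients. The intervention mix and pathway costs were never
#' published at this level and are left `NULL`; fill them with
#' [calibrate_parameters()] or a config file before simulating.
#'
#' @inheritParams model_parameters
#' @return A `model_parameters` object with `mix` and `costs` unset.
#' @export
#' @examples
#' p <- base_case_parameters()
#' p$probabilities["DAPT", "CABG", "VASCULAR"]  # 0.0693
base_case_parameters <- function(n_trials = 10000L, seed = 42L) {
  model_parameters(
    probabilities = base_case_probabilities(),
    life_years = base_case_life_years(),
    utilities = base_case_utilities(),
    n_trials = n_trials, seed = seed
  )
}

#' Is the parameter set ready for simulation?
#'
#' @param params A `model_parameters` object.
#' @return `TRUE` when both the intervention mix and the cost model are set.
#' @export
is_fully_specified <- function(params) {
  !is.null(params$mix) && !is.null(params$costs)
}

require_fully_specified <- function(params) {
  missing <- c(if (is.null(params$mix)) "mix",
               if (is.null(params$costs)) "costs")
  if (length(missing)) {
    stop(sprintf(
      "parameter block(s) missing: %s; supply them in the config or run calibrate_parameters()",
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat("  strategies:    ", paste(strategies(), collapse = ", "), "\n")
  cat("  interventions: ", paste(interventions(), collapse = ", "), "\n")
  cat("  outcomes:      ", paste(outcomes(), collapse = ", "), "\n")
  cat("  mix:           ", if (is.null(x$mix)) "<unset>" else "set", "\n")
  cat("  costs:         ", if (is.null(x$costs)) "<unset>" else "set", "\n")
  cat("  n_trials:      ", x$n_trials, " seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
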