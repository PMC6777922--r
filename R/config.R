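# YAML config round-trip. Schema (all sections optional except as noted):
#
#   probabilities:           # fractions; NO_EVENT is derived, never listed
#     DAPT: {PCI: {VASCULAR: 0.0361, BLEEDING: 0.0374, DEATH: 0.0120}, ...}
#   mix:                     # required unless allow_uncalibrated
#     DAPT: {PCI: w, CABG: w, MEDICAL: w}
#   life_years: {NO_EVENT: 14.5, BLEEDING: 12.3, VASCULAR: 5.2, DEATH: 0}
#   utilities:
#     PROCEDURAL: {NO_EVENT: 0.86, ...}
#   costs:                   # required unless allow_uncalibrated
#     DAPT: {PCI: {NO_EVENT: {family: GAMMA, mean: ..., sd: ...}, ...}, ...}
#   qaly_override: {NO_EVENT: 12.04, ...}   # optional
#   simulation: {n_trials: 10000, seed: 42}
#
# Missing probabilities / life_years / utilities sections fall back to the
# base-case defaults; missing mix / costs raise unless allow_uncalibrated.

#' Load model parameters from a YAML config file
#'
#' @param config_path Path to a YAML file following the documented schema
#'   (see the bundled `inst/extdata/base_case.yaml`).
#' @param allow_uncalibrated If `FALSE` (default), a config without `mix` and
#'   `costs` sections is an error, because the model cannot be simulated;
#'   set `TRUE` to load such a config for calibration.
#' @return A validated [model_parameters()] object.
#' @export
load_parameters <- function(config_path, allow_uncalibrated = FALSE) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  if (!is.list(cfg)) stop("config: top level must be a mapping", call. = FALSE)
  known <- c("strategies", "probabilities", "mix", "life_years", "utilities",
             "costs", "qaly_override", "simulation")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("config: unknown section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  probs <- if (is.null(cfg$probabilities)) {
    base_case_probabilities()
  } else {
    parse_probabilities(cfg$probabilities)
  }
  life_years <- if (is.null(cfg$life_years)) {
    base_case_life_years()
  } else {
    parse_named_numeric(cfg$life_years, outcomes(), "life_years")
  }
  utilities <- if (is.null(cfg$utilities)) {
    base_case_utilities()
  } else {
    parse_utilities(cfg$utilities)
  }
  mix <- if (is.null(cfg$mix)) NULL else parse_mix(cfg$mix)
  costs <- if (is.null(cfg$costs)) NULL else parse_costs(cfg$costs)
  qaly_override <- if (is.null(cfg$qaly_override)) {
    NULL
  } else {
    parse_named_numeric(cfg$qaly_override, outcomes(), "qaly_override")
  }

  sim <- cfg$simulation
  n_trials <- if (is.null(sim$n_trials)) 10000L else sim$n_trials
  seed <- if (is.null(sim$seed)) 42L else sim$seed

  params <- model_parameters(
    probabilities = probs, life_years = life_years, utilities = utilities,
    mix = mix, costs = costs, n_trials = n_trials, seed = seed,
    qaly_override = qaly_override
  )
  if (!allow_uncalibrated) require_fully_specified(params)
  params
}

parse_named_numeric <- function(x, keys, section) {
  vals <- unlist(x)
  missing <- setdiff(keys, names(vals))
  if (length(missing)) {
    stop(sprintf("%s: missing key(s): %s", section,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(vals), keys)
  if (length(extra)) {
    stop(sprintf("%s: unknown key(s): %s", section,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(vals)) {
    stop(sprintf("%s: values must be numeric", section), call. = FALSE)
  }
  vals[keys]
}

parse_probabilities <- function(x) {
  rows <- list()
  for (s in names(x)) {
    if (!s %in% strategies()) {
      stop(sprintf("probabilities.%s: unknown strategy", s), call. = FALSE)
    }
    for (i in names(x[[s]])) {
      if (!i %in% interventions()) {
        stop(sprintf("probabilities.%s.%s: unknown intervention", s, i),
             call. = FALSE)
      }
      cell <- x[[s]][[i]]
      p3 <- parse_named_numeric(cell, complication_outcomes(),
                                sprintf("probabilities.%s.%s", s, i))
      for (o in complication_outcomes()) {
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = s, intervention = i, outcome = o, prob = p3[[o]]
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  if (nrow(df) != 18L) {
    stop("probabilities: all 6 (strategy, intervention) cells required",
         call. = FALSE)
  }
  outcome_probability_table(df)
}

parse_utilities <- function(x) {
  m <- matrix(NA_real_, 2L, 4L,
              dimnames = list(utility_classes(), outcomes()))
  for (cl in names(x)) {
    if (!cl %in% utility_classes()) {
      stop(sprintf("utilities.%s: unknown utility class", cl), call. = FALSE)
    }
    m[cl, ] <- parse_named_numeric(x[[cl]], outcomes(),
                                   sprintf("utilities.%s", cl))
  }
  m
}

parse_mix <- function(x) {
  m <- matrix(NA_real_, 2L, 3L,
              dimnames = list(strategies(), interventions()))
  for (s in names(x)) {
    if (!s %in% strategies()) {
      stop(sprintf("mix.%s: unknown strategy", s), call. = FALSE)
    }
    m[s, ] <- parse_named_numeric(x[[s]], interventions(),
                                  sprintf("mix.%s", s))
  }
  if (anyNA(m)) stop("mix: both strategies required", call. = FALSE)
  intervention_mix(m)
}

parse_costs <- function(x) {
  rows <- list()
  for (s in names(x)) {
    for (i in names(x[[s]])) {
      for (o in names(x[[s]][[i]])) {
        e <- x[[s]][[i]][[o]]
        id <- sprintf("costs.%s.%s.%s", s, i, o)
        if (is.null(e$family) || is.null(e$mean)) {
          stop(sprintf("%s: family and mean required", id), call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = s, intervention = i, outcome = o,
          family = e$family, mean = e$mean,
          sd = if (is.null(e$sd)) 0 else e$sd
        )
      }
    }
  }
  cost_model(do.call(rbind, rows))
}

#' Write model parameters to a YAML config file
#'
#' The written file round-trips: `load_parameters(write_parameters(p, f))`
#' reproduces `p` bit-exactly for all stored numeric fields (17 significant
#' digits are written, enough to reconstruct any double).
#'
#' @param params A `model_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  cfg <- list()
  cfg$probabilities <- nested_from_array(
    params$probabilities, complication_outcomes()
  )
  if (!is.null(params$mix)) {
    cfg$mix <- lapply(stats::setNames(strategies(), strategies()), function(s) {
      as.list(params$mix[s, interventions()])
    })
  }
  cfg$life_years <- as.list(params$life_years[outcomes()])
  cfg$utilities <- lapply(
    stats::setNames(utility_classes(), utility_classes()),
    function(cl) as.list(params$utilities[cl, outcomes()])
  )
  if (!is.null(params$costs)) {
    costs <- params$costs
    cfg$costs <- lapply(stats::setNames(strategies(), strategies()), function(s) {
      lapply(stats::setNames(interventions(), interventions()), function(i) {
        lapply(stats::setNames(outcomes(), outcomes()), function(o) {
          e <- costs[costs$strategy == s & costs$intervention == i &
                       costs$outcome == o, ]
          list(family = e$family, mean = e$mean, sd = e$sd)
        })
      })
    })
  }
  if (!is.null(params$qaly_override)) {
    cfg$qaly_override <- as.list(params$qaly_override[outcomes()])
  }
  cfg$simulation <- list(n_trials = params$n_trials, seed = params$seed)
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

nested_from_array <- function(arr, outs) {
  lapply(stats::setNames(strategies(), strategies()), function(s) {
    lapply(stats::setNames(interventions(), interventions()), function(i) {
      as.list(arr[s, i, outs])
    })
  })
}
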