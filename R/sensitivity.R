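#' Perturb one model parameter
#'
#' Returns a new parameter set with the parameter at `parameter_id` (a dotted
#' path) set to `value`, keeping all invariants:
#'
#' * `probabilities.<strategy>.<intervention>.<outcome>` — for a complication
#'   outcome the NO_EVENT residual is recomputed; for `NO_EVENT` itself the
#'   three complication probabilities are rescaled proportionally to absorb
#'   the change.
#' * `mix.<strategy>.<intervention>` — the other two weights are rescaled
#'   proportionally.
#' * `life_years.<outcome>`, `utilities.<class>.<outcome>`,
#'   `costs.<strategy>.<intervention>.<outcome>.mean` — set directly.
#'
#' @param params A `model_parameters` object.
#' @param parameter_id Dotted path, e.g. `"probabilities.DAPT.PCI.BLEEDING"`.
#' @param value New value, within the parameter's legal range.
#' @return A new validated `model_parameters` object.
#' @export
perturb <- function(params, parameter_id, value) {
  parts <- strsplit(parameter_id, ".", fixed = TRUE)[[1]]
  section <- parts[1]
  out <- params
  if (section == "probabilities") {
    if (length(parts) != 4L) {
      stop(sprintf("cannot resolve parameter id '%s'", parameter_id),
           call. = FALSE)
    }
    s <- match_strategy(parts[2]); i <- match_intervention(parts[3])
    o <- match_outcome(parts[4])
    if (value < 0 || value > 1) {
      stop(sprintf("%s: probability %g outside [0, 1]", parameter_id, value),
           call. = FALSE)
    }
    p <- out$probabilities[s, i, ]
    if (o == "NO_EVENT") {
      rest <- 1 - value
      others <- p[complication_outcomes()]
      tot <- sum(others)
      p[complication_outcomes()] <- if (tot > 0) {
        others * rest / tot
      } else {
        rest / 3
      }
      p["NO_EVENT"] <- value
    } else {
      p[o] <- value
      p["NO_EVENT"] <- complement_no_event(
        p[["VASCULAR"]], p[["BLEEDING"]], p[["DEATH"]]
      )
    }
    out$probabilities[s, i, ] <- p
  } else if (section == "mix") {
    if (is.null(out$mix)) stop("parameter block(s) missing: mix", call. = FALSE)
    s <- match_strategy(parts[2]); i <- match_intervention(parts[3])
    if (value < 0 || value > 1) {
      stop(sprintf("%s: weight %g outside [0, 1]", parameter_id, value),
           call. = FALSE)
    }
    w <- out$mix[s, ]
    others <- setdiff(interventions(), i)
    tot <- sum(w[others])
    w[others] <- if (tot > 0) w[others] * (1 - value) / tot else (1 - value) / 2
    w[i] <- value
    out$mix[s, ] <- w
  } else if (section == "life_years") {
    o <- match_outcome(parts[2])
    out$life_years[o] <- value
  } else if (section == "utilities") {
    cl <- match.arg(parts[2], utility_classes())
    o <- match_outcome(parts[3])
    out$utilities[cl, o] <- value
  } else if (section == "costs") {
    if (is.null(out$costs)) {
      stop("parameter block(s) missing: costs", call. = FALSE)
    }
    if (length(parts) != 5L || parts[5] != "mean") {
      stop(sprintf("cannot resolve parameter id '%s'", parameter_id),
           call. = FALSE)
    }
    s <- match_strategy(parts[2]); i <- match_intervention(parts[3])
    o <- match_outcome(parts[4])
    row <- which(out$costs$strategy == s & out$costs$intervention == i &
                   out$costs$outcome == o)
    out$costs$mean[row] <- value
  } else {
    stop(sprintf("cannot resolve parameter id '%s'", parameter_id),
         call. = FALSE)
  }
  validate_parameters(out)
}

# Resolve a parameter id to its current value (used for default axis ranges).
current_value <- function(params, parameter_id) {
  parts <- strsplit(parameter_id, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    probabilities = params$probabilities[parts[2], parts[3], parts[4]],
    mix = params$mix[parts[2], parts[3]],
    life_years = params$life_years[[parts[2]]],
    utilities = params$utilities[parts[2], parts[3]],
    costs = {
      row <- which(params$costs$strategy == parts[2] &
                     params$costs$intervention == parts[3] &
                     params$costs$outcome == parts[4])
      params$costs$mean[row]
    },
    stop(sprintf("cannot resolve parameter id '%s'", parameter_id),
         call. = FALSE)
  )
}

#' Define a sensitivity axis
#'
#' One varied parameter with its range and number of grid steps. With `low`
#' or `high` `NULL`, the range defaults to +/- 50% of the parameter's current
#' value at evaluation time (clamped to `[0, 1]` for probabilities).
#'
#' @param parameter_id Dotted parameter path (see [perturb()]).
#' @param low,high Range endpoints (`low <= high`), or `NULL` for the
#'   default relative range.
#' @param steps Number of grid points, `>= 1`.
#' @return An object of class `sensitivity_axis`.
#' @export
sensitivity_axis <- function(parameter_id, low = NULL, high = NULL,
                             steps = 21L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be >= 1", call. = FALSE)
  if (!is.null(low) && !is.null(high) && low > high) {
    stop("axis low must be <= high", call. = FALSE)
  }
  structure(list(parameter_id = parameter_id, low = low, high = high,
                 steps = steps),
            class = "sensitivity_axis")
}

axis_values <- function(axis, params) {
  lo <- axis$low
  hi <- axis$high
  if (is.null(lo) || is.null(hi)) {
    cur <- current_value(params, axis$parameter_id)
    if (is.null(lo)) lo <- 0.5 * cur
    if (is.null(hi)) hi <- 1.5 * cur
    if (startsWith(axis$parameter_id, "probabilities") ||
        startsWith(axis$parameter_id, "mix") ||
        startsWith(axis$parameter_id, "utilities")) {
      hi <- min(hi, 1)
    }
  }
  if (axis$steps == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = axis$steps)
}

#' Two-way sensitivity analysis
#'
#' Re-evaluates the cost-effectiveness comparison on a grid of joint values
#' of two parameters. Analytic mode rolls back the decision tree exactly at
#' every cell (deterministic); Monte Carlo mode simulates each cell with a
#' fixed per-cell sub-seed derived from the master seed.
#'
#' @param params A fully specified `model_parameters` object.
#' @param axis_a,axis_b [sensitivity_axis()] objects over distinct parameters.
#' @param evaluation `"analytic"` (default) or `"monte_carlo"`.
#' @param n Trials per cell and strategy in Monte Carlo mode.
#' @param seed Master seed for Monte Carlo mode.
#' @return An object of class `sensitivity_grid`; its `$grid` is a
#'   long-format data.frame with columns `axis_a_value`, `axis_b_value`,
#'   `cer_dapt`, `cer_tapt`, `preferred`.
#' @export
two_way_sensitivity <- function(params, axis_a, axis_b,
                                evaluation = c("analytic", "monte_carlo"),
                                n = params$n_trials, seed = params$seed) {
  evaluation <- match.arg(evaluation)
  stopifnot(inherits(axis_a, "sensitivity_axis"),
            inherits(axis_b, "sensitivity_axis"))
  if (identical(axis_a$parameter_id, axis_b$parameter_id)) {
    stop("the two axes must vary distinct parameters", call. = FALSE)
  }
  require_fully_specified(params)
  va <- axis_values(axis_a, params)
  vb <- axis_values(axis_b, params)
  ncell <- length(va) * length(vb)
  cell_seeds <- if (evaluation == "monte_carlo") {
    derive_subseeds(seed, ncell)
  } else {
    NULL
  }
  rows <- vector("list", ncell)
  k <- 0L
  for (ia in seq_along(va)) {
    pa <- perturb(params, axis_a$parameter_id, va[ia])
    for (ib in seq_along(vb)) {
      k <- k + 1L
      pab <- perturb(pa, axis_b$parameter_id, vb[ib])
      if (evaluation == "analytic") {
        cer_d <- cost_effectiveness_ratio(expected_values(pab, "DAPT"))
        cer_t <- cost_effectiveness_ratio(expected_values(pab, "TAPT"))
      } else {
        ss <- derive_subseeds(cell_seeds[k], 2L)
        cer_d <- simulate_cohort(pab, "DAPT", n, ss[1])$summary$cer
        cer_t <- simulate_cohort(pab, "TAPT", n, ss[2])$summary$cer
      }
      rows[[k]] <- data.frame(
        axis_a_value = va[ia], axis_b_value = vb[ib],
        cer_dapt = cer_d, cer_tapt = cer_t,
        preferred = if (is.na(cer_d) || is.na(cer_t)) {
          NA_character_
        } else if (cer_d <= cer_t) "DAPT" else "TAPT"
      )
    }
  }
  structure(
    list(grid = do.call(rbind, rows),
         axis_a = axis_a, axis_b = axis_b,
         axis_a_values = va, axis_b_values = vb,
         evaluation = evaluation),
    class = "sensitivity_grid"
  )
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %s x %s (%d x %d, %s)\n",
              x$axis_a$parameter_id, x$axis_b$parameter_id,
              length(x$axis_a_values), length(x$axis_b_values),
              x$evaluation))
  cat(sprintf("  DAPT preferred in %d of %d cells\n",
              sum(x$grid$preferred == "DAPT", na.rm = TRUE), nrow(x$grid)))
  invisible(x)
}

#' @export
as.data.frame.sensitivity_grid <- function(x, ...) x$grid
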