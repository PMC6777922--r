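#' Model enumerations
#'
#' The decision tree has two pretreatment strategies, three downstream
#' interventions and four mutually exclusive 30-day outcomes. The order
#' returned here is the canonical order used by every table in the package.
#'
#' @return Character vector of labels.
#' @name enums
NULL

#' @rdname enums
#' @export
strategies <- function() c("DAPT", "TAPT")

#' @rdname enums
#' @export
interventions <- function() c("PCI", "CABG", "MEDICAL")

#' @rdname enums
#' @export
outcomes <- function() c("NO_EVENT", "BLEEDING", "VASCULAR", "DEATH")

#' @rdname enums
#' @export
utility_classes <- function() c("PROCEDURAL", "MEDICAL")

#' Utility class of an intervention
#'
#' PCI and CABG share one set of utility coefficients (procedural
#' revascularization); medical management has its own. This mapping is fixed.
#'
#' @param intervention Character vector of intervention labels.
#' @return Character vector of utility-class labels.
#' @export
#' @examples
#' utility_class(c("PCI", "CABG", "MEDICAL"))
utility_class <- function(intervention) {
  match.arg(intervention, interventions(), several.ok = TRUE)
  ifelse(intervention == "MEDICAL", "MEDICAL", "PROCEDURAL")
}

match_strategy <- function(strategy) match.arg(strategy, strategies())
match_intervention <- function(intervention) match.arg(intervention, interventions())
match_outcome <- function(outcome) match.arg(outcome, outcomes())

# Complication outcomes, i.e. everything printed in the probability tables;
# NO_EVENT is always the residual.
complication_outcomes <- function() c("BLEEDING", "VASCULAR", "DEATH")
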