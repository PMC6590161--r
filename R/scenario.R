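#' Evidence-based treatment scenario
#'
#' Bundles the trial-style parameters the threshold formulas consume:
#' baseline outcome risk without treatment, the treatment effect (as treated
#' risk or relative risk reduction), the probability of the treatment-harm
#' event, and the decision-maker's preference weight for that harm relative
#' to the disease outcome.
#'
#' Exactly one of `treated_risk` and `rrr` is required; the other is derived
#' from \eqn{RRR = (M - M_{rx})/M}. If both are supplied they must agree to
#' within `1e-6` (useful when re-reading a serialized scenario).
#'
#' The `regime` flag records whether disease probability and outcome
#' probabilities can be treated as independent. When the morbid outcome is
#' itself part of the disease definition (e.g. recurrent venous
#' thromboembolism, where "disease" is only diagnosed once the recurrence
#' has happened), the regime is `"dependent"`: the classic
#' disease-probability threshold would double-count the outcome, and the
#' tree must instead be evaluated with the diagnosis taken as certain
#' (disease probability forced to 1). See [regime_check()] and
#' [scenario_threshold()].
#'
#' @param baseline_risk Probability `M` of the disease outcome without
#'   treatment, in \[0, 1\].
#' @param treated_risk Probability `M_rx` of the outcome on treatment, in
#'   \[0, 1\]. Supply this or `rrr`.
#' @param rrr Relative risk reduction, in \[0, 1\].
#' @param harm_rx Probability `H_rx` of the treatment-harm event, in \[0, 1\].
#' @param rv_harm Relative value `RV_H` of the harm outcome versus the
#'   disease outcome, positive; 1 means equally bad (the default).
#' @param disease_prob Optional probability `P` of disease, in \[0, 1\]. Under
#'   the dependent regime it is forced to 1 whenever the tree is evaluated.
#' @param regime `"independent"` (classic model applies) or `"dependent"`
#'   (outcome defines disease; only the outcome-risk threshold is valid).
#' @return An object of class `ebm_scenario`.
#' @examples
#' # EINSTEIN extension trial, rivaroxaban vs placebo for recurrent VTE
#' s <- ebm_scenario(baseline_risk = 42 / 594, treated_risk = 8 / 602,
#'                   harm_rx = 0.048, regime = "dependent")
#' s$rrr  # 0.812
#' @export
ebm_scenario <- function(baseline_risk, treated_risk = NULL, rrr = NULL,
                         harm_rx, rv_harm = 1, disease_prob = NULL,
                         regime = c("independent", "dependent")) {
  regime <- match.arg(regime)
  assert_probability(baseline_risk)
  assert_probability(harm_rx)
  if (!is.numeric(rv_harm) || length(rv_harm) != 1L || is.na(rv_harm) ||
      rv_harm <= 0)
    stop("rv_harm must be a single positive number", call. = FALSE)
  if (!is.null(disease_prob)) assert_probability(disease_prob)
  if (is.null(treated_risk) && is.null(rrr))
    stop("supply treated_risk or rrr", call. = FALSE)

  if (!is.null(treated_risk)) {
    assert_probability(treated_risk)
    if (baseline_risk == 0 && treated_risk > 0)
      stop("treated_risk > 0 with baseline_risk = 0 has no defined RRR",
           call. = FALSE)
    rrr_derived <- if (baseline_risk == 0) 0 else
      (baseline_risk - treated_risk) / baseline_risk
    if (!is.null(rrr) && abs(rrr - rrr_derived) > 1e-6)
      stop("treated_risk and rrr are inconsistent: (M - M_rx)/M = ",
           signif(rrr_derived, 8), " but rrr = ", signif(rrr, 8), call. = FALSE)
    rrr <- rrr_derived
  } else {
    if (!is.numeric(rrr) || length(rrr) != 1L || is.na(rrr) ||
        rrr < 0 || rrr > 1)
      stop("rrr must be a single number in [0, 1]", call. = FALSE)
    treated_risk <- baseline_risk * (1 - rrr)
  }

  structure(
    list(baseline_risk = baseline_risk, treated_risk = treated_risk,
         rrr = rrr, harm_rx = harm_rx, rv_harm = rv_harm,
         disease_prob = disease_prob, regime = regime),
    class = "ebm_scenario")
}

#' @export
print.ebm_scenario <- function(x, ...) {
  cat("Evidence-based treatment scenario (", x$regime, " regime)\n", sep = "")
  cat(sprintf("  baseline outcome risk M      = %s\n", format_percent(x$baseline_risk, 1)))
  cat(sprintf("  treated outcome risk  M_rx   = %s\n", format_percent(x$treated_risk, 1)))
  cat(sprintf("  relative risk reduction RRR  = %s\n", format_percent(x$rrr, 1)))
  cat(sprintf("  treatment harm risk   H_rx   = %s\n", format_percent(x$harm_rx, 1)))
  cat(sprintf("  harm preference weight RV_H  = %.3g\n", x$rv_harm))
  if (!is.null(x$disease_prob))
    cat(sprintf("  disease probability   P      = %s\n", format_percent(x$disease_prob, 1)))
  invisible(x)
}

#' Classify a scenario as independent or dependent regime
#'
#' The classic threshold model assumes the probability of disease and the
#' utilities attached to its outcomes are independent. When the morbid event
#' both defines the disease and drives the utilities (secondary prophylaxis,
#' recurrence prevention, diagnoses established by detecting the event), the
#' assumption fails and evaluating the classic disease-probability threshold
#' would count the same event twice. This helper sets the scenario's regime
#' from that structural question.
#'
#' @param s An [ebm_scenario()].
#' @param outcome_defines_disease Logical: is the outcome used to define
#'   disease/diagnosis (e.g. recurrent VTE), rather than an independent
#'   consequence of it (e.g. death after a pathology-confirmed cancer)?
#' @return The scenario with its `regime` field set accordingly.
#' @seealso [scenario_threshold()], which enforces the regime guard.
#' @export
regime_check <- function(s, outcome_defines_disease) {
  stopifnot(inherits(s, "ebm_scenario"),
            is.logical(outcome_defines_disease),
            length(outcome_defines_disease) == 1L,
            !is.na(outcome_defines_disease))
  s$regime <- if (outcome_defines_disease) "dependent" else "independent"
  s
}

#' Compute the threshold appropriate to a scenario's regime
#'
#' Dispatches to [ebm_probability_threshold()] or [outcome_threshold()] and
#' enforces the double-counting guard: a disease-probability threshold is
#' refused for a dependent-regime scenario (where outcome and disease
#' definitions coincide) with an error directing the caller to the
#' outcome-risk threshold. An outcome-risk threshold is always permitted;
#' under the dependent regime it corresponds to evaluating the tree with the
#' disease probability set to 1.
#'
#' @param s An [ebm_scenario()].
#' @param kind `"outcome_risk"` or `"disease_probability"`.
#' @return A [threshold_result()].
#' @examples
#' s <- ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048,
#'                   regime = "dependent")
#' scenario_threshold(s, "outcome_risk")  # 5.9%
#' @export
scenario_threshold <- function(s, kind = c("outcome_risk", "disease_probability")) {
  stopifnot(inherits(s, "ebm_scenario"))
  kind <- match.arg(kind)
  if (kind == "disease_probability") {
    if (s$regime == "dependent")
      stop("double counting: the outcome defines the disease in this ",
           "scenario, so a disease-probability threshold is invalid; ",
           "use the outcome-risk threshold (kind = \"outcome_risk\") instead",
           call. = FALSE)
    ebm_probability_threshold(s$rv_harm, s$harm_rx, s$rrr, s$baseline_risk)
  } else {
    outcome_threshold(s$rv_harm, s$harm_rx, s$rrr)
  }
}
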