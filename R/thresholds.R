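#' Threshold result container
#'
#' Internal constructor shared by the threshold functions. A threshold may
#' legitimately exceed 1 (no attainable probability or risk justifies
#' treatment); such values are reported as-is with `never_treat = TRUE`
#' rather than clamped, because implausibly high thresholds are a
#' substantive finding, not an error.
#'
#' @param kind `"disease_probability"` or `"outcome_risk"`.
#' @param value The threshold, a nonnegative number (possibly > 1 or `Inf`).
#' @param inputs Named list echoing the parameters used.
#' @param note Optional diagnostic message for degenerate inputs.
#' @return An object of class `threshold_result` with fields `kind`,
#'   `value`, `valid` (value defined and at most 1), `never_treat`,
#'   `inputs`, `note`.
#' @keywords internal
threshold_result <- function(kind = c("disease_probability", "outcome_risk"),
                             value, inputs = list(), note = NULL) {
  kind <- match.arg(kind)
  defined <- is.finite(value)
  valid <- defined && value <= 1
  structure(
    list(kind = kind, value = value, valid = valid,
         never_treat = !valid, inputs = inputs, note = note),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, digits = if (x$kind == "outcome_risk") 1 else 0, ...) {
  label <- if (x$kind == "disease_probability")
    "Disease-probability threshold Pt" else "Outcome-risk threshold Mt"
  if (x$never_treat) {
    cat(label, ": never treat",
        if (is.finite(x$value)) sprintf(" (value %.4g exceeds 1)", x$value),
        "\n", sep = "")
  } else {
    cat(sprintf("%s = %s (treat above, withhold below)\n",
                label, format_percent(x$value, digits)))
  }
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Classic threshold probability from generic net benefit and harm
#'
#' The threshold probability of disease at which the expected utilities of
#' treating and not treating are equal:
#' \deqn{P_t = \frac{1}{1 + B/H} = \frac{H}{B + H},}
#' where \eqn{B = U_1 - U_3} is the net benefit of treating the diseased and
#' \eqn{H = U_4 - U_2} the net harm of treating the disease-free. Treat when
#' the estimated probability of disease exceeds \eqn{P_t}. The ratio form
#' makes the threshold scale-invariant: only \eqn{B/H} matters, not the
#' utility units.
#'
#' @param b Net benefit, nonnegative. A negative value (treatment worse even
#'   for the diseased) yields a `never_treat` result.
#' @param h Net harm, strictly positive. With no net harm there is no
#'   threshold: treatment is favoured at any disease probability, and an
#'   error says so.
#' @return A [threshold_result()] of kind `"disease_probability"`.
#' @examples
#' classic_threshold(b = 0.4, h = 0.1)   # Pt = 0.2
#' classic_threshold(b = 0.1, h = 0.1)   # Pt = 0.5
#' @export
classic_threshold <- function(b, h) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(h), length(h) == 1L, is.finite(h))
  if (h <= 0)
    stop("net harm must be positive: with H <= 0 treatment is favoured at ",
         "any disease probability and no threshold exists", call. = FALSE)
  inputs <- list(b = b, h = h)
  if (b < 0) {
    value <- if (b + h > 0) h / (b + h) else Inf
    return(threshold_result("disease_probability", value, inputs,
                            note = "net benefit is negative: treatment harms even the diseased"))
  }
  threshold_result("disease_probability", h / (b + h), inputs)
}

#' Evidence-based threshold probability of disease
#'
#' The classic threshold probability re-expressed in the effect measures
#' reported by trials, with an explicit preference weight:
#' \deqn{P_t = \frac{RV_H \cdot H_{rx}}{RRR \cdot M}.}
#' Valid only when disease probability and outcome probabilities are
#' independent (see [regime_check()]). A value above 1 means no disease
#' probability can justify treatment and is flagged `never_treat`.
#'
#' @param rv_harm Preference weight \eqn{RV_H} for the harm outcome relative
#'   to the disease outcome, positive.
#' @param harm_rx Probability of the treatment-harm event, in \[0, 1\].
#' @param rrr Relative risk reduction, in (0, 1\].
#' @param baseline_risk Baseline outcome risk `M`, in (0, 1\].
#' @return A [threshold_result()] of kind `"disease_probability"`.
#' @examples
#' # rivaroxaban for VTE: Pt = 1 * 0.048 / (0.812 * 0.071) = 83%
#' ebm_probability_threshold(1, 0.048, 0.812, 0.071)
#' @export
ebm_probability_threshold <- function(rv_harm, harm_rx, rrr, baseline_risk) {
  stopifnot(is.numeric(rv_harm), length(rv_harm) == 1L, rv_harm > 0)
  assert_probability(harm_rx)
  stopifnot(is.numeric(rrr), length(rrr) == 1L, is.finite(rrr), rrr >= 0)
  stopifnot(is.numeric(baseline_risk), length(baseline_risk) == 1L,
            is.finite(baseline_risk), baseline_risk >= 0, baseline_risk <= 1)
  inputs <- list(rv_harm = rv_harm, harm_rx = harm_rx, rrr = rrr,
                 baseline_risk = baseline_risk)
  if (rrr * baseline_risk == 0) {
    note <- if (rrr == 0)
      "RRR = 0: treatment does not affect the underlying risk" else
      "baseline risk = 0: there is no outcome risk to avert"
    return(threshold_result("disease_probability", Inf, inputs, note = note))
  }
  threshold_result("disease_probability",
                   rv_harm * harm_rx / (rrr * baseline_risk), inputs)
}

#' Outcome-risk threshold when the outcome defines the disease
#'
#' When the morbid outcome is part of the disease definition the classic
#' model double-counts it; setting the disease probability to 1 (diagnosis
#' certain) and solving the tree instead yields a threshold on the baseline
#' outcome risk:
#' \deqn{M_t = \frac{RV_H \cdot H_{rx}}{RRR}.}
#' Treat when the baseline outcome risk without treatment exceeds
#' \eqn{M_t}. With equal valuation (`rv_harm = 1`) this reduces to
#' \eqn{M_t = H_{rx}/RRR}. The threshold never depends on the baseline risk
#' or disease probability, and \eqn{M_t \le P_t} always (they differ by the
#' factor `baseline_risk`).
#'
#' @inheritParams ebm_probability_threshold
#' @return A [threshold_result()] of kind `"outcome_risk"`.
#' @examples
#' outcome_threshold(1, 0.048, 0.812)     # 5.9%
#' outcome_threshold(0.75, 0.048, 0.812)  # 4.4%
#' @export
outcome_threshold <- function(rv_harm, harm_rx, rrr) {
  stopifnot(is.numeric(rv_harm), length(rv_harm) == 1L, rv_harm > 0)
  assert_probability(harm_rx)
  stopifnot(is.numeric(rrr), length(rrr) == 1L, is.finite(rrr), rrr >= 0)
  inputs <- list(rv_harm = rv_harm, harm_rx = harm_rx, rrr = rrr)
  if (rrr == 0)
    return(threshold_result("outcome_risk", Inf, inputs,
                            note = "RRR = 0: treatment does not affect the underlying risk"))
  threshold_result("outcome_risk", rv_harm * harm_rx / rrr, inputs)
}

#' Threshold probability from NNT and NNH
#'
#' The evidence-based threshold in the metrics clinicians quote:
#' \eqn{P_t = RV_H \cdot NNT / NNH}, where NNT is the number needed to treat
#' at the baseline risk (\eqn{1/(M \cdot RRR)}) and NNH the number needed to
#' harm (\eqn{1/H_{rx}}). Algebraically identical to
#' [ebm_probability_threshold()]; the preference weighting (default 1)
#' extends the published NNT/NNH form consistently with it.
#'
#' @param nnt Number needed to treat, positive.
#' @param nnh Number needed to harm, positive.
#' @param rv_harm Preference weight for the harm outcome, positive; default 1.
#' @return A [threshold_result()] of kind `"disease_probability"`.
#' @examples
#' nnt_nnh_threshold(nnt = 17.35, nnh = 20.83)  # ~0.83
#' @export
nnt_nnh_threshold <- function(nnt, nnh, rv_harm = 1) {
  if (!is.numeric(nnt) || length(nnt) != 1L || !is.finite(nnt) || nnt <= 0)
    stop("nnt must be a single positive number", call. = FALSE)
  if (!is.numeric(nnh) || length(nnh) != 1L || !is.finite(nnh) || nnh <= 0)
    stop("nnh must be a single positive number", call. = FALSE)
  stopifnot(is.numeric(rv_harm), length(rv_harm) == 1L, rv_harm > 0)
  threshold_result("disease_probability", rv_harm * nnt / nnh,
                   inputs = list(nnt = nnt, nnh = nnh, rv_harm = rv_harm))
}

#' Apply the treat/no-treat decision rule
#'
#' Compares an estimated probability (or risk) with a computed threshold:
#' treat above, withhold below, indifferent at exact equality (the threshold
#' is by construction the indifference point; callers wanting a tie policy
#' apply it on top). A `never_treat` threshold always yields `"no_treat"`.
#'
#' The estimate must be of the same kind as the threshold — a disease
#' probability against a disease-probability threshold, a baseline outcome
#' risk against an outcome-risk threshold. Supplying `estimate_kind` makes
#' the check explicit; mismatches are an error, since comparing across kinds
#' is meaningless.
#'
#' @param estimate Estimated probability or risk, in \[0, 1\].
#' @param threshold A [threshold_result()].
#' @param estimate_kind Optional; `"disease_probability"` or
#'   `"outcome_risk"`. Must match `threshold$kind` when given.
#' @return `"treat"`, `"no_treat"`, or `"indifferent"`.
#' @examples
#' mt <- outcome_threshold(1, 0.048, 0.812)
#' decide(0.15, mt)    # "treat": intermediate-risk recurrence exceeds 5.9%
#' decide(0.002, mt)   # "no_treat"
#' @export
decide <- function(estimate, threshold, estimate_kind = NULL) {
  assert_probability(estimate)
  stopifnot(inherits(threshold, "threshold_result"))
  if (!is.null(estimate_kind)) {
    estimate_kind <- match.arg(estimate_kind,
                               c("disease_probability", "outcome_risk"))
    if (estimate_kind != threshold$kind)
      stop("kind mismatch: estimate is a ", estimate_kind,
           " but the threshold is of kind ", threshold$kind, call. = FALSE)
  }
  if (threshold$never_treat) return("no_treat")
  if (estimate > threshold$value) "treat"
  else if (estimate < threshold$value) "no_treat"
  else "indifferent"
}
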