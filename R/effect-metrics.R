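#' Relative risk reduction from baseline and treated risks
#'
#' \eqn{RRR = (M - M_{rx})/M}: the fraction of the baseline outcome risk
#' removed by treatment. Negative values (treatment increases risk) are
#' permitted but flagged with a warning.
#'
#' @param m Baseline risk, in (0, 1\].
#' @param m_rx Treated risk, in \[0, 1\].
#' @return The relative risk reduction.
#' @examples
#' rrr_from_risks(42 / 594, 8 / 602)  # 0.812
#' @export
rrr_from_risks <- function(m, m_rx) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m <= 1,
            is.numeric(m_rx), length(m_rx) == 1L, is.finite(m_rx),
            m_rx >= 0, m_rx <= 1)
  if (m <= 0)
    stop("baseline risk must be positive to define a relative reduction",
         call. = FALSE)
  rrr <- (m - m_rx) / m
  if (rrr < 0)
    warning("treated risk exceeds baseline risk: treatment is harmful (RRR = ",
            signif(rrr, 4), ")", call. = FALSE)
  rrr
}

#' Residual risk after applying a relative risk reduction
#'
#' \eqn{p (1 - RRR)}: with `rrr = 1` the outcome is completely prevented;
#' with `rrr = 0` treatment does not affect the underlying risk. Relative
#' effects are assumed constant over the baseline-risk range, the usual
#' modelling convention for trial effect estimates.
#'
#' @param p Risk without treatment, in \[0, 1\].
#' @param rrr Relative risk reduction, at most 1; negative values (harmful
#'   treatment) are allowed as long as the residual risk stays at most 1.
#' @return The residual risk \eqn{p(1 - rrr)}.
#' @examples
#' apply_rrr(0.071, 0.812)  # ~0.013
#' @export
apply_rrr <- function(p, rrr) {
  assert_probability(p)
  stopifnot(is.numeric(rrr), length(rrr) == 1L, is.finite(rrr), rrr <= 1)
  out <- p * (1 - rrr)
  if (out > 1)
    stop("residual risk ", signif(out, 4), " exceeds 1 (rrr = ",
         signif(rrr, 4), " too harmful at p = ", signif(p, 4), ")",
         call. = FALSE)
  out
}

#' Absolute risk reduction
#'
#' \eqn{ARR = M - M_{rx}}. Besides the exact difference, a `"paper"`
#' rounding mode is offered in which both risks are first rounded to one
#' decimal of a percent before subtracting — the convention used when
#' reporting ARR from already-rounded published percentages (7.1% − 1.3% =
#' 5.8%, whereas the exact difference of the underlying counts is 5.74%).
#'
#' @param m Baseline risk, in \[0, 1\].
#' @param m_rx Treated risk, in \[0, 1\].
#' @param mode `"exact"` (default) or `"paper"` (operands rounded to one
#'   decimal of a percent first).
#' @return The absolute risk reduction, as a proportion.
#' @examples
#' arr_from_risks(42 / 594, 8 / 602)                  # 0.0574
#' arr_from_risks(42 / 594, 8 / 602, mode = "paper")  # 0.058
#' @export
arr_from_risks <- function(m, m_rx, mode = c("exact", "paper")) {
  assert_probability(m)
  assert_probability(m_rx)
  mode <- match.arg(mode)
  if (mode == "paper")
    (round(m * 100, 1) - round(m_rx * 100, 1)) / 100
  else
    m - m_rx
}

#' Number needed to treat / number needed to harm
#'
#' Reciprocal frequencies: `nnt(arr)` is the number of patients who must be
#' treated for one to benefit; `nnh(harm_rx)` the number treated for one to
#' be harmed. At baseline risk `m` with relative reduction `rrr`,
#' `nnt` equals \eqn{1/(m \cdot rrr)}.
#'
#' @param arr Absolute risk reduction, strictly positive.
#' @param harm_rx Probability of the treatment-harm event, strictly positive.
#' @return The reciprocal.
#' @examples
#' nnt(0.058)  # ~17.2
#' nnh(0.048)  # ~20.8
#' @export
nnt <- function(arr) {
  if (!is.numeric(arr) || length(arr) != 1L || !is.finite(arr) || arr <= 0)
    stop("no benefit: absolute risk reduction must be positive to define NNT",
         call. = FALSE)
  1 / arr
}

#' @rdname nnt
#' @export
nnh <- function(harm_rx) {
  if (!is.numeric(harm_rx) || length(harm_rx) != 1L || !is.finite(harm_rx) ||
      harm_rx <= 0)
    stop("no harm: harm probability must be positive to define NNH",
         call. = FALSE)
  1 / harm_rx
}

#' Preference weight from a times-worse trade ratio
#'
#' Converts the intuitive elicitation "the disease outcome is k times worse
#' than the harm outcome" (equivalently, the patient would accept up to k
#' excess harm events to avoid one disease event) into the relative value
#' weight \eqn{RV_H = 1/k}. A patient rating a clot 22 times worse than a
#' bleed has \eqn{RV_H = 1/22 \approx 0.045}; equal weighting (k = 1) gives
#' \eqn{RV_H = 1}. Full precision is kept; round only for display.
#'
#' @param k Times-worse ratio of the disease outcome versus the harm
#'   outcome, strictly positive.
#' @return The preference weight `rv_harm`.
#' @examples
#' rv_from_trade_ratio(22)   # 0.0455 (prints as 0.045 at 3 dp)
#' 1 / rv_from_trade_ratio(1 / 0.75)  # inverse ratio 1.33
#' @export
rv_from_trade_ratio <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("the trade ratio must be a single positive number", call. = FALSE)
  1 / k
}

#' Risk ratio from an odds ratio at a given baseline risk
#'
#' Treatment effects are sometimes published as odds ratios; for use in the
#' threshold formulas they are converted to a risk ratio at the baseline
#' risk via \eqn{RR = OR / (1 - M + M \cdot OR)}, from which
#' \eqn{RRR = 1 - RR}. A convenience conversion: at low baseline risk OR and
#' RR nearly coincide.
#'
#' @param or Odds ratio, positive.
#' @param m Baseline risk, in (0, 1).
#' @return `rr_from_or`: the risk ratio; `rrr_from_or`: the relative risk
#'   reduction \eqn{1 - RR}.
#' @examples
#' rr_from_or(0.23, 0.071)   # ~0.245
#' rrr_from_or(0.23, 0.071)  # ~0.755
#' @export
rr_from_or <- function(or, m) {
  stopifnot(is.numeric(or), length(or) == 1L, is.finite(or), or > 0)
  assert_probability(m)
  or / (1 - m + m * or)
}

#' @rdname rr_from_or
#' @export
rrr_from_or <- function(or, m) 1 - rr_from_or(or, m)

#' Summarise treatment-effect metrics from risks
#'
#' One-row data frame of the standard effect measures derived from a pair of
#' risks and a harm probability: RRR, ARR (exact or paper-rounded mode),
#' NNT, and NNH. All entries are mutually consistent when computed in exact
#' mode from the same risk pair.
#'
#' @inheritParams arr_from_risks
#' @param harm_rx Probability of the treatment-harm event, or `NA` to omit
#'   NNH.
#' @return A data frame with columns `m`, `m_rx`, `rrr`, `arr`, `nnt`,
#'   `nnh`.
#' @examples
#' effect_summary(42 / 594, 8 / 602, harm_rx = 0.048)
#' @export
effect_summary <- function(m, m_rx, harm_rx = NA_real_,
                           mode = c("exact", "paper")) {
  mode <- match.arg(mode)
  rrr <- rrr_from_risks(m, m_rx)
  arr <- arr_from_risks(m, m_rx, mode = mode)
  data.frame(
    m = m, m_rx = m_rx, rrr = rrr, arr = arr,
    nnt = if (arr > 0) nnt(arr) else NA_real_,
    nnh = if (is.finite(harm_rx) && harm_rx > 0) nnh(harm_rx) else NA_real_)
}

#' Format a proportion as a percentage string
#'
#' Display helper: stored values are always proportions in \[0, 1\]; percent
#' appears only in formatting.
#'
#' @param x Proportion(s).
#' @param digits Decimal places of the percentage.
#' @return Character vector like `"5.9%"`.
#' @examples
#' format_percent(0.059113, 1)  # "5.9%"
#' @export
format_percent <- function(x, digits = 1) {
  paste0(formatC(round(x * 100, digits), format = "f", digits = digits), "%")
}
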