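#' Locate a threshold numerically on the decision tree
#'
#' Independent numeric oracle for the closed-form thresholds: finds the
#' value of one scenario parameter at which the expected utilities of the
#' treat and no-treat arms are equal, by bisection on the expected-utility
#' difference \eqn{EU_{Rx}(x) - EU_{NoRx}(x)}. The tree is rebuilt from the
#' evidence-based parameterization at every trial point, so the solver never
#' reuses the closed-form algebra it is meant to check.
#'
#' The disease probability used when sweeping a non-`P` parameter is the
#' scenario's `disease_prob`; under the dependent regime it is forced to 1
#' (diagnosis certain), which is how the outcome-risk threshold arises:
#' bisecting over `M` at `P = 1` recovers \eqn{M_t}, while bisecting over
#' `P` recovers \eqn{P_t}.
#'
#' Bisection is used deliberately: the expected-utility difference happens
#' to be linear in each single parameter under the additive utility
#' parameterization, but bisection stays correct if that parameterization
#' is ever swapped. Convergence is to `1e-12` on the expected-utility
#' difference within at most 200 iterations; the solve is fully
#' deterministic.
#'
#' @param s An [ebm_scenario()].
#' @param parameter Which parameter to solve over: `"P"` (disease
#'   probability), `"M"` (baseline risk), `"H_rx"`, `"RV_H"`, or `"RRR"`.
#' @param bracket Length-2 numeric interval to search; the expected-utility
#'   difference must change sign over it, otherwise the decision is uniform
#'   over the bracket and an error is raised.
#' @return The root, a single number.
#' @examples
#' s <- ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048)
#' numeric_threshold(s, "P")                       # ~0.833, matches Pt
#' s1 <- ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048,
#'                    regime = "dependent")
#' numeric_threshold(s1, "M", bracket = c(1e-9, 1))  # ~0.0591, matches Mt
#' @export
numeric_threshold <- function(s, parameter = c("P", "M", "H_rx", "RV_H", "RRR"),
                              bracket = c(0, 1)) {
  stopifnot(inherits(s, "ebm_scenario"))
  parameter <- match.arg(parameter)
  stopifnot(is.numeric(bracket), length(bracket) == 2L,
            all(is.finite(bracket)), bracket[1] < bracket[2])

  f <- function(x) eu_difference(s, parameter, x)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop("no threshold in [", lo, ", ", hi, "]: the treat/no-treat ",
         "preference does not change over the bracket for parameter ",
         parameter, call. = FALSE)
  mid <- (lo + hi) / 2
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    # converge the bracket itself, not just the EU difference: a shallow
    # EU slope would otherwise stop far from the indifference point
    if (fmid == 0 || (abs(fmid) < 1e-12 && (hi - lo) < 1e-13)) return(mid)
    if (sign(fmid) == sign(flo)) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid
    }
  }
  mid
}

# EU_Rx - EU_NoRx with one scenario parameter replaced by x; the disease
# probability is the replaced value (parameter "P"), 1 under the dependent
# regime, or the scenario's disease_prob otherwise.
eu_difference <- function(s, parameter, x) {
  p <- NULL
  switch(parameter,
         P = { p <- x },
         M = { s$baseline_risk <- x },
         H_rx = { s$harm_rx <- x },
         RV_H = { s$rv_harm <- x },
         RRR = { s$rrr <- x })
  if (is.null(p)) {
    p <- if (s$regime == "dependent") 1
         else if (!is.null(s$disease_prob)) s$disease_prob
         else stop("scenario has no disease probability: set disease_prob ",
                   "or use the dependent regime (P = 1) when solving over ",
                   parameter, call. = FALSE)
  }
  u <- utilities_from_ebm(s)
  expected_utility_treat(p, u) - expected_utility_notreat(p, u)
}
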