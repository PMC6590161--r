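#' Terminal utilities of the treat/no-treat decision tree
#'
#' Constructs the four terminal utilities of the two-branch decision tree
#' underlying the threshold model: treat vs. no-treat crossed with disease
#' present vs. absent. Utilities are on a 0--1 scale where 1 is perfect
#' health, so disutilities (morbid outcomes, treatment harms) subtract from 1.
#'
#' The derived quantities net benefit \eqn{B = U_1 - U_3} (how much better
#' off a diseased patient is when treated) and net harm \eqn{H = U_4 - U_2}
#' (how much worse off a disease-free patient is when treated) drive the
#' classic threshold probability; see [classic_threshold()].
#'
#' @param u_treat_disease Utility \eqn{U_1} of treating a diseased patient,
#'   in \[0, 1\].
#' @param u_treat_nodisease Utility \eqn{U_2} of treating a disease-free
#'   patient, in \[0, 1\].
#' @param u_notreat_disease Utility \eqn{U_3} of not treating a diseased
#'   patient, in \[0, 1\].
#' @param u_notreat_nodisease Utility \eqn{U_4} of not treating a
#'   disease-free patient, in \[0, 1\].
#' @return An object of class `utility_quadruple`.
#' @examples
#' u <- utility_quadruple(0.8, 0.9, 0.4, 1.0)
#' net_benefit(u)  # 0.4
#' net_harm(u)     # 0.1
#' @export
utility_quadruple <- function(u_treat_disease, u_treat_nodisease,
                              u_notreat_disease, u_notreat_nodisease) {
  u <- c(u_treat_disease, u_treat_nodisease,
         u_notreat_disease, u_notreat_nodisease)
  if (length(u) != 4L || !is.numeric(u) || anyNA(u) || any(!is.finite(u)))
    stop("all four utilities must be finite numeric scalars", call. = FALSE)
  if (any(u < 0) || any(u > 1))
    stop("utilities must lie in [0, 1] (1 = perfect health); got (",
         paste(signif(u, 6), collapse = ", "), ")", call. = FALSE)
  structure(
    list(u_treat_disease = u[[1]], u_treat_nodisease = u[[2]],
         u_notreat_disease = u[[3]], u_notreat_nodisease = u[[4]]),
    class = "utility_quadruple")
}

#' @export
print.utility_quadruple <- function(x, ...) {
  cat("Decision-tree terminal utilities (1 = perfect health)\n")
  cat(sprintf("  U1 treat,    disease: %.6g\n", x$u_treat_disease))
  cat(sprintf("  U2 treat,    no disease: %.6g\n", x$u_treat_nodisease))
  cat(sprintf("  U3 no treat, disease: %.6g\n", x$u_notreat_disease))
  cat(sprintf("  U4 no treat, no disease: %.6g\n", x$u_notreat_nodisease))
  cat(sprintf("  net benefit B = U1 - U3 = %.6g; net harm H = U4 - U2 = %.6g\n",
              net_benefit(x), net_harm(x)))
  invisible(x)
}

assert_probability <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(name, " must be a single probability in [0, 1], got ",
         deparse(p), call. = FALSE)
  invisible(p)
}

#' Expected utility of the treat and no-treat arms
#'
#' Expected utility at disease probability `p`:
#' \eqn{EU_{Rx} = p U_1 + (1-p) U_2} for the treat arm and
#' \eqn{EU_{NoRx} = p U_3 + (1-p) U_4} for the no-treat arm. The threshold
#' probability is where the two cross.
#'
#' @param p Probability of disease, in \[0, 1\].
#' @param u A [utility_quadruple()].
#' @return Expected utility, a number between the two terminal utilities of
#'   the arm.
#' @examples
#' u <- utility_quadruple(0.8, 0.9, 0.4, 1.0)
#' expected_utility_treat(0.5, u)    # 0.85
#' expected_utility_notreat(0.5, u)  # 0.70
#' @export
expected_utility_treat <- function(p, u) {
  assert_probability(p)
  stopifnot(inherits(u, "utility_quadruple"))
  p * u$u_treat_disease + (1 - p) * u$u_treat_nodisease
}

#' @rdname expected_utility_treat
#' @export
expected_utility_notreat <- function(p, u) {
  assert_probability(p)
  stopifnot(inherits(u, "utility_quadruple"))
  p * u$u_notreat_disease + (1 - p) * u$u_notreat_nodisease
}

#' Net benefit and net harm of treatment
#'
#' Net benefit \eqn{B = U_1 - U_3}: the utility gain from treating a patient
#' who has the disease. Net harm \eqn{H = U_4 - U_2}: the utility loss from
#' treating a patient who does not.
#'
#' @param u A [utility_quadruple()].
#' @return A single number.
#' @export
net_benefit <- function(u) {
  stopifnot(inherits(u, "utility_quadruple"))
  u$u_treat_disease - u$u_notreat_disease
}

#' @rdname net_benefit
#' @export
net_harm <- function(u) {
  stopifnot(inherits(u, "utility_quadruple"))
  u$u_notreat_nodisease - u$u_treat_nodisease
}

#' Map an evidence-based scenario onto decision-tree utilities
#'
#' Translates trial-style effect parameters into the four terminal utilities
#' of the decision tree, using additive unit disutilities: the disease
#' outcome costs one unit of utility scaled by its probability, and the
#' treatment-harm event costs `rv_harm` units scaled by its probability
#' `harm_rx`. This yields
#' \deqn{U_1 = 1 - (1 - RRR)\,M - RV_H H_{rx},\quad
#'       U_2 = 1 - RV_H H_{rx},\quad U_3 = 1 - M,\quad U_4 = 1.}
#' With these utilities the classic threshold \eqn{1/(1 + B/H)} reduces
#' exactly to the evidence-based form \eqn{RV_H H_{rx} / (RRR \cdot M)}.
#'
#' Parameter combinations that would push a terminal utility below 0 (e.g.
#' `rv_harm * harm_rx > 1`) are rejected with an error rather than clamped:
#' clamping would silently break the algebraic identity between the generic
#' and evidence-based threshold forms.
#'
#' @param s An [ebm_scenario()].
#' @return A [utility_quadruple()].
#' @examples
#' s <- ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048)
#' utilities_from_ebm(s)
#' @export
utilities_from_ebm <- function(s) {
  stopifnot(inherits(s, "ebm_scenario"))
  harm_cost <- s$rv_harm * s$harm_rx
  u1 <- 1 - (1 - s$rrr) * s$baseline_risk - harm_cost
  u2 <- 1 - harm_cost
  u3 <- 1 - s$baseline_risk
  u4 <- 1
  if (u1 < 0 || u2 < 0)
    stop("scenario yields negative terminal utility (rv_harm * harm_rx = ",
         signif(harm_cost, 6), ", residual disease risk = ",
         signif((1 - s$rrr) * s$baseline_risk, 6),
         "): combined disutility exceeds the 0-1 utility scale", call. = FALSE)
  utility_quadruple(u1, u2, u3, u4)
}

#' Monte Carlo expected utility on the decision tree
#'
#' Stochastic check of the closed-form expected utilities: simulates `n`
#' patients who are diseased with probability `p`; diseased patients suffer
#' the outcome with probability `baseline_risk` (no-treat arm) or
#' `baseline_risk * (1 - rrr)` (treat arm); patients in the treat arm
#' additionally suffer the harm event with probability `harm_rx`,
#' independently. Each outcome event costs 1 unit of utility and each harm
#' event costs `rv_harm` units, so the simulated mean converges to the
#' closed-form expected utility of the corresponding arm.
#'
#' The RNG seed is mandatory and applied locally (via [withr::with_seed()]);
#' the caller's RNG state is untouched.
#'
#' @param s An [ebm_scenario()].
#' @param arm `"treat"` or `"notreat"`.
#' @param p Probability of disease.
#' @param n Number of simulated patients.
#' @param seed Integer RNG seed.
#' @return An object of class `mc_estimate` with fields `mean_utility`,
#'   `std_error`, `n_draws`, `seed`.
#' @examples
#' s <- ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048)
#' mc_expected_utility(s, "treat", p = 1, n = 1e4, seed = 42)
#' @export
mc_expected_utility <- function(s, arm = c("treat", "notreat"), p, n, seed) {
  stopifnot(inherits(s, "ebm_scenario"))
  arm <- match.arg(arm)
  assert_probability(p)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    stop("n must be a positive integer", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an explicit integer seed is required", call. = FALSE)
  n <- as.integer(n)
  draws <- withr::with_seed(seed, {
    diseased <- stats::rbinom(n, 1L, p)
    outcome_p <- if (arm == "treat") s$baseline_risk * (1 - s$rrr) else s$baseline_risk
    outcome <- stats::rbinom(n, 1L, outcome_p) * diseased
    harm <- if (arm == "treat") stats::rbinom(n, 1L, s$harm_rx) else 0L
    1 - outcome - s$rv_harm * harm
  })
  m <- mean(draws)
  se <- stats::sd(draws) / sqrt(n)
  structure(list(mean_utility = m, std_error = se, n_draws = n, seed = seed),
            class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo expected utility: %.6f (SE %.2g, n = %d, seed = %s)\n",
              x$mean_utility, x$std_error, x$n_draws, format(x$seed)))
  invisible(x)
}
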