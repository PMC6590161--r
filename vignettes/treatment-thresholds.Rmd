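---
title: "Treatment thresholds: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment thresholds: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatthresh)
```

## The decision problem

A clinician (or patient) must choose between treating and not treating when
the presence of disease, or the occurrence of a morbid outcome, is
uncertain. The threshold model answers: at what probability does treatment
become the rational choice? Above the threshold, treat; below it, don't;
at it, the two options have equal expected utility.

The model is a two-branch decision tree. Each arm (treat `Rx`, no-treat
`NoRx`) splits on disease status with probability $p$, giving four terminal
utilities on a 0–1 scale (1 = perfect health):

* $U_1$: treat, diseased; $U_2$: treat, disease-free;
* $U_3$: no treat, diseased; $U_4$: no treat, disease-free.

Expected utilities are linear in $p$:

$$EU_{Rx} = p\,U_1 + (1-p)\,U_2, \qquad EU_{NoRx} = p\,U_3 + (1-p)\,U_4.$$

With net benefit $B = U_1 - U_3$ (gain from treating the diseased) and net
harm $H = U_4 - U_2$ (loss from treating the disease-free), the
indifference point is the classic threshold probability

$$P_t = \frac{1}{1 + B/H} = \frac{H}{B + H}.$$

Only the ratio $B/H$ matters — the threshold is invariant to rescaling the
utility units — which `classic_threshold()` implements and the test suite
asserts.

## Evidence-based parameterization

Trials do not report $U_1,\dots,U_4$; they report a baseline outcome risk
$M$, a treated risk $M_{rx}$ (equivalently a relative risk reduction
$RRR = (M - M_{rx})/M$), and a treatment-harm probability $H_{rx}$. We add
an explicit preference weight $RV_H > 0$: how bad the decision-maker
considers the harm outcome relative to the disease outcome (1 = equally
bad; `rv_from_trade_ratio(k)` converts from the elicitation "the disease
outcome is $k$ times worse").

`utilities_from_ebm()` maps these onto the tree with *additive unit
disutilities*: the disease outcome costs 1 unit of utility weighted by its
probability, the harm event costs $RV_H$ units weighted by $H_{rx}$:

$$U_1 = 1 - (1 - RRR)M - RV_H H_{rx}, \quad U_2 = 1 - RV_H H_{rx}, \quad
  U_3 = 1 - M, \quad U_4 = 1.$$

Substituting into the generic threshold gives $B = M \cdot RRR - RV_H
H_{rx}$, $H = RV_H H_{rx}$, and hence the closed form

$$P_t = \frac{RV_H \, H_{rx}}{RRR \cdot M}.$$

The additive form is a design choice: disutility combination inside the
tree could in principle be multiplicative, but the additive mapping is the
unique one under which the generic ratio form and the effect-measure form
coincide *exactly*, and that identity is enforced as a property test (1,000
generated scenarios, agreement to $10^{-12}$). For the same reason,
parameter combinations that would push a terminal utility below zero are
rejected with an error rather than clamped — clamping would silently break
the identity.

## Two thresholds, and why double counting matters

The classic $P_t$ presumes the probability of disease and the utilities are
independent: the utilities do not move when $p$ does. That fails for a
large class of problems — secondary prophylaxis and recurrence prevention —
where the morbid event *is* the disease definition (a recurrent venous
thromboembolism is only diagnosed once the recurrence happens). Using the
same event in the probability branch and in the utilities counts it twice.

The consistent way out is to treat the diagnosis — the predisposition to
the event — as certain, set $p = 1$, and solve the tree for the baseline
outcome risk at which treating and not treating break even:

$$M_t = \frac{RV_H \, H_{rx}}{RRR}.$$

Treat when the predicted outcome risk without treatment exceeds $M_t$.
Since $M_t = P_t \cdot M$ and $M \le 1$, always $M_t \le P_t$ — the
outcome-risk threshold is never more demanding than the (inapplicable)
probability threshold, which helps explain why observed practice sits below
the classic model's prescriptions.

In code, the distinction is a regime flag on the scenario. `regime_check()`
sets it from the structural question ("does the outcome define the
disease?"), and `scenario_threshold()` refuses to compute a
disease-probability threshold for a dependent-regime scenario, with an
error pointing at the outcome-risk threshold. We made the guard an error
rather than a warning: silently returning the double-counted number is
precisely the misapplication the model distinguishes.

## Worked example

```{r example}
m <- 42 / 594    # recurrence risk on placebo, 7.1%
m_rx <- 8 / 602  # on rivaroxaban, 1.3%
effect_summary(m, m_rx, harm_rx = 0.048)

# classic threshold, only valid if disease probability were independent:
ebm_probability_threshold(1, 0.048, 0.812, 0.071)

# the applicable outcome-risk threshold (diagnosis = predisposition, P = 1):
outcome_threshold(1, 0.048, 0.812)
outcome_threshold(0.75, 0.048, 0.812)   # empirical preference weight
```

The implausible 83% against the clinically plausible 5.9% (4.4% at the
empirical preference weight $RV_H = 0.75$) is the model's central contrast.
Varying $RV_H$ from 0.045 (a patient who would accept 22 excess bleeds to
avoid one clot) to 1 spans outcome-risk thresholds from 0.3% to 5.9%, a
range that brackets guideline risk categories (3%/15%/30% for low /
intermediate / high recurrence risk).

## Parameters and units

| Parameter | Meaning | Range | Default |
|---|---|---|---|
| `baseline_risk` ($M$) | outcome risk without treatment | $[0,1]$ proportion | — |
| `treated_risk` ($M_{rx}$) or `rrr` | treated risk / relative risk reduction | $[0,1]$ | one required |
| `harm_rx` ($H_{rx}$) | probability of the treatment-harm event | $[0,1]$ | — |
| `rv_harm` ($RV_H$) | harm disutility relative to the disease outcome | $>0$ | 1 (equal) |
| `disease_prob` ($P$) | disease probability | $[0,1]$ | optional; forced to 1 under the dependent regime |

All stored values are proportions; percent appears only in display
formatting (`format_percent()`) and in configuration files that declare
`units: percent`. Two arithmetic modes exist for the absolute risk
reduction because published summaries subtract *rounded* percentages
(7.1% − 1.3% = 5.8%) while the relative reduction is computed from the raw
counts (81.2%); `arr_from_risks(..., mode = "paper")` reproduces the former,
the default `"exact"` mode the latter (5.74%). The mode never touches
stored values.

Odds-ratio effect inputs are accepted as a convenience and converted at the
baseline risk via $RR = OR/(1 - M + M \cdot OR)$ before use.

## Numerical choices

**Bisection oracle.** `numeric_threshold()` locates the indifference point
directly on the tree by bisection on $EU_{Rx}(x) - EU_{NoRx}(x)$, rebuilding
the utilities at every trial point. Under the additive parameterization the
difference is linear in each single parameter, so any bracketing method
would do; bisection was chosen because it stays correct if the utility
parameterization is ever swapped for a nonlinear one. Convergence requires
both the expected-utility difference below $10^{-12}$ *and* the bracket
below $10^{-13}$ (at most 200 iterations): with a shallow utility slope the
difference alone can be tiny far from the root. The solver is deterministic.
A bracket over which the preference never reverses is an error, not a
boundary answer.

**Thresholds above 1** are returned as computed, flagged `never_treat`, and
never clamped: a threshold of 2 means no attainable probability justifies
treatment, which is a finding. Exact equality of estimate and threshold
reports `"indifferent"`; callers wanting a tie-break apply their own
policy on top.

**Degenerate inputs.** $RRR = 0$ (treatment does not affect the risk) and
$M = 0$ (nothing to avert) produce infinite, `never_treat` thresholds with
a diagnostic note; $H = 0$ in the generic form is an error ("treat at any
probability"), since no threshold exists. $H_{rx} = 0$ in the
effect-measure forms legitimately gives a threshold of 0.

**Monte Carlo oracle.** `mc_expected_utility()` simulates patients
(disease $\sim$ Bernoulli($p$); outcome with probability $M$ or
$M(1-RRR)$; harm with probability $H_{rx}$ in the treat arm,
independently; each event subtracting its disutility), so its mean
converges to the closed-form expected utility. An explicit seed is
mandatory and applied locally — no global RNG state is touched. Tests
require agreement within 4 standard errors at $n = 2 \times 10^5$ draws and
check the $1/\sqrt{n}$ scaling of the standard error.

## What the scenario generator emulates — and what it does not

`generate_scenarios()` draws parameters uniformly over clinically plausible
ranges: baseline risk 0.001–0.5, RRR 0.05–0.99, harm risk 0–0.2, preference
weight 0.02–1.5 (spanning strongly outcome-averse to mildly harm-averse
decision-makers), regime sampled evenly; draws implying negative terminal
utilities are rejected. These ranges are wide enough to exercise the
algebraic identities, the $M_t \le P_t$ ordering, and the monotonicity of
$M_t$ (increasing in $RV_H$ and $H_{rx}$, decreasing in $RRR$) far beyond
the single worked example.

What passing these property suites does *not* show: anything about
uncertainty in the inputs. The model consumes point estimates; trial
effects come with confidence intervals, baseline risks come from prediction
models with their own error, and elicited preference weights vary within
patients over time. The package deliberately propagates none of that
(sweeps over $H_{rx}$ and $RV_H$ are the supported, transparent substitute
for probabilistic sensitivity analysis). Likewise out of scope: the
test/test–treatment two-threshold model with sensitivity and specificity —
when the diagnosis is the predisposition and is certain, test
characteristics have no role — multi-arm trees, time-dependent (Markov)
utilities, and cost units.

## Sensitivity sweeps

`sweep_outcome_threshold()` tabulates $M_t$ over a harm-risk grid, one
series per preference weight; each series is the straight line with slope
$RV_H/RRR$, so series are ordered by $RV_H$ at any fixed harm risk. The
shipped reproduction grid is $H_{rx} \in [0, 0.10]$ in steps of 0.005,
covering the observed 4.8% bleeding risk with headroom. The long-format
table (`param_name`, `param_value`, `series_label`, `threshold`,
`never_treat`) is the source of truth; `plot_sweep()` is an optional
rendering. `sweep_probability_threshold()` contrasts the generic
$1/(1+B/H)$ curve with the NNT/NNH identity line $P_t = NNT/NNH$ — the same
threshold on two metric scales. The NNT/NNH form accepts the $RV_H$ weight
(default 1), the weighting being the direct analogue of its role in the
effect-measure closed form.

## Known limitations

* Point estimates only; no uncertainty propagation.
* The additive disutility mapping is validated by its internal consistency
  (the exact Eq-(1)-to-effect-measure identity and the reproduced worked
  example), not against an external utility catalogue.
* Preference elicitation is reduced to a single scalar $RV_H$; real
  preference structures (risk attitudes, time preference) do not reduce to
  one number.
* Constant relative effects across baseline risk is an assumption inherited
  from standard trial-effect modelling; where it fails, thresholds computed
  at a distant baseline risk mislead.

## Reproducibility note

Property suites in the tests use 1,000 generated scenarios per identity and
$2 \times 10^5$ Monte Carlo draws per comparison under fixed seeds; the
whole suite runs in well under a minute on a single CPU. These sizes are
the package's chosen defaults for demonstrating the identities to the
stated tolerances, and the closed-form evaluations themselves are
instantaneous.
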