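# treatthresh

Treatment thresholds from expected-utility decision trees, for clinicians,
guideline developers and decision analysts who need to answer: *above what
probability of disease — or risk of a morbid outcome — does treatment become
the rational choice?*

## The model

A two-branch treat/no-treat decision tree with terminal utilities
U1 (treat, diseased), U2 (treat, disease-free), U3 (no treat, diseased),
U4 (no treat, disease-free) yields the classic threshold probability of
disease at which the expected utilities of the two arms cross:

    Pt = 1 / (1 + B/H) = H / (B + H),   B = U1 − U3,  H = U4 − U2.

Parameterized in the effect measures trials actually report — baseline
outcome risk `M`, relative risk reduction `RRR`, treatment-harm probability
`H_rx` — and an explicit preference weight `RV_H` (how bad the harm outcome
is relative to the disease outcome, 1 = equally bad):

    Pt = RV_H · H_rx / (RRR · M).

That formula assumes disease probability and outcome utilities are
independent. In secondary prophylaxis and recurrence prevention the morbid
outcome *defines* the disease, the independence fails (double counting),
and the valid question is instead the baseline outcome risk above which
treatment wins, obtained by taking the diagnosis (the predisposition) as
certain, P = 1:

    Mt = RV_H · H_rx / RRR,    with always  Mt ≤ Pt.

The package provides the closed forms, the NNT/NNH reformulation
(`Pt = RV_H · NNT/NNH`), effect-metric conversions (RRR/ARR/NNT/NNH, odds
ratios, preference trade ratios), a regime guard that refuses the
double-counted threshold, a deterministic bisection solver and a Monte
Carlo simulator that locate thresholds directly on the tree as independent
checks, one-way sensitivity sweeps, YAML/JSON scenario configs, and a small
CLI (`inst/cli/treatthresh.R`).

## Worked example: extended anticoagulation after venous thromboembolism

In the extension trial of rivaroxaban for secondary VTE prevention, the
recurrence risk was 42/594 = 7.1% on placebo and 8/602 = 1.3% on treatment
(RRR 81.2%); major bleeding risk on treatment was 4.8%.

```r
library(treatthresh)

effect_summary(42/594, 8/602, harm_rx = 0.048)
#>            m       m_rx       rrr        arr      nnt      nnh
#> 1 0.07070707 0.01328904 0.8120551 0.05741803 17.41613 20.83333

# Classic threshold (only valid if disease were independent of the outcome):
ebm_probability_threshold(1, 0.048, 0.812, 0.071)
#> Disease-probability threshold Pt = 83% (treat above, withhold below)

# The outcome defines the disease here, so the applicable threshold is:
outcome_threshold(1, 0.048, 0.812)
#> Outcome-risk threshold Mt = 5.9% (treat above, withhold below)

outcome_threshold(0.75, 0.048, 0.812)   # empirical preference weight
#> Outcome-risk threshold Mt = 4.4% (treat above, withhold below)

mt <- outcome_threshold(1, 0.048, 0.812)
decide(0.15, mt)   # intermediate-risk patient, 15% recurrence risk
#> [1] "treat"
```

Read: anticoagulate only patients whose predicted recurrence risk without
treatment exceeds 5.9% (4.4% once typical patient preferences — a bleed
rated three-quarters as bad as a clot — are weighted in). The implausible
83% is what the misapplied classic formula would demand, and the contrast
between the two is the model's point. Varying the preference weight from
0.045 (22 bleeds accepted per clot avoided) to 1 spans thresholds 0.3%–5.9%.

The regime guard makes the misapplication an error instead of a number:

```r
s <- ebm_scenario(baseline_risk = 42/594, treated_risk = 8/602,
                  harm_rx = 0.048, regime = "dependent")
scenario_threshold(s, "disease_probability")
#> Error: double counting: the outcome defines the disease in this scenario, ...
```

A ready-made config for this scenario ships in
`inst/extdata/einstein.yaml`:

```sh
Rscript inst/cli/treatthresh.R threshold --config inst/extdata/einstein.yaml
```

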