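# Shared fixtures: the rivaroxaban secondary-prevention scenario (EINSTEIN
# extension trial counts) and a hand-sized utility quadruple.

einstein_scenario <- function(rv_harm = 1, regime = "dependent") {
  ebm_scenario(baseline_risk = 42 / 594, treated_risk = 8 / 602,
               harm_rx = 0.048, rv_harm = rv_harm, regime = regime)
}

# Same scenario at the printed (rounded) precision used in the worked example.
einstein_rounded <- function(rv_harm = 1, regime = "dependent") {
  ebm_scenario(baseline_risk = 0.071, rrr = 0.812, harm_rx = 0.048,
               rv_harm = rv_harm, regime = regime)
}

toy_quadruple <- function() utility_quadruple(0.8, 0.9, 0.4, 1.0)
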