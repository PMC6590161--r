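# Extended anticoagulation for secondary prevention of venous
# thromboembolism (EINSTEIN extension trial, rivaroxaban vs placebo).
# Recurrence risks are the trial event proportions (42/594 placebo,
# 8/602 rivaroxaban); major-bleeding risk 4.8%. The recurrence outcome
# defines the disease, hence the dependent regime: only the outcome-risk
# threshold is meaningful.
schema_version: "1.0"
question: outcome_risk_threshold
rounding_mode: paper
scenario:
  units: proportion
  baseline_risk: 0.0707070707070707   # 42/594 = 7.1%
  treated_risk: 0.0132890365448505    # 8/602 = 1.3%
  harm_rx: 0.048
  rv_harm: 1.0
  regime: dependent
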