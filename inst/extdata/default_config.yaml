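# Default cohort-generator configuration: the observed study conditions.
seed: 1
"n": 639   # quoted: a bare n is a YAML 1.1 boolean
delay_probs: [0.07042254, 0.13145540, 0.06259781, 0.37715180, 0.09389671, 0.26447574]
subtype_probs: [0.60, 0.25, 0.15]
stage_probs: [0.10, 0.62, 0.28]
hr_by_category: [1.0, 1.18, 1.27, 1.54, 1.92, 2.35]
baseline_hazard: 0.021
system_interval_means: [23.2, 14.7, 18.5]
system_interval_shape: 4
intensity_odds: [1.0, 1.3, 1.7, 2.4, 3.1, 3.8]
complication_base: 0.15
horizon_months: 120
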