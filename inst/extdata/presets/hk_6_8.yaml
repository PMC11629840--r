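# Hong-Kong-like clinic cohort, ages 6-8 at baseline.
# Less hyperopic, longer-eyed baselines and more parental myopia than
# the UK-like preset (stated assumptions; no published distribution
# parameters exist for the validation cohorts). onset_intercept is
# calibrated so the expected myopia incidence by age 15+ is 94%.
description: Hong-Kong-like clinic cohort, 6-8 years, ~94% myopia incidence
band: age_6_8
parental_probs: [0.25, 0.45, 0.30]
ser_mean: 0.90
ser_sd: 0.55
al_mean: 23.10
al_sd: 0.70
ser_al_corr: -0.45
onset_slope: 0.9
onset_intercept: 0.1645
outcome_ser_noise_sd: 0.35
target_incidence: 0.94
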