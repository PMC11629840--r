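# UK-like population cohort, ages 6-8 at baseline.
# Baseline biometry assumed for non-myopic UK schoolchildren (no
# published distribution parameters exist for the validation cohorts;
# these are stated assumptions, not estimates of any real cohort).
# onset_intercept is calibrated so the expected myopia incidence by age
# 15+ is 58% under this baseline-score distribution.
description: UK-like population cohort, 6-8 years, ~58% myopia incidence
band: age_6_8
parental_probs: [0.45, 0.40, 0.15]
ser_mean: 1.10
ser_sd: 0.60
al_mean: 22.70
al_sd: 0.65
ser_al_corr: -0.45
onset_slope: 0.9
onset_intercept: -2.1815
outcome_ser_noise_sd: 0.35
target_incidence: 0.58
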