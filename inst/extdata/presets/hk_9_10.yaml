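# Hong-Kong-like clinic cohort, ages 9-10 at baseline (totals 0-6).
# onset_intercept is calibrated so the expected myopia incidence by age
# 15+ is 76% (57/75) under this baseline-score distribution.
description: Hong-Kong-like clinic cohort, 9-10 years, ~76% myopia incidence
band: age_9_10
parental_probs: [0.25, 0.45, 0.30]
ser_mean: 0.70
ser_sd: 0.55
al_mean: 23.40
al_sd: 0.70
ser_al_corr: -0.45
onset_slope: 0.9
onset_intercept: -0.9451
outcome_ser_noise_sd: 0.35
target_incidence: 0.76
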