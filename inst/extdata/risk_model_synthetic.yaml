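# Synthetic calibration of the Weibull proportional-hazards STR risk model.
#
# These coefficients are NOT a transcription of a published coefficient
# table; they are a calibration of the same model family chosen to
# reproduce the documented behaviour of personalised screening-interval
# models for type 2 diabetes: cumulative incidence
#   F(t|x) = 1 - exp(-exp(b'x) * t^p),  t in months,
# intervals clamped to [6, 60] months, a cohort-mean interval of about 32
# months at a 4.0% risk margin, and 6 months at a 0.0% margin, for a Dutch
# primary-care type 2 diabetes population (HbA1c ~56 mmol/mol, SBP ~143
# mmHg, short diabetes duration, mostly no retinopathy). Replace with a
# transcribed coefficient set for analyses of real data.
provenance:
  source: "synthetic calibration (see package vignette)"
  transcription_date: "2026-09-25"
  status: synthetic
shape: 1.3
coefficients:
  intercept: -23.2
  male: 0.2
  log_duration: 0.3
  log_hba1c: 2.0
  log_sbp: 1.5
  retinopathy_present: 1.2
min_interval_months: 6
max_interval_months: 60
snap_to_menu: false
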