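# Example model configuration. Omitted entries keep package defaults.
population:
  annual_referrals: 490
  high_low_ratio: 2.5
  gp_defer_prob: 0.5
scenario:
  preset: h2-modified
risk:
  treatment_hr: 0.2
  beta_abcd2: 0.35
costs:
  clinic_slot: 150
  admission_per_day: 300
  price_year: PLACEHOLDER
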