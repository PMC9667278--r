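# Default report configuration: the shipped "paper-like" synthetic pond.
# All synthetic-generator fields omitted here take the package defaults
# (10 cores of 40 cm sliced in 10-cm layers, Co-60 10-6000 Bq/kg and
# Cs-137 5-50 Bq/kg wet weight, reference date 2020-01-01).
synthetic:
  seed: 1
scenario:
  dose_ages: [0, 1, 5, 10, 15, 20]
  lar_ages: [0, 10, 20, 30, 40, 50, 60, 70, 80, 90]
  sweep_amounts_cm: [0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30]
  sweep_age: 30
  duration_years: 1
  outdoor_fraction: 1
  limit_mSv: 0.1
  limit_age: 20
  limit_sex: average
  limit_resolution_cm: 1
  limit_max_depth_cm: 100
risk:
  a_max: 110
output:
  dir: results/report
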