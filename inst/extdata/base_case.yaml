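settings:
  cycle_length: 0.25
  discount_rate: 0.03
  cohort_size: 1000.0
  psa_draws: 2000
  max_age: 110.0
  wtp: 100000.0
  wtp_grid:
  - 0.0
  - 2500.0
  - 5000.0
  - 7500.0
  - 10000.0
  - 12500.0
  - 15000.0
  - 17500.0
  - 20000.0
  - 22500.0
  - 25000.0
  - 27500.0
  - 30000.0
  - 32500.0
  - 35000.0
  - 37500.0
  - 40000.0
  - 42500.0
  - 45000.0
  - 47500.0
  - 50000.0
  - 52500.0
  - 55000.0
  - 57500.0
  - 60000.0
  - 62500.0
  - 65000.0
  - 67500.0
  - 70000.0
  - 72500.0
  - 75000.0
  - 77500.0
  - 80000.0
  - 82500.0
  - 85000.0
  - 87500.0
  - 90000.0
  - 92500.0
  - 95000.0
  - 97500.0
  - 100000.0
  - 102500.0
  - 105000.0
  - 107500.0
  - 110000.0
  - 112500.0
  - 115000.0
  - 117500.0
  - 120000.0
  - 122500.0
  - 125000.0
  - 127500.0
  - 130000.0
  - 132500.0
  - 135000.0
  - 137500.0
  - 140000.0
  - 142500.0
  - 145000.0
  - 147500.0
  - 150000.0
  - 152500.0
  - 155000.0
  - 157500.0
  - 160000.0
  - 162500.0
  - 165000.0
  - 167500.0
  - 170000.0
  - 172500.0
  - 175000.0
  - 177500.0
  - 180000.0
  - 182500.0
  - 185000.0
  - 187500.0
  - 190000.0
  - 192500.0
  - 195000.0
  - 197500.0
  - 200000.0
  seed: 1
  include_acute_qaly: yes
  half_cycle: no
  extinction_tol: 1.0e-06
parameters:
  cost_ct:
    family: beta_pert
    base: 198.0
    min: 168.0
    mode: 198.0
    max: 228.0
    low: 168.0
    high: 228.0
  cost_cta:
    family: beta_pert
    base: 774.0
    min: 658.0
    mode: 774.0
    max: 890.0
    low: 658.0
    high: 890.0
  cost_mri:
    family: beta_pert
    base: 625.0
    min: 531.0
    mode: 625.0
    max: 718.0
    low: 531.0
    high: 718.0
  cost_mra:
    family: beta_pert
    base: 1023.0
    min: 870.0
    mode: 1023.0
    max: 1176.0
    low: 870.0
    high: 1176.0
  cost_ctp:
    family: beta_pert
    base: 836.0
    min: 711.0
    mode: 836.0
    max: 961.0
    low: 711.0
    high: 961.0
  cost_software:
    family: beta_pert
    base: 89.0
    min: 44.0
    mode: 89.0
    max: 520.0
    low: 44.0
    high: 520.0
  freq_cta_vs_mra:
    family: uniform
    base: 0.5
    min: 0.0
    max: 1.0
    low: 0.0
    high: 1.0
  freq_ctp_vs_mri:
    family: uniform
    base: 0.5
    min: 0.0
    max: 1.0
    low: 0.0
    high: 1.0
  cost_tpa:
    family: beta_pert
    base: 8004.0
    min: 6403.0
    mode: 8004.0
    max: 9605.0
    low: 6403.0
    high: 9605.0
  cost_mt_procedure:
    family: beta_pert
    base: 15836.0
    min: 5270.0
    mode: 15836.0
    max: 26401.0
    low: 5270.0
    high: 26401.0
  cost_mt_physician:
    family: beta_pert
    base: 2749.0
    min: 1262.0
    mode: 2749.0
    max: 4236.0
    low: 1262.0
    high: 4236.0
  cost_acute_mrs0_2:
    family: beta_pert
    base: 14382.0
    min: 14210.0
    mode: 14382.0
    max: 14554.0
    low: 14210.0
    high: 14554.0
  cost_acute_mrs3_5:
    family: beta_pert
    base: 17879.0
    min: 17660.0
    mode: 17879.0
    max: 18097.0
    low: 17660.0
    high: 18097.0
  cost_acute_death:
    family: beta_pert
    base: 23498.0
    min: 22614.0
    mode: 23498.0
    max: 24382.0
    low: 22614.0
    high: 24382.0
  cost_longterm_mrs0:
    family: beta_pert
    base: 2836.0
    min: 2269.0
    mode: 2836.0
    max: 3403.0
    low: 2269.0
    high: 3403.0
  cost_longterm_mrs1:
    family: beta_pert
    base: 2741.0
    min: 2336.0
    mode: 2741.0
    max: 3504.0
    low: 2336.0
    high: 3504.0
  cost_longterm_mrs2:
    family: beta_pert
    base: 3378.0
    min: 2703.0
    mode: 3378.0
    max: 4054.0
    low: 2703.0
    high: 4054.0
  cost_longterm_mrs3:
    family: beta_pert
    base: 5801.0
    min: 4641.0
    mode: 5801.0
    max: 6961.0
    low: 4641.0
    high: 6961.0
  cost_longterm_mrs4:
    family: beta_pert
    base: 11742.0
    min: 9393.0
    mode: 11742.0
    max: 14090.0
    low: 9393.0
    high: 14090.0
  cost_longterm_mrs5:
    family: beta_pert
    base: 17262.0
    min: 13809.0
    mode: 17262.0
    max: 20714.0
    low: 13809.0
    high: 20714.0
  utility_mrs0:
    family: beta
    base: 0.85
    alpha: 39.833837078536
    beta: 7.029500660918
    low: 0.8
    high: 1.0
  utility_mrs1:
    family: beta
    base: 0.8
    alpha: 85.952362614858
    beta: 21.488090653715
    low: 0.8
    high: 0.95
  utility_mrs2:
    family: beta
    base: 0.7
    alpha: 45.565114343178
    beta: 19.527906147076
    low: 0.68
    high: 0.9
  utility_mrs3:
    family: beta
    base: 0.51
    alpha: 48.226081129163
    beta: 46.334862261353
    low: 0.45
    high: 0.65
  utility_mrs4:
    family: beta
    base: 0.3
    alpha: 10.276969474792
    beta: 23.979595441181
    low: 0.1
    high: 0.4
  utility_mrs5:
    family: beta
    base: 0.15
    alpha: 2.550536619725
    beta: 14.453040845107
    low: 0.0
    high: 0.32
  recurrence_prob:
    family: beta
    base: 0.013
    alpha: 13.0
    beta: 986.0
    low: 0.006953560206
    high: 0.020909310061
  post_recurrence_death:
    family: beta
    base: 0.0513
    alpha: 5.1
    beta: 94.9
    low: 0.017176868263
    high: 0.101619102032
  death_hr_mrs0:
    family: log_normal
    base: 1.0
    se: 0.076
    low: 0.861605936716
    high: 1.160623386384
  death_hr_mrs1:
    family: log_normal
    base: 1.0
    se: 0.46
    low: 0.405926393389
    high: 2.463500812676
  death_hr_mrs2:
    family: log_normal
    base: 1.11
    se: 0.46
    low: 0.450578296662
    high: 2.73448590207
  death_hr_mrs3:
    family: log_normal
    base: 1.27
    se: 0.46
    low: 0.515526519604
    high: 3.128646032098
  death_hr_mrs4:
    family: log_normal
    base: 1.71
    se: 0.46
    low: 0.694134132695
    high: 4.212586389675
  death_hr_mrs5:
    family: log_normal
    base: 2.37
    se: 0.46
    low: 0.962045552332
    high: 5.838496926041
trial_defaults:
  DAWN:
    prop_male:
      MT_SMC: 0.393
      SMC: 0.515
    tpa_frequency:
      MT_SMC: 0.1
      SMC: 0.1
  DEFUSE3:
    prop_male:
      MT_SMC: 0.5
      SMC: 0.489
    tpa_frequency:
      MT_SMC: 0.1
      SMC: 0.1

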