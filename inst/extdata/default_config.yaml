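settings:
  cohort_size: 1000
  n_cycles: 25
  start_age: 60
  gdp_per_capita: 12551.49
transition:
  sarcopenia_prevalence:
    value: 0.12
    low: 0.1
    high: 0.15
    dist: beta
    dsa: ci
  rr_cvd_fall:
    value: 2.17
    low: 1.06
    high: 2.95
    dist: lognormal
    dsa: ci
  sarc_incidence_60_69:
    value: 0.04
    dsa: pct10
  sarc_incidence_70_79:
    value: 0.12
    dsa: pct10
  sarc_incidence_80plus:
    value: 0.17
    dsa: pct10
  p_death_background:
    value: 0.09
    dsa: pct10
  fracture_after_fall:
    value: 0.26
    low: 0.23
    high: 0.29
    dist: beta
    dsa: ci
  rr_sarc_cvd:
    value: 1.33
    low: 1.04
    high: 1.71
    dist: lognormal
    dsa: ci
  rr_sarc_fall:
    value: 1.89
    low: 1.33
    high: 2.68
    dist: lognormal
    dsa: ci
  rr_sarc_death:
    value: 2.0
    low: 1.71
    high: 2.34
    dist: lognormal
    dsa: ci
  rr_sarc_fracture:
    value: 1.71
    low: 1.44
    high: 2.03
    dist: lognormal
    dsa: ci
  sarcopenia_recovery_rate:
    value: 0.16
    low: 0.14
    high: 0.18
    dist: beta
    dsa: ci
  intervention_rr_incidence:
    value: 0.45
    low: 0.37
    high: 0.55
    dist: beta
    dsa: ci
  intervention_rr_recovery:
    value: 3.61
    low: 1.05
    high: 13.66
    dist: lognormal
    dsa: ci
  possible_sarcopenia_prop:
    value: 0.4
    low: 0.36
    high: 0.44
    dist: beta
    dsa: ci
screening_tools:
  sens_msra7:
    value: 0.81
    low: 0.72
    high: 0.88
    dist: beta
    dsa: ci
  sens_sarcf:
    value: 0.34
    low: 0.19
    high: 0.53
    dist: beta
    dsa: ci
  sens_calf:
    value: 0.81
    low: 0.77
    high: 0.84
    dist: beta
    dsa: ci
  sens_msra5:
    value: 0.61
    low: 0.54
    high: 0.69
    dist: beta
    dsa: ci
  sens_ishii:
    value: 0.81
    low: 0.78
    high: 0.85
    dist: beta
    dsa: ci
  sens_finger_ring:
    value: 0.71
    low: 0.65
    high: 0.77
    dist: beta
    dsa: ci
  sens_sarcf_msra5:
    value: 0.42
    low: 0.38
    high: 0.47
    dist: beta
    dsa: ci
  sens_sarcf_msra7:
    value: 0.64
    low: 0.57
    high: 0.7
    dist: beta
    dsa: ci
  sens_sarc_calf:
    value: 0.59
    low: 0.57
    high: 0.7
    dist: beta
    dsa: ci
  sens_awgs2019:
    value: 1.0
  spec_msra7:
    value: 0.43
    low: 0.35
    high: 0.52
    dist: beta
    dsa: ci
  spec_sarcf:
    value: 0.9
    low: 0.83
    high: 0.95
    dist: beta
    dsa: ci
  spec_calf:
    value: 0.73
    low: 0.71
    high: 0.76
    dist: beta
    dsa: ci
  spec_msra5:
    value: 0.74
    low: 0.69
    high: 0.79
    dist: beta
    dsa: ci
  spec_ishii:
    value: 0.76
    low: 0.73
    high: 0.79
    dist: beta
    dsa: ci
  spec_finger_ring:
    value: 0.85
    low: 0.82
    high: 0.87
    dist: beta
    dsa: ci
  spec_sarcf_msra5:
    value: 0.98
    low: 0.88
    high: 1.0
    dist: beta
    dsa: ci
  spec_sarcf_msra7:
    value: 1.0
  spec_sarc_calf:
    value: 0.85
    low: 0.75
    high: 0.92
    dist: beta
    dsa: ci
  spec_awgs2019:
    value: 1.0
costs:
  cost_intervention:
    value: 1119.05
    sd: 119.05
    dist: gamma
    dsa: pct10
  cost_fracture:
    value: 3599.05
    sd: 695.07
    dist: gamma
    dsa: pct10
  cost_cvd_initial:
    value: 4149.29
    sd: 414.93
    dist: gamma
    dsa: pct10
  cost_cvd_continuing:
    value: 1904.77
    sd: 190.48
    dist: gamma
    dsa: pct10
  cost_msra7:
    value: 0.71
    sd: 0.07
    dist: gamma
    dsa: pct10
  cost_sarcf:
    value: 0.71
    sd: 0.07
    dist: gamma
    dsa: pct10
  cost_msra5:
    value: 0.71
    sd: 0.07
    dist: gamma
    dsa: pct10
  cost_calf:
    value: 0.21
    sd: 0.02
    dist: gamma
    dsa: pct10
  cost_ishii:
    value: 1.52
    sd: 0.15
    dist: gamma
    dsa: pct10
  cost_finger_ring:
    value: 0.21
    sd: 0.02
    dist: gamma
    dsa: pct10
  cost_sarcf_msra5:
    value: 1.43
    sd: 0.14
    dist: gamma
    dsa: pct10
  cost_sarcf_msra7:
    value: 1.43
    sd: 0.14
    dist: gamma
    dsa: pct10
  cost_sarc_calf:
    value: 0.92
    sd: 0.09
    dist: gamma
    dsa: pct10
  cost_handgrip:
    value: 1.31
    sd: 0.13
    dist: gamma
    dsa: pct10
  cost_gait:
    value: 0.71
    sd: 0.07
    dist: gamma
    dsa: pct10
  cost_dxa:
    value: 42.86
    sd: 4.29
    dist: gamma
    dsa: pct10
utilities:
  u_nonsarc:
    value: 0.76
    sd: 0.08
    dist: beta
    dsa: pct10
  u_sarc:
    value: 0.68
    sd: 0.07
    dist: beta
    dsa: pct10
  u_sarc_fracture:
    value: 0.51
    sd: 0.05
    dist: beta
    dsa: pct10
  u_nonsarc_cvd:
    value: 0.75
    sd: 0.17
    dist: beta
    dsa: pct10
  u_sarc_cvd:
    value: 0.56
    sd: 0.06
    dist: beta
    dsa: pct10
  u_sarc_cvd_fracture:
    value: 0.42
    sd: 0.04
    dist: beta
    dsa: pct10
  u_nonsarc_fracture_60_64:
    value: 0.57
  u_nonsarc_fracture_65_69:
    value: 0.55
  u_nonsarc_fracture_70_74:
    value: 0.53
  u_nonsarc_fracture_75_79:
    value: 0.52
  u_nonsarc_fracture_80_84:
    value: 0.51
  u_nonsarc_fracture_85plus:
    value: 0.5
economics:
  discount_rate:
    value: 0.03
    low: 0.01
    high: 0.05
    dist: beta
    dsa: explicit
  gdp_per_capita:
    value: 12551.49
age_schedules:
- disease: CVD
  age_low: 60.0
  age_high: 64.0
  incidence: 0.0096076
  prevalence: 0.0977751
  mortality: 0.0019024
- disease: CVD
  age_low: 65.0
  age_high: 69.0
  incidence: 0.0126487
  prevalence: 0.122446
  mortality: 0.002768
- disease: CVD
  age_low: 70.0
  age_high: 74.0
  incidence: 0.0166524
  prevalence: 0.1533419
  mortality: 0.0040274
- disease: CVD
  age_low: 75.0
  age_high: 79.0
  incidence: 0.0219234
  prevalence: 0.1920336
  mortality: 0.0058598
- disease: CVD
  age_low: 80.0
  age_high: 84.0
  incidence: 0.0288629
  prevalence: 0.240488
  mortality: 0.008526
- disease: CVD
  age_low: 85.0
  age_high: 120.0
  incidence: 0.0390583
  prevalence: 0.3080217
  mortality: 0.0128793
- disease: fall
  age_low: 60.0
  age_high: 64.0
  incidence: 0.0593242
  prevalence: 0.0593242
  mortality: 5.7859487e-05
- disease: fall
  age_low: 65.0
  age_high: 69.0
  incidence: 0.0689249
  prevalence: 0.0689249
  mortality: 8.6316211e-05
- disease: fall
  age_low: 70.0
  age_high: 74.0
  incidence: 0.0800793
  prevalence: 0.0800793
  mortality: 0.0001288
- disease: fall
  age_low: 75.0
  age_high: 79.0
  incidence: 0.0930389
  prevalence: 0.0930389
  mortality: 0.0001921
- disease: fall
  age_low: 80.0
  age_high: 84.0
  incidence: 0.1080958
  prevalence: 0.1080958
  mortality: 0.0002866
- disease: fall
  age_low: 85.0
  age_high: 120.0
  incidence: 0.1274874
  prevalence: 0.1274874
  mortality: 0.000445
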