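population: non_epithelioid
description: Pembrolizumab plus platinum-pemetrexed vs chemotherapy, non-epithelioid
  population
wtp: 38042.49
discount_rate: 0.05
discount_method: annual
horizon_years: 10.0
cycle_days: 21.0
half_cycle: trapezoid
time_unit: cycles
currency:
  code: USD
  cny_per_usd: 7.0467
  price_year: 2023.0
seed: 1
psa:
  n_draws: 10000
  sd_divisor: 3.92
costs:
  pembrolizumab: 4654.66
  pemetrexed: 143.53
  cisplatin: 35.03
  nivolumab: 3279.69
  bevacizumab: 496.69
  gemcitabine: 153.21
  carboplatin: 43.94
  laboratory: 120.96
  ct_scan: 268.88
  end_of_life: 1460.3
  admin_premedication: 93.93
  admin_infusion: 1.86
  admin_premedication_secondary: 39.14
utilities:
  pfs: 0.706
  pd: 0.565
ae:
  costs:
    neutropenia: 411.93
    anemia: 921.1
    thrombocytopenia: 1523.82
    lipase_increase: 44.3
    fatigue: 103.0
    hyperglycemia: 361.91
  disutilities:
    neutropenia: 0.09
    anemia: 0.12
    thrombocytopenia: 0.11
    lipase_increase: 0.47
    fatigue: 0.29
    hyperglycemia: 0.2
ranges:
  disutility_anemia:
  - 0.01
  - 0.14
  discount_rate:
  - 0.0
  - 0.08
arms:
  pembro_chemo:
    label: Pembrolizumab plus chemotherapy
    os:
      family: gengamma_prentice
      mu: 2.314
      sigma: 0.955
      Q: -0.835
    pfs:
      family: gengamma_prentice
      mu: 1.6226
      sigma: 0.9186
      Q: -0.942
    chemo_drugs:
    - pemetrexed
    - cisplatin
    chemo_cycles: 6
    antibody_drug: pembrolizumab
    antibody_cycles: 35
    antibody_paid_cycles: 4.5471
    subsequent:
      drugs:
      - bevacizumab
      - gemcitabine
      - carboplatin
      mode: per_cycle
      cap_cycles: 10.1769
    ae_incidence:
      fatigue: 0.0676
      anemia: 0.2387
      thrombocytopenia: 0.1081
      neutropenia: 0.3198
      lipase_increase: 0.0721
      hyperglycemia: 0.0631
  chemo:
    label: Chemotherapy
    os:
      family: lognormal
      meanlog: 2.114
      sdlog: 0.969
    pfs:
      family: gamma
      shape: 2.1439
      rate: 0.3955
    chemo_drugs:
    - pemetrexed
    - cisplatin
    chemo_cycles: 6
    antibody_drug: ~
    antibody_cycles: 0
    antibody_paid_cycles: 0.0
    subsequent:
      drugs: nivolumab
      mode: per_cycle
      cap_cycles: 10.1769
    ae_incidence:
      fatigue: 0.0569
      anemia: 0.1327
      thrombocytopenia: 0.0474
      neutropenia: 0.1577
      lipase_increase: 0.0237
      hyperglycemia: 0.0427
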