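econ:
  wtp: 97048.0
  discount: 0.03
  horizon_years: 40.0
  cycle_months: 1.0
  u_pf: 0.76
  u_pd: 0.68
  du_ae: 0.16
  du_iv: 0.025
  conv_factor: 0.9198
  testing_cost: 934.0
  include_testing: no
  currency:
    year: 2023.0
    usd_twd: 31.35
ae_policy: first-cycle
ae_granularity: aggregate
arms:
  pemigatinib:
    label: pemigatinib
    route: oral
    pfs:
      family: log-normal
      params:
        meanlog: 1.988
        sdlog: 0.989
    os:
      family: log-logistic
      params:
        scale: 18.387
        shape: 1.626
    cost_med_annual: 97645.0
    cost_nonmed_annual: 9361.0
    cost_supportive_annual: 15978.0
    p_ae: 0.56
    ae_events:
      event:
      - stomatitis
      - palmar-plantar erythrodysesthesia
      - fatigue or lethargy
      - hypophosphatemia
      prob:
      - 0.083
      - 0.056
      - 0.019
      - 0.102
      disutility:
      - 0.0375
      - 0.085
      - 0.085
      - 0.0
  mfolfox:
    label: mFOLFOX
    route: iv
    pfs:
      family: log-normal
      params:
        meanlog: 1.43
        sdlog: 0.754
    os:
      family: log-normal
      params:
        meanlog: 1.834
        sdlog: 0.873
    cost_med_annual: 13230.0
    cost_nonmed_annual: 27512.0
    cost_supportive_annual: 15978.0
    p_ae: 0.54
    ae_events:
      event:
      - hypophosphatemia
      - fatigue or lethargy
      - neutropenia
      - infection
      - pain
      - biliary event
      - hypertension
      prob:
      - 0.01
      - 0.19
      - 0.12
      - 0.18
      - 0.1
      - 0.19
      - 0.05
      disutility:
      - 0.0
      - 0.085
      - 0.0607
      - 0.085
      - 0.069
      - 0.085
      - 0.03
  fu5lv:
    label: 5-FU/LV
    route: iv
    pfs:
      family: log-normal
      params:
        meanlog: 0.809
        sdlog: 0.9209
    os:
      family: log-normal
      params:
        meanlog: 1.794
        sdlog: 0.81
    cost_med_annual: 5707.0
    cost_nonmed_annual: 27512.0
    cost_supportive_annual: 15978.0
    p_ae: 0.18
    ae_events:
      event:
      - stomatitis
      - palmar-plantar erythrodysesthesia
      - hypophosphatemia
      prob:
      - 0.05
      - 0.04
      - 0.07
      disutility:
      - 0.0375
      - 0.085
      - 0.0
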