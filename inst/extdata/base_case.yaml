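engine:
  cycle_length: 1.0
  horizon: 120
  discount_rate: 0.05
  wtp: 33819.0
  midpoint: yes
  background_mortality: ~
survival:
  pfs:
    NI:
      family: log_normal
      lambda: 1.93843
      gamma: 1.26135
    C:
      family: log_logistic
      lambda: 7.5378
      gamma: 2.29427
  os:
    A:
      NI:
        family: weibull_ph
        lambda: 0.0241553
        gamma: 1.1284343
      C:
        family: log_logistic
        lambda: 14.25065
        gamma: 1.76236
    E:
      NI:
        family: log_logistic
        lambda: 19.01452
        gamma: 1.51241
      C:
        family: log_logistic
        lambda: 16.70245
        gamma: 1.70694
    'N':
      NI:
        family: exponential
        lambda: 0.0412831
        gamma: ~
      C:
        family: log_logistic
        lambda: 9.03382
        gamma: 2.17796
utilities:
  u_pfs: 0.706
  u_pd: 0.565
  u_death: 0.0
  disutility:
    asthenia: 0.07
    anemia: 0.073
    neutropenia: 0.2
  incidence:
    NI:
      asthenia: 0.0
      anemia: 0.0033
      neutropenia: 0.0067
    C:
      asthenia: 0.042
      anemia: 0.1127
      neutropenia: 0.1514
prices:
  drugs:
    nivolumab: 15.96
    ipilimumab: 77.96
    pemetrexed: 0.88
    cisplatin: 0.12
    carboplatin: 0.09
    vinorelbine: 1.52
    gemcitabine: 0.07
  admin_iv: 7.83
  followup: 69.13
  ae_cost:
    asthenia: 96.05
    anemia: 500.78
    neutropenia: 434.57
patient:
  weight: 65.0
  bsa: 1.72
  crcl: 60.0
  age: 69.0
treatment:
  first_line_duration:
    NI: 6.0
    C: 4.0
  dosing:
    q2w: 2.0
    q3w: 1.333333333333
    q6w: 0.724702380952
    d1d8: 2.666666666667
  second_line_method: transition
  followup_in_pd: yes
  mix:
    p_carbo: 0.5
    p_immuno: 0.5
    p_nivo_mono: 0.5
    p_vinorelbine: 0.5
  second_line_duration:
    ni_chemo: 5.0
    c_immuno: 3.0
    c_chemo: 16.0
psa:
  n_iter: 1000
  seed: 743
notes:
  cn_os_gamma: non-epithelioid C-arm OS shape 2.17796 reconstructed from a corrupted
    source entry
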