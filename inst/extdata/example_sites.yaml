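sites:
  - site_code: S01
    n_women: 500
    dialect: alpha
    twin_rate: 0.015
    neonatal_admission_rate: 0.10
    date_window: ["2017-01-01", "2018-11-30"]
    missingness:
      height: {mechanism: MAR, rate: 0.2, driver: weight}
      ethnicity: {mechanism: MCAR, rate: 0.1}
    defect_rates:
      duplicate_row: 0.005
      implausible_value: 0.005
  - site_code: S02
    n_women: 500
    dialect: charlie
    twin_rate: 0.015
    neonatal_admission_rate: 0.10
    date_window: ["2017-01-01", "2018-11-30"]
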