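smoking:
  cessation_prob: 0.01
  initiation_prob: 0.0
  adult_age: 25.0
econ:
  exchange_rate_pen_per_usd: 3.3
  inflation_factor: 0.1047
  discount_rate: 0.05
  wage_growth_rate: 0.02
  retirement_age:
    male: 65.0
    female: 65.0
  mincer:
    male:
      beta0: 7.1
      beta_edu: 0.09
      beta_age: 0.055
      beta_age2: -0.00055
    female:
      beta0: 6.9
      beta_edu: 0.09
      beta_age: 0.055
      beta_age2: -0.00055
  mean_education_years:
    male: 10.5
    female: 9.800000000000001
  caregiver_hourly_wage: 9.0
  prevalence_impact_share: 0.5
  elasticity: -0.4
  gdp_usd_millions: 219039.0
  cigarette_price_pen: 12.0
  tax_share: 0.733
  annual_consumption_packs: 130000000.0
shs_uplift:
  male: 0.136
  female: 0.12
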