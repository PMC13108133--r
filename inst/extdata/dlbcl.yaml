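# Incidence-dominant preset: diffuse large B-cell lymphoma treated by CAR-T.
# Rapid mortality (0.5-year duration) leaves prevalence at half the yearly
# incidence, so there is essentially no backlog.
name: dlbcl
epidemiology:
  prevalence_rate: 1.25/100000
  incidence_rate: 2.5/100000
  incidence_basis: population
  population_size: 11500000
  births_per_year: 120000
  growth_rate: 0.0
  backlog_spread_years: 1
  disease_duration_years: 0.5
  uptake_fraction: 1.0
economics:
  budget_cap: 10000000.0
  social_discount_rate: 0.03
  inflation_rate: 0.0
  horizon_years: 25
price: 350000.0
durability_years: 2.5
truncation: window_only
schemes:
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 5}
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 10}
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 15}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 5}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 10}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 15}
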