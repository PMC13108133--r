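# Prevalence-dominant preset: Leber congenital amaurosis (RPE65) treated by
# one-time gene therapy. Large prevalent backlog, tiny per-newborn incidence.
name: lca
epidemiology:
  prevalence_rate: 1/10700
  incidence_rate: 1/750000
  incidence_basis: births
  population_size: 11500000
  births_per_year: 120000
  growth_rate: 0.0
  backlog_spread_years: 1
  disease_duration_years: 70.0
  uptake_fraction: 1.0
economics:
  budget_cap: 250000000.0
  social_discount_rate: 0.03
  inflation_rate: 0.0
  horizon_years: 25
price: 1000000.0
durability_years: 75.0
truncation: window_only
schemes:
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 5}
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 10}
  - {bond_type: health_impact, bond_rate: 0.03, n_payments: 15}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 5}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 10}
  - {bond_type: corporate, bond_rate: 0.10, n_payments: 15}
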