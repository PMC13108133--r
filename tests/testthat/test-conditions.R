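econ_lca <- econ_spec(budget_cap = 250e6)

discounted_pair <- function(epi, scheme, econ, policy = "window_only") {
  fl <- patient_flow(epi, econ$horizon_years)
  up <- build_upfront_stream(fl, scheme$price)
  ab <- build_abp_stream(fl, scheme, policy)
  r <- econ$social_discount_rate
  list(up_nom = up, ab_nom = ab,
       up_dis = discount_stream(up, r), ab_dis = discount_stream(ab, r))
}

test_that("condition 1 requires the cap to bite upfront but not under ABP", {
  sch <- payment_scheme(1e6, n_payments = 5, bond_rate = 0.03)
  p <- discounted_pair(lca_epi(), sch, econ_lca)
  c1 <- condition1(p$up_dis, p$ab_dis, econ_lca)
  expect_true(c1$upfront_exceeds_cap) # ~EUR 1.07bn vs EUR 250m cap
  expect_true(c1$abp_within_cap)
  expect_true(c1$pass)

  # cap above both maxima: ABP not needed
  loose <- econ_spec(budget_cap = 5e9)
  expect_false(condition1(p$up_dis, p$ab_dis, loose)$pass)
  # cap below both maxima: ABP does not help
  tight <- econ_spec(budget_cap = 1e6)
  c1t <- condition1(p$up_dis, p$ab_dis, tight)
  expect_true(c1t$upfront_exceeds_cap)
  expect_false(c1t$abp_within_cap)
  expect_false(c1t$pass)

  expect_error(condition1(p$up_nom, p$ab_dis, econ_lca),
               class = "abpsim_invalid_parameter")
})

test_that("condition 2a equals one exactly for n = 1 and for i = r on the full ledger", {
  sch1 <- payment_scheme(1e6, n_payments = 1, bond_rate = 0.08)
  p1 <- discounted_pair(lca_epi(), sch1, econ_lca)
  expect_identical(condition2a(p1$up_nom, p1$ab_nom, 0.03), 1)

  # per-patient NPV identity: at i = r every patient's annuities are worth P
  sch <- payment_scheme(1e6, n_payments = 10, bond_rate = 0.03)
  p <- discounted_pair(lca_epi(growth_rate = 0.02), sch, econ_lca,
                       policy = "full_ledger")
  expect_equal(condition2a(p$up_nom, p$ab_nom, 0.03), 1, tolerance = 1e-12)
})

test_that("condition 2a is monotone in the bond rate around the social rate", {
  rates <- c(0.00, 0.01, 0.02, 0.03, 0.05, 0.08, 0.12)
  ratios <- vapply(rates, function(i) {
    sch <- payment_scheme(1e6, n_payments = 10, bond_rate = i)
    p <- discounted_pair(lca_epi(), sch, econ_lca, policy = "full_ledger")
    condition2a(p$up_nom, p$ab_nom, 0.03)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios[rates < 0.03] < 1))
  expect_true(all(ratios[rates > 0.03] > 1))
})

test_that("condition 2a rejects a zero-value upfront stream", {
  zero <- cashflow_stream(rep(0, 5))
  abp <- cashflow_stream(rep(1, 5))
  expect_error(condition2a(zero, abp, 0.03),
               class = "abpsim_invalid_parameter")
})

test_that("condition 2b reduces to A/P when the year-0 backlog dominates", {
  sch <- payment_scheme(1e6, n_payments = 5, bond_rate = 0.03)
  p <- discounted_pair(lca_epi(), sch, econ_lca)
  a <- annuity_due(1e6, 0.03, 5)$annuity_amount
  expect_equal(condition2b(p$up_dis, p$ab_dis), a / 1e6, tolerance = 1e-9)
  expect_equal(round(condition2b(p$up_dis, p$ab_dis), 3), 0.212)

  sch1 <- payment_scheme(1e6, n_payments = 1, bond_rate = 0.10)
  p1 <- discounted_pair(lca_epi(), sch1, econ_lca)
  expect_equal(condition2b(p1$up_dis, p1$ab_dis), 1)
})

test_that("the six financing schemes keep the prevalence-dominant max-BI ratio in 8-24%", {
  ratios <- vapply(default_scheme_grid(1e6), function(sch) {
    p <- discounted_pair(lca_epi(), sch, econ_lca)
    condition2b(p$up_dis, p$ab_dis)
  }, numeric(1))
  expect_true(all(ratios >= 0.08 & ratios <= 0.24))
})

test_that("condition 3 metrics: NPV matching is exact, the nominal premium is n*A/P", {
  for (i in c(0, 0.03, 0.10)) {
    for (n in c(2, 5, 12)) {
      sch <- payment_scheme(1e6, n_payments = n, bond_rate = i)
      expect_equal(condition3(sch, "npv_at_bond_rate"), 1, tolerance = 1e-12)
    }
  }
  sch <- payment_scheme(1e6, n_payments = 5, bond_rate = 0.03)
  expect_equal(round(condition3(sch, "nominal_sum"), 2), 1.06)
  sch0 <- payment_scheme(1e6, n_payments = 5, bond_rate = 0)
  expect_equal(condition3(sch0, "nominal_sum"), 1)
  expect_error(condition3(sch, "bogus"))
})

test_that("condition 4 caps the annuity count at the durability of effect", {
  mk <- function(n) payment_scheme(1e6, n_payments = n, bond_rate = 0.03)
  expect_true(condition4(mk(15), 75))   # lifetime durability
  expect_false(condition4(mk(10), 2.5)) # short-lived benefit
  expect_true(condition4(mk(2), 2.5))
  expect_false(condition4(mk(3), 2.5))
})

test_that("full evaluation reproduces the headline feasibility verdicts", {
  econ <- econ_spec(budget_cap = 250e6)
  fl <- patient_flow(lca_epi(), 25)
  hib10 <- evaluate_conditions(
    fl, payment_scheme(1e6, n_payments = 10, bond_rate = 0.03),
    econ, durability_years = 75)
  expect_true(hib10$overall_feasible)

  econ_d <- econ_spec(budget_cap = 10e6)
  fl_d <- patient_flow(dlbcl_epi(), 25)
  corp10 <- evaluate_conditions(
    fl_d, payment_scheme(350000, n_payments = 10, bond_rate = 0.10,
                         bond_type = "corporate"),
    econ_d, durability_years = 2.5)
  expect_false(corp10$overall_feasible)
  expect_false(corp10$c4_pass)
})

test_that("an n = 1 scheme behaves exactly like upfront payment", {
  econ <- econ_spec(budget_cap = 250e6)
  fl <- patient_flow(lca_epi(), 25)
  rep1 <- evaluate_conditions(
    fl, payment_scheme(1e6, n_payments = 1, bond_rate = 0.10),
    econ, durability_years = 75)
  expect_equal(rep1$c2a_ratio, 1)
  expect_equal(rep1$c2b_ratio, 1)
  expect_false(rep1$c1_pass) # the ABP bill breaches the cap just as upfront does
  expect_false(rep1$overall_feasible)
})

test_that("condition ratios are invariant under joint demographic scaling", {
  econ <- econ_spec(budget_cap = 250e6)
  sch <- payment_scheme(1e6, n_payments = 10, bond_rate = 0.05,
                        bond_type = "corporate")
  rep_a <- evaluate_conditions(patient_flow(lca_epi(), 25), sch, econ, 75)
  big <- epi_spec(prevalence_rate = 1 / 10700, incidence_rate = 1 / 750000,
                  incidence_basis = "births",
                  population_size = 11.5e6 * 4, births_per_year = 120000 * 4)
  rep_b <- evaluate_conditions(patient_flow(big, 25), sch, econ, 75)
  expect_equal(rep_b$c2a_ratio, rep_a$c2a_ratio, tolerance = 1e-12)
  expect_equal(rep_b$c2b_ratio, rep_a$c2b_ratio, tolerance = 1e-12)
  expect_equal(rep_b$c3_ratio, rep_a$c3_ratio, tolerance = 1e-12)
})

test_that("evaluation is a pure function: repeated runs are identical", {
  econ <- econ_spec(budget_cap = 250e6)
  fl <- patient_flow(lca_epi(growth_rate = 0.02), 25)
  sch <- payment_scheme(1e6, n_payments = 15, bond_rate = 0.03)
  expect_identical(evaluate_conditions(fl, sch, econ, 75),
                   evaluate_conditions(fl, sch, econ, 75))
})

test_that("horizon mismatch between flow and economics is rejected", {
  econ <- econ_spec(budget_cap = 250e6, horizon_years = 25)
  fl <- patient_flow(lca_epi(), 20)
  sch <- payment_scheme(1e6, n_payments = 5, bond_rate = 0.03)
  expect_error(evaluate_conditions(fl, sch, econ, 75),
               class = "abpsim_invalid_parameter")
})
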