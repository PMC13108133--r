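test_that("the prevalence-dominant preset is feasible on health impact bonds only", {
  rep <- run_preset("lca")
  expect_equal(nrow(rep), 6L)
  hib <- rep[rep$bond_type == "health_impact", ]
  corp <- rep[rep$bond_type == "corporate", ]
  # 10- and 15-year health impact bonds satisfy all four conditions
  expect_true(all(hib$overall_feasible[hib$maturity_years %in% c(10, 15)]))
  expect_false(any(corp$overall_feasible))
  # the corporate NPV ratios exceed 1: spreading at 10% costs the payer more
  expect_true(all(corp$c2a_ratio > 1))
  expect_true(all(hib$c2a_pass))
})

test_that("the incidence-dominant preset fails on durability everywhere", {
  rep <- run_preset("dlbcl")
  expect_equal(nrow(rep), 6L)
  expect_false(any(rep$overall_feasible))
  expect_false(any(rep$c4_pass)) # 5-15 annuities vs ~2.5-year durability
  # the upfront bill never fits under the EUR 10m cap, so ABP cannot rescue it
  expect_false(any(rep$c1_pass))
})

test_that("an empty scheme grid yields an empty report with the full header", {
  rep <- run_preset("lca", scheme_grid = list())
  expect_equal(nrow(rep), 0L)
  expect_true(all(c("bond_type", "c2a_ratio", "overall_feasible") %in%
                    names(rep)))
})

test_that("unknown presets are rejected with the list of available ones", {
  expect_error(abp_preset("nope"), "lca", class = "abpsim_config_error")
  expect_error(run_preset("nope"), "dlbcl", class = "abpsim_config_error")
})

test_that("feasibility verdicts survive spreading the backlog over up to five years", {
  cfg <- abp_preset("lca")
  grid <- feasibility_sweep(cfg, list(backlog_spread_years = 1:5))
  expect_equal(nrow(grid), 5L)
  # the ABP-side conditions (scale-free ratios and durability) hold for every
  # backlog spread; only the absolute cap comparison depends on demography,
  # and there the upfront bill simply stops breaching the cap at m = 5
  expect_true(all(grid$c2a_pass & grid$c2b_pass & grid$c3_pass & grid$c4_pass))
  expect_true(all(grid$overall_feasible[grid$backlog_spread_years <= 4]))
  for (m in 1:5) {
    epi_m <- epi_spec(prevalence_rate = 1 / 10700,
                      incidence_rate = 1 / 750000,
                      incidence_basis = "births", backlog_spread_years = m)
    expect_equal(classify_dominance(epi_m), "prevalence_dominant")
  }
})

test_that("growth-rate sweep leaves the prevalence-dominant verdict unchanged", {
  grid <- feasibility_sweep(abp_preset("lca"),
                            list(growth_rate = c(0, 0.01, 0.02)))
  expect_equal(nrow(grid), 3L)
  expect_true(all(grid$overall_feasible))
})

test_that("a single-point sweep equals a direct evaluation", {
  cfg <- abp_preset("lca")
  grid <- feasibility_sweep(cfg, list(bond_rate = 0.03))
  fl <- patient_flow(cfg$epidemiology, 25)
  direct <- evaluate_conditions(fl, cfg$schemes[[1]], cfg$economics,
                                cfg$durability_years, cfg$truncation)
  expect_equal(grid$c2a_ratio, direct$c2a_ratio)
  expect_equal(grid$c2b_ratio, direct$c2b_ratio)
  expect_equal(grid$overall_feasible, direct$overall_feasible)
})

test_that("multi-axis sweeps cover the full Cartesian grid deterministically", {
  cfg <- abp_preset("lca")
  axes <- list(bond_rate = c(0.01, 0.03, 0.10), n_payments = c(5, 10))
  g1 <- feasibility_sweep(cfg, axes)
  g2 <- feasibility_sweep(cfg, axes)
  expect_equal(nrow(g1), 6L)
  expect_identical(g1, g2)
  # spot-check one cell against pointwise evaluation
  cell <- g1[g1$bond_rate == 0.10 & g1$n_payments == 10, ]
  fl <- patient_flow(cfg$epidemiology, 25)
  direct <- evaluate_conditions(
    fl, payment_scheme(cfg$price, n_payments = 10, bond_rate = 0.10),
    cfg$economics, cfg$durability_years)
  expect_equal(cell$c2a_ratio, direct$c2a_ratio)
})

test_that("sweep inputs are validated", {
  cfg <- abp_preset("lca")
  expect_error(feasibility_sweep(cfg, list()), class = "abpsim_invalid_parameter")
  expect_error(feasibility_sweep(cfg, list(widget = 1:3)),
               class = "abpsim_invalid_parameter")
  expect_error(feasibility_sweep(cfg, list(bond_rate = c(0.1, 0.05))),
               class = "abpsim_invalid_parameter")
  expect_error(feasibility_sweep(cfg, list(bond_rate = numeric(0))),
               class = "abpsim_invalid_parameter")
  expect_error(feasibility_sweep(cfg, list(bond_rate = c(0, Inf))),
               class = "abpsim_invalid_parameter")
})

test_that("the cost-equivalence rate threshold equals the social discount rate", {
  cfg <- abp_preset("lca")
  expect_equal(rate_threshold(cfg, seq(0, 0.06, by = 0.005)), 0.03)
  expect_equal(rate_threshold(cfg, 0.03), 0.03) # single-point grid
})

test_that("the rate threshold is independent of the therapy price", {
  grid <- seq(0, 0.08, by = 0.01)
  thresholds <- vapply(c(0.35e6, 1e6, 2e6), function(p) {
    cfg <- abp_preset("lca")
    cfg$price <- p
    cfg$schemes <- list(payment_scheme(p, n_payments = 10, bond_rate = 0.03))
    rate_threshold(cfg, grid)
  }, numeric(1))
  expect_equal(thresholds, rep(0.03, 3))
})

test_that("a grid with no cost-equivalent rate signals none", {
  cfg <- abp_preset("lca")
  expect_warning(thr <- rate_threshold(cfg, c(0.05, 0.06, 0.07)),
                 "no rate")
  expect_true(is.na(thr))
})
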