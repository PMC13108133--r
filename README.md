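# abpsim

Budget-impact simulation of annuity-based payments (ABP) for one-time
advanced therapies.

## The problem

Gene and cell therapies are administered once, priced in the hundreds of
thousands to millions of euros per patient, and often launch into a backlog
of prevalent patients who have been waiting for a treatment to exist. Paying
for everyone upfront can blow through a payer's yearly budget cap in the
launch year, even when the therapy is cost-effective over a lifetime.
Spreading the price over `n` yearly annuities inside a managed entry
agreement is the commonly proposed fix — but annuities carry financing costs
and mortgage future budgets, so they are not always the better deal.

`abpsim` is a deterministic cohort-level simulator for payers, HTA analysts
and health economists that makes this trade-off explicit. It projects the
yearly flow of treated patients from disease epidemiology, builds the payer's
budget-impact stream under upfront payment and under ABP, and screens four
feasibility conditions a scheme must pass to be acceptable to *both* the
payer and the manufacturer.

## The model

**Patient flow.** A disease with prevalence `prev` (fraction of the
population) and incidence `inc` (per population or per newborn) produces a
prevalent backlog treated in equal shares over the first `m` years, plus an
incident cohort `inc0 * (1+g)^t` in every year `t` of the `T = 25`-year
horizon. `prev/inc >> 1` is a *prevalence-dominant* disease (large backlog,
e.g. a congenital retinal dystrophy treated by gene therapy);
`prev/inc <= 1` is *incidence-dominant* (rapidly fatal disease, no queue,
e.g. an aggressive lymphoma treated by CAR-T).

**Financing.** A negotiated upfront price `P` is converted into `n` equal
annuities due at the *beginning* of each year, priced at bond rate `i`:

    A = i * P / (1 - (1+i)^-n) * 1 / (1+i),     A = P/n  when  i = 0.

By construction the schedule's net present value at the bond rate is exactly
`P`, so the financier is compensated for its cost of capital. `i` is around
1–3% for a governmental health impact bond and 8–10% for a corporate bond.

**Streams.** Every patient starting therapy in year `s` owes `A` in years
`s .. s+n-1`; summing over cohorts gives the yearly ABP budget impact
`BI_A,t`, against `BI_U,t = P * initiated_t` upfront. Streams are discounted
at the social rate `r` (default 3%).

**The four conditions.**

1. The discounted upfront stream must breach the payer's yearly cap
   `BI_max` while the ABP stream stays within it (otherwise ABP is either
   useless or insufficient).
2. Cost-equivalence: (2a) `NPV(BI_A, r) <= NPV(BI_U, r)`; (2b) the worst
   ABP year must not exceed the worst upfront year,
   `BI_A,Max / BI_U,Max <= 1`.
3. The manufacturer must be made whole: the schedule's NPV at the bond rate
   must match `P` (reported alongside the nominal premium `n*A/P`).
4. The annuity count may not exceed the durability of the therapeutic
   effect in whole years.

## Worked example

```r
library(abpsim)

annuity_due(1e6, 0.03, 5)
#> Annuity-due schedule: 5 yearly payment(s) of 211,995 (principal 1,000,000, bond rate 3.00%)

run_preset("lca")[, c("bond_type", "bond_rate", "maturity_years",
                      "c2a_ratio", "c2b_ratio", "overall_feasible")]
#>       bond_type bond_rate maturity_years c2a_ratio  c2b_ratio overall_feasible
#> 1 health_impact      0.03              5 0.9998540 0.21199473             TRUE
#> 2 health_impact      0.03             10 0.9996636 0.11381603             TRUE
#> 3 health_impact      0.03             15 0.9994646 0.08132678             TRUE
#> 4     corporate      0.10              5 1.1310700 0.23981589            FALSE
#> 5     corporate      0.10             10 1.2994707 0.14795036            FALSE
#> 6     corporate      0.10             15 1.4688597 0.11952162            FALSE
```

Reading the LCA (prevalence-dominant, EUR 1m therapy, EUR 250m cap) report:
health-impact-bond ABP at 3% passes everything — its worst year costs the
payer 8–21% of the worst upfront year (`c2b_ratio`) and its discounted total
is no dearer than paying upfront (`c2a_ratio <= 1`). Corporate-bond ABP at
10% fails: the payer would overpay by 13–47% in NPV terms. The
incidence-dominant preset fails across the board because a 5–15-year
annuity cannot be justified for a therapy whose effect is only credible for
about 2.5 years:

```r
any(run_preset("dlbcl")$overall_feasible)
#> [1] FALSE
```

Sweeps and the cost-equivalence rate threshold:

```r
feasibility_sweep(abp_preset("lca"), list(backlog_spread_years = 1:5))
rate_threshold(abp_preset("lca"), seq(0, 0.06, by = 0.005))
#> [1] 0.03   # ABP stays cost-equivalent only while the bond rate <= social rate
```

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/abpsim.R", package="abpsim"))')" \
    run --preset lca --out lca_report.csv
```

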