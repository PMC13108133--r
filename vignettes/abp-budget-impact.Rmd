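---
title: "Annuity-based payment feasibility: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annuity-based payment feasibility: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpsim)
```

## The model

`abpsim` simulates a healthcare payer's yearly drug expenditure for a
one-time advanced therapy over a horizon of `T` years (default 25), under
two funding modalities, and screens whether annuity-based payment (ABP) is
a defensible alternative to paying upfront.

The model is a deterministic, expected-value cohort model: patient counts
are real numbers, there is no sampling, and repeated evaluation of the same
inputs is bit-identical. It accounts for drug purchasing costs only — no
disease-cost offsets, no health outcomes, no mortality dynamics beyond what
the epidemiological rates already encode.

### Patient flow

An `epi_spec` turns disease epidemiology into a flow of treatment starts:

* a **prevalent backlog** `prev * population` waiting at launch, treated in
  equal shares over the first `m` years (`backlog_spread_years`); and
* an **incident cohort** in every year `t`, `inc0 * (1+g)^t`, where `inc0`
  is incidence times the population (or times yearly births, for diseases
  quoted per newborn) and `g` is a demographic growth factor.

Both components are scaled by an uptake fraction (default 1). The ratio of
backlog to first-year inflow classifies the disease: `prev/inc > 1` is
prevalence-dominant, otherwise incidence-dominant. For a stationary disease
`prev = inc x duration`, which the constructor checks as a warning (only
when both rates share the population denominator — a per-newborn incidence
cannot be compared to a per-population prevalence directly).

### Financing

`annuity_due(P, i, n)` converts the negotiated upfront price into `n` equal
payments due at the *beginning* of each year, priced at bond rate `i`:

$$A = \frac{iP}{1-(1+i)^{-n}}\cdot\frac{1}{1+i}.$$

The schedule satisfies $\sum_{t=0}^{n-1} A (1+i)^{-t} = P$: whoever
finances the spread (a government issuing a health impact bond at ~1–3%, or
the manufacturer issuing a corporate bond at ~8–10%) recovers exactly the
price at its own cost of capital. Two algebraic limits are implemented in
closed form rather than through the (singular or ulp-inexact) formula:
`i = 0` gives `A = P/n`, and `n = 1` gives `A = P` exactly for any rate, so
a one-annuity scheme is *identically* an upfront payment.

### Streams and discounting

Each patient starting in year `s` owes `A` in years `s, ..., s+n-1`
(per-patient ledger semantics); summing over cohorts gives the ABP stream,
against `P x starts_t` upfront. Two truncation policies exist because the
payer's window and the manufacturer's contract differ:

* `window_only` (default, the payer's budget perspective): payments falling
  at or beyond year `T` are dropped from the stream;
* `full_ledger`: the stream is extended to year `T + n - 2` so every
  contracted payment appears. This is the analytically clean setting — the
  per-patient identity below only holds on the full ledger.

Streams are nominal until passed through `discount_stream(stream, r)`,
which applies `(1+r)^{-t}` with `t = 0` in the first model year (payments
are due at the start of the year, so the first one is undiscounted — the
same convention as the annuity-due timing). A discounted stream refuses to
be discounted again. A constant inflation rate (default 0: everything in
real terms, since no anchor rate exists for the scenarios shipped) can be
applied to nominal streams before discounting.

### The four conditions

`evaluate_conditions()` screens a (flow, scheme, economics) triple:

1. **Budget cap.** `max_t BI_U,t > BI_max` *and* `max_t BI_A,t <= BI_max`
   on discounted streams. The cap itself is a fixed yearly amount and is
   not discounted. If upfront fits under the cap, ABP solves a problem the
   payer does not have; if ABP still breaches it, spreading did not help.
2. **Cost equivalence.** (2a) `NPV(BI_A, r)/NPV(BI_U, r) <= 1`; (2b)
   `max_t BI_A,t / max_t BI_U,t <= 1` on discounted streams. Ratios of
   exactly 1 pass (the requirement is "no greater than"); numerically, a
   relative tolerance of 1e-9 guards the boundary.
3. **Manufacturer compensation.** The default metric is the NPV of the
   annuity schedule at the bond rate over the price — exactly 1 by
   construction, reported as an audit column. The nominal premium `nA/P`
   (what the payer concedes undiscounted) is available as a secondary
   metric. We chose the NPV metric as the default because it is the one
   the acceptance inequality actually defines; the package deliberately
   exposes both rather than a single opaque "condition 3 number".
4. **Durability.** `n <= floor(durability_years)`. Charging an annuity
   beyond the period over which the therapeutic effect is credible is not
   defensible to either party.

A useful analytic consequence of the annuity-due identity: on the full
ledger, a patient treated in year `s` contributes `P (1+r)^{-s}` to the ABP
NPV whenever `i = r` — exactly their upfront contribution. Condition 2a's
ratio is therefore exactly 1 at `i = r`, below 1 for `i < r`, above 1 for
`i > r` on the full ledger — the
bond rate may not exceed the social discount rate for ABP to be
cost-equivalent. `rate_threshold()` makes this scan explicit; it is
price-invariant because both NPVs scale linearly in `P`.

## Shipped scenarios and defaults

Two presets bracket the epidemiological regimes:

| parameter | `lca` (prevalence-dominant) | `dlbcl` (incidence-dominant) |
|---|---|---|
| prevalence | 1/10,700 of population | 1.25/100,000 of population |
| incidence | 1/750,000 newborns/yr | 2.5/100,000 population/yr |
| price | EUR 1,000,000 | EUR 350,000 |
| yearly budget cap | EUR 250m | EUR 10m |
| durability | 75 y (lifetime) | 2.5 y |
| schemes | 3% and 10% bonds x {5, 10, 15} y | same |

Shared defaults: horizon 25 y, social discount rate 3%, inflation 0,
backlog spread `m = 1` (the extreme everyone-at-launch case; sweeps over
`m = 1..5` are one call), uptake 1, growth `g = 0` as the base with
sensitivity up to 2%.

The reference demography — 11.5 million population, 120,000 births/yr — is
a deliberate package choice (Belgian-scale, matching the price anchors).
All three condition *ratios* are invariant under jointly rescaling
population and births (tested), so this choice only moves absolute euro
streams relative to the cap. That matters in one visible place: with the
default demography the LCA upfront bill is ~EUR 1.07bn at `m = 1` but
dilutes to ~EUR 215m at `m = 5`, slipping just under the EUR 250m cap — so
condition 1 (and only condition 1) flips at `m = 5`. The scale-free
conditions and the dominance classification are unchanged for all
`m` in 1..5.

## What the simulator does and does not emulate

The generator reproduces the *structure* of the study conditions: backlog
plus geometric incident growth, annuity-due financing, social discounting,
a fixed yearly cap. It does not emulate stochastic epidemiology, age
structure, waiting-list dynamics beyond the equal `m`-split, uptake ramps,
outcome-contingent annuity reductions, or loss to follow-up. Feasibility
verdicts on real dossiers will additionally depend on exactly those
features, so a green screen here is a structural argument, not a forecast.

Numerical behaviours worth knowing:

* All currency arithmetic is double precision; rounding to whole euros
  happens only in display and reports.
* Boundary ties (ratios of exactly 1) count as passes, with a 1e-9 guard.
* `write_report()` renders ratio columns to 2 decimals and is
  byte-deterministic; configs round-trip through YAML at 15 significant
  digits.
* Fractional patients are intentional (expected-value model).

## Test problem sizes

The test suite checks the annuity/NPV identity over a grid of rates 0–25%
and maturities 1–30; validates stream semantics against a brute-force
per-patient ledger on over a hundred randomized small instances (up to 5
cohorts, up to 4 annuities) under both truncation policies; and exercises
the preset screens at the shipped 25-year, 6-scheme size. These sizes keep
the full suite in the tens of seconds while covering every operation; the
model's cost is linear in horizon x schemes, so larger sweeps scale
predictably.

## Known limitations

* The incidence-dominant regime's condition-2b behaviour is sensitive to
  whether the small residual backlog is included in the upfront maximum;
  published figure-level values for that regime are not reproduced by these
  semantics and are not claimed.
* Condition 3's default metric is exactly 1 by construction; it is a
  consistency audit, not a discriminating test. Use the `nominal_sum`
  metric to see the payer's concession.
* `window_only` truncation deliberately under-counts the payer's late
  liabilities; pair any headline number with a `full_ledger` run (one
  argument) when intergenerational burden is the question.
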