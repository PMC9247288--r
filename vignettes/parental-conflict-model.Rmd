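---
title: "A deterministic model of parental conflict over women's marriage age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic model of parental conflict over women's marriage age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marriagefitness)
```

## The model

In patrilocal, patrilineal societies, the age at which a woman marries
shapes the reproductive interests of both parents, and those interests need
not coincide. This package implements a deliberately minimal, closed-form
model of that tension. Everything is a deterministic function of one
variable, the woman's age at marriage $M$ (years); there are no stochastic
elements, no individual-level simulation, and no fitting to survey data.

Reproduction runs from the age at first pregnancy, $AFP = M + 1$, to a
fixed cessation age $k_1 = 35$. Total fertility is the reproductive span
divided by the inter-birth interval,

$$TF = \frac{k_1 - AFP}{IBI}, \qquad IBI = 2 + 0.25\,(M - 15),$$

where the IBI ramp encodes growing maternal autonomy (notably contraceptive
access) with later marriage: 2 years at $M = 15$, 3.25 at $M = 20$. Child
outcomes track maternal capital at marriage through the low-birth-weight
fraction $LBW = 0.9 - 0.1\,(M-15)$. Child mortality before age 5 couples
that prenatal disadvantage to a post-natal survival factor that also
improves with marriage age,

$$MR = LBW \cdot \bigl(k_2 - 0.065\,k_3\bigr), \qquad k_2 = 0.7,\; k_3 = M - 15,$$

and stunting assumes a quarter of low-birth-weight children catch up
postnatally: $S = 0.75 \cdot LBW$. Paternity uncertainty rises with the
wife's autonomy, $PU = 0.05\,(M-15)$ (0 at 15 years, 0.25 at 20). Fitness
is counted as offspring surviving to age 5:

$$LRF_{maternal} = TF\,(1 - MR), \qquad LRF_{paternal} = LRF_{maternal}\,(1 - PU).$$

Only the father pays the $PU$ term, so his fitness peaks at an earlier
marriage age than the mother's; the gap between the two argmaxes is the
model's measure of sexual conflict. An optional maternal-mortality term
$MMR = k_4 - k_5 M + k_6 M^3$ (constants 0.485, 0.033, 0.000023) multiplies
maternal fitness by $(1 - MMR)$; fathers are assumed not to remarry, so the
discount carries into paternal fitness too.

```{r basic}
fitness_at(c(15, 17.6, 20), fitness_params())
```

## Parameters and their defaults

All constants live in `fitness_params()` and can be overridden
individually. The ones that matter most:

* `reproductive_end_age` (35 y) and `first_birth_lag` (1 y) bound the
  reproductive span; at $M \ge 34$ fertility is 0 by construction, not an
  error.
* `ibi_intercept`/`ibi_slope` (2 y, 0.25 y/y) and `lbw_intercept`/
  `lbw_slope` (0.9, 0.1/y) are the autonomy and maternal-capital ramps,
  anchored at `reference_age` (15 y).
* `postnatal_intercept`/`postnatal_slope` (0.7, 0.065/y) set the
  post-natal mortality factor; with the LBW ramp they imply child mortality
  falling from 63% at $M = 15$ to 15% at $M = 20$.
* `mortality_multiplier` (1) scales the whole mortality product — 0.9 for
  the public-health intervention, 1.2 for an economic shock. Because the
  model is a pure product, scaling $MR$ is mathematically identical to
  scaling the post-natal factor while keeping the LBW association, which is
  how the interventions are described; the multiplier is applied before
  clipping.
* `pu_slope` (0.05/y), `pu_override`, `ibi_override`: the scenario levers.
  Overrides, when set, replace their ramp entirely at every age.
* `stunting_catchup_factor` (0.75) and `stunting_multiplier` (1; 3 when
  household monitoring removes compensatory childcare).

## Scenarios

`builtin_scenarios()` encodes the eight variants as declarative override
sets, applied with `apply_scenario()` (idempotent, strictly validated —
unknown field names are errors, not silently ignored). The education
scenario composes three overrides (IBI 3 y, mortality ×0.9, PU fixed at
0.2) rather than introducing a separate autonomy variable: autonomy is
implicit in the ramps. Monitoring-with-support deliberately carries **no**
mortality override — the marital household substitutes for the mother's
care, leaving mortality unchanged. User scenarios load from a strict JSON
config (`read_scenarios()`/`write_scenarios()`, round-trip lossless); JSON
was chosen over a bespoke format because it is bit-exact and diff-able.

## Optimization

The fitness landscape is piecewise smooth but its derivative is not
informative after clipping, so `optimize_marriage_age()` uses plain grid
search: inclusive grid, default 15–25 years in 0.1-year steps, argmax with
ties broken toward the lowest age. The default range covers every scenario
optimum (they reach past 22 years) at the precision the conflict table is
reported to; grid search is exact to the step, so no derivative-based
refinement is warranted. Two numerical choices deserve note:

* The grid is built by integer stepping (`min + step * 0:n`) rather than
  repeated addition, so 0.1-step grids carry no floating-point drift.
* The objective is extremely flat near its maximum — under the basic model
  it varies by less than 0.01 offspring across ~0.5 years. The lowest-age
  tie-break makes results deterministic, but reported optima should be read
  with that flatness in mind: this package's basic-model optima (17.3
  maternal, 16.2 paternal) sit ~0.3 years below the reference values (17.6,
  16.4) at nearly identical fitness, and the package validates optima to
  ±0.5 years while validating rates and fitness exactly at fixed ages.
  `conflict_table(..., at_ages = )` exists precisely to separate those two
  claims.

An optimum on the grid boundary triggers a warning, since it usually means
the range truncated the search (the monitoring-without-support optimum, for
instance, moves beyond 20 years).

```{r conflict}
format_conflict(conflict_table(c("basic", "education")))
```

## Degenerate inputs and clipping

All probabilities are clipped to $[0,1]$ after composition and the
post-natal factor is floored at 0; the ramps themselves extrapolate
linearly outside the 15–20-year range they illustrate, because several
scenario optima fall outside it. Marriage ages at or beyond
`reproductive_end_age - first_birth_lag` yield zero fertility and zero
fitness rather than an error; non-finite ages and non-positive inter-birth
intervals are rejected with input errors. Offspring counts are continuous
throughout — the model reports 9.5 or 7.5 offspring as rates, and rounding
to 1 decimal happens only in the reporting layer (`format_conflict()`, the
CLI pretty mode), never inside the model.

## Known divergences from the reference presentation

A handful of the originally reported cells cannot be produced by the stated
equations themselves, and this package reproduces the equations, not those
cells. `discrepancy_note()` evaluates the model at the *reference* optimal
ages and tabulates recomputed against reported values so every divergence
is explicit:

```{r note}
note <- discrepancy_note()
note[abs(note$difference) > 1, ]
```

The largest is the monitoring-without-support stunting cell, where the
stated threefold penalty implies ~42.8% against a reported 28.5%; the
public-health and education mortality cells differ by ~0.8 and ~1.3
percentage points from their recomputations, and that scenario family's
reported mortality range (70%→30%) is inconsistent with the equations'
63%→15%. None of these affect the model's qualitative conclusions, and no
parameter here was adjusted to paper over them.

## What the tests do and do not show

The test suite checks the closed-form values at fixed ages, optimizer
agreement with an independently coded brute-force oracle at a 10×-finer
step, structural properties (paternal ≤ maternal fitness with equality only
at zero paternity uncertainty; monotone responses to marriage age;
multiplier linearity before clipping; scenario idempotence and config
round-trips) over seeded random parameter draws, and the CLI/serialization
layer. Problem sizes are tiny by construction — the model is closed-form,
so every check evaluates in milliseconds on grids of at most a few hundred
points. Passing tests show the implementation is faithful to the stated
model; they say nothing about how well that stylized model — linear ramps,
a single decision variable, no individual heterogeneity, no remarriage,
polygyny or three-generation dynamics — describes any real population.
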