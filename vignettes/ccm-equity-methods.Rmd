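---
title: "Methods: equity-stratified cost-effectiveness of pneumonia CCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity-stratified cost-effectiveness of pneumonia CCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(ccmequity)
```

## The model

`ccmequity` evaluates strategies for scaling up community case
management (CCM) of childhood pneumonia across household wealth
quintiles (Q1 wealthiest … Q5 poorest).  The pipeline has four fitted
or configured components, combined deterministically.

### Cost per child treated

CCM cost splits into a constant direct antibiotic cost, US$ 0.27 per
child everywhere, and a non-antibiotic cost (staffing, infrastructure,
access) modelled as a straight line in the stratum's U5MR and fitted by
ordinary least squares to the 30 published calibration cells (five
countries × six strata).  The published cells are collinear to within
rounding — the OLS line reproduces every cell to within one cent — so
the line, not the cells, is shipped as the default model
(`default_cost_model()`, intercept ≈ 0.4948, slope ≈ 0.01070 US$ per
U5MR unit).  Money is computed at full precision and reported at two
decimals; comparisons against published cells use a ±0.01 US$
rounding tolerance.  Whether the original analysis used one global
line or per-country adjustments is not stated; the printed cells are
consistent with a single global line, which we adopt.

### Effectiveness and the potential impact fraction

Effectiveness observed in nine historical CCM trials (1986–1998)
declines with the U5MR of the study setting.  The default trendline is
constrained through the conventional anchor (U5MR 0, effectiveness
100 %), with closed-form slope `Σ x(y−100)/Σ x²` ≈ −0.4563 % per U5MR
unit; an unconstrained OLS line (intercept ≈ 75.6, slope ≈ −0.258) is
available as `form = "ols"`.  The exact functional form used by the
original authors is unpublished: the anchored line evaluated at U5MR
219 and gap-adjusted yields 50.03 %, versus a published 50.4 % for the
same stratum — a ~0.4-point residual we surface explicitly in the
acceptance tolerance rather than reverse-engineer.  Raw predictions
are clamped to [0, 100] (the anchored line crosses zero near U5MR
219), then adjusted upward by 50 % of the remaining gap to 100 %,
reflecting assumed improvements in programme quality since the trials.
The adjustment fraction is a parameter (`adjustment`, default 0.5).

The potential impact fraction of raising coverage from `c0` to `c1` at
adjusted effectiveness `e` (as a fraction) is

$$\mathrm{PIF} = \frac{e\,(c_1 - c_0)}{1 - c_0 e}.$$

No closed form is published for this step; we derived it from the
premise that *observed* deaths already reflect current coverage:
expected deaths are proportional to `c(1−e) + (1−c)`, and the PIF is
the relative change of that quantity.  It degenerates correctly
(`PIF = e·c1` at `c0 = 0`; `PIF = 1` at full coverage and perfect
effectiveness) and equals the exact expectation obtained by
enumerating the (covered, dies) outcome cells of a finite episode
cohort, which the test suite checks to 1e-9.

### Burden

Quintile deaths are `u5mr/1000 × births`, with the national birth
cohort split equally across quintiles by default (the source data do
not state quintile cohort sizes; population fifths are the natural
reading).  Pneumonia deaths apply a cause-of-death proportion, and
episodes divide by a case fatality rate (CFR):
`episodes = pneumonia_deaths / CFR`.

Cause proportions follow logit-linear trends in U5MR with softmax
renormalisation — the simplex constraint holds at every U5MR by
construction — with positive slopes for pneumonia, diarrhoea and
malaria and negative slopes for congenital, preterm and injury causes,
matching the qualitative pattern that infectious causes dominate in
poorer, higher-mortality strata.  CFR is a configurable parametric
curve (`linear` or `logistic` in U5MR), clamped positive and
non-decreasing.

### The scale-up engine

All four strategies allocate the *same* target — by default 10 % of
the nationally uncovered pneumonia episodes — so cost differences
reflect unit costs and lives differences reflect burden and
effectiveness:

- **inequity-promoting** fills the wealthiest uncovered pool first,
  spilling into the next quintile when a pool is exhausted;
- **equity-promoting** fills from the poorest;
- **equity-neutral** takes the band `[0.5 − step/2, 0.5 + step/2]` of
  the cumulative wealth-ordered uncovered distribution;
- **mainstream** distributes proportionally to current covered
  episodes (falling back to uniform shares, with a warning, if nothing
  is covered anywhere), capping at each pool and redistributing
  overflow.

Band boundaries and spillover are our constructions; the source only
names the strategies.  Lives saved are `Σ_q D_q · PIF_q`; cost per
life saved divides the scale-up cost by lives saved.
`lives_for_budget()` expands a strategy greedily at marginal cost
until the budget is spent or the uncovered population is exhausted
(fractional episode coverage allowed).  Because the PIF is linear in
the target coverage, marginal lives per newly covered episode are
constant within a quintile and greedy filling is exact; the naive
`budget / CPLS` figure can be recovered from `compare_strategies()`
output.  The engine contains no randomness.

## The synthetic world

Quintile U5MRs and per-child costs are published; quintile coverage,
CFR curves and cause proportions were published only as figures.  The
generator (`generate_country()`) and the shipped demo scenario
(`demo_scenario()`, also as
`inst/extdata/demo_scenario_synthetic.csv` — *synthetic* is in the
filename deliberately) therefore state a world with the documented
qualitative structure:

- coverage declining from Q1 to Q5 (steepest in Nigeria and Cambodia),
  except Egypt's documented non-monotone pattern — a mid-wealth excess
  over Q1 and a Q1→Q5 gap of exactly 7.6 percentage points;
- per-country logistic CFR curves rising steeply with U5MR (the
  original analysis likewise used region-specific CFR models).  The
  steepness implements the documented mechanism that the poorest
  strata's case fatality and burden offset their higher cost and lower
  effectiveness.  Parameters were fixed once, by analytic design,
  before the acceptance tests were first run;
- cause trends as above, with eight causes.

**What a green test establishes — and what it does not.**  The demo
scenario reproduces the qualitative findings: equity-promoting has the
lowest cost per life saved in all five countries, mainstream never
does, Bangladesh shows a near-tie between equity-promoting and
equity-neutral, Peru (the most inequitable country, QR ≈ 6.6) the
largest equity advantage, and the poorest Nigerian quintile is
marginally cheaper to treat in aggregate than Q4.  It does *not*
reproduce the published absolute cost-per-life-saved or
lives-per-US$1M numbers, whose inputs are unpublished; the shipped
numbers are the same order of magnitude but are not calibrated to
match and must not be quoted as the originals.  Known unrealism: with
a single smooth CFR(U5MR) curve per country spanning the full quintile
gradient, CFR levels in low-mortality quintiles (e.g. wealthier Peru)
come out lower than literature pneumonia CFRs; relative gradients, not
levels, carry the analysis.

The generator draws every stochastic quantity from one stream seeded
by a single integer; identical config means bit-identical output, and
generation restores the caller's RNG state.

## Numerical choices

- Simplex and inverse-property tolerances are 1e-9; OLS is delegated
  to `stats::lm` and checked against closed-form normal equations to
  1e-10 in the tests.
- Raw effectiveness is clamped to [0, 100] *before* the gap
  adjustment.
- Allocation conservation is enforced to within one episode;
  fractional episodes are allowed throughout (all quantities are
  expectations, not counts).
- `cfr_model()` clamps to `[cfr_min, cfr_max]` with
  `cfr_min = 1e-6 > 0` so `episodes = deaths/CFR` is always defined.
- Degenerate inputs fail fast with named errors: zero uncovered
  population, zero lives saved (no infinities returned), coverage or
  simplex violations naming row and field.

## Limitations

Beyond the synthetic-world caveats above: births are split equally
across quintiles unless overridden; no meta-analytic weighting of the
nine historical trials (none was used originally); no time dynamics,
discounting, or multi-intervention portfolios; and the run
configuration is JSON rather than YAML.
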