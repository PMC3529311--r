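# ccmequity

Equity-stratified cost-effectiveness analysis of community case
management (CCM) of childhood pneumonia.

## The problem

In many low- and middle-income countries, falls in under-five mortality
have been accompanied by *widening* gaps between rich and poor.  Health
planners deciding where to scale up an intervention therefore face a
real question: is it more cost-effective to extend coverage where
delivery is easy (the current "mainstream" pattern, which favours
wealthier strata), or to target the poorest, where the burden — and the
cost of delivery — are both highest?

`ccmequity` implements an EQUIST-style decision pipeline that answers
this for CCM of childhood pneumonia (antibiotic treatment delivered by
community health workers), at the resolution of household **wealth
quintiles** (Q1 = wealthiest … Q5 = poorest).  For every quintile *q*
of a country it combines five determinants:

- **U5MR** `u_q` — under-five deaths per 1000 live births;
- **cost per child treated** `k(u_q) = k_ab + a + b·u_q`, a constant
  antibiotic cost (US$ 0.27) plus a non-antibiotic cost that rises
  linearly with U5MR (fitted by OLS to 30 published calibration cells);
- **effectiveness** `E(u_q)`, a trendline through historical CCM trials
  constrained through (U5MR 0, 100 %), adjusted upwards by 50 % of the
  remaining gap to 100 %: `E_adj = E + 0.5·(100 − E)`;
- **current coverage** `c_q` and **burden**: observed pneumonia deaths
  `D_q` (from U5MR, births and cause-of-death proportions) and episodes
  `N_q = D_q / CFR_q`.

Raising coverage from `c_q` to `c_q + Δc` averts a **potential impact
fraction** of the observed deaths,

```
PIF = e·Δc / (1 − c_q·e),   e = E_adj / 100,
```

so lives saved are `Σ_q D_q · PIF_q` and the cost is
`Σ_q k(u_q) · N_q · Δc_q`.  Four strategies allocate the same national
scale-up target (10 % of uncovered episodes by default): mainstream
(proportional to current coverage), inequity-promoting (wealthiest
first), equity-neutral (middle band), equity-promoting (poorest first).

## Worked example

```r
library(ccmequity)

m_cost <- default_cost_model()       # OLS over the 30 published cells
round(cost_per_child(m_cost, 219), 2)
#> [1] 3.11                           # poorest Nigerian quintile, US$

m_eff <- default_effectiveness_model()
adjusted_effectiveness(m_eff, 219)
#> [1] 50.03022                       # percent; published value 50.4

compare_strategies(demo_scenario()[["Nigeria"]])
#>   country           strategy target_episodes    cost lives_saved
#> 1 Nigeria         mainstream         1424901 2854947    7541.419
#> 2 Nigeria inequity_promoting         1424901 2415777    3894.446
#> 3 Nigeria     equity_neutral         1424901 3055890    7918.109
#> 4 Nigeria   equity_promoting         1424901 4427560   25645.361
#>   cost_per_life_saved lives_for_budget budget_capped
#> 1            378.5690         2641.526         FALSE
#> 2            620.3133         1612.089         FALSE
#> 3            385.9368         2591.098         FALSE
#> 4            172.6457         5792.210         FALSE
```

Each row is one scale-up strategy applied to the same target (10 % of
the uncovered pneumonia episodes nationally): total cost of the newly
treated children, expected lives saved, US$ per life saved, and lives
saved if a fixed US$ 1 million budget is spent under that strategy.
Here the equity-promoting allocation saves a life for US$ 173 — less
than half the cost of the mainstream pattern — because the poorest
quintile's case fatality and burden outweigh its higher delivery cost
and lower effectiveness.  This ranking holds in all five shipped demo
countries.

Note the demo scenario is *synthetic*: quintile U5MRs and costs are the
published values, but coverage, CFR curves and cause proportions are
plausible stand-ins (the originals were published only as figures); see
`vignettes/ccm-equity-methods.Rmd`.

## Command line

```sh
inst/cli/ccmequity compare --country Nigeria --out results.csv
inst/cli/ccmequity run --config config.json --out-dir out/
inst/cli/ccmequity synth --seed 7 --out synthetic_country.csv
```

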