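---
title: "Modelling diets under blue-water constraints: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diets under blue-water constraints: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterdiet)
```

## The problem

Irrigation claims roughly half of India's useable freshwater (557 of
1123 BCM/year, 49.6%), and with the population projected to grow from 1.15
billion (2010) to 1.40 billion (2025) and 1.64 billion (2050), holding the
national irrigation volume constant forces per-person blue-water use down by
18.0% and 30.3% respectively. `waterdiet` asks how population dietary
patterns can absorb those cuts: it perturbs each baseline pattern as little
as possible while meeting a common per-person blue-water level, WHO nutrient
guidelines and unchanged dietary energy, then prices the consequences in
greenhouse-gas emissions and in life-years via a cohort life table.

```{r}
wb <- water_budget()
demand_share(wb)          # current irrigation share of useable water, %
future_demand_share(wb)   # 2050 share if diets do not change, %
```

## The optimisation model

For one pattern with baseline consumption $b_g$ (g/day) over food groups
$g$, the optimiser solves

$$\min_{c \ge 0} \; \sum_g w_g \left( 100\,\frac{c_g - b_g}{b_g} \right)^2$$

subject to

* **water**: $\sum_g c_g\,\mathrm{bwf}_g \le L$,
* **energy**: $\sum_g c_g\,e_g = E_0$ (the baseline energy, relative
  tolerance $10^{-6}$),
* **WHO rules**: carbohydrate 55–75% of energy, fat 15–30%, protein
  10–15%, free sugars ≤ 10% of energy, sodium ≤ 2000 mg/day, fruits plus
  vegetables ≥ 400 g/day (all defaults of `nutrient_rules()`, each
  configurable).

The weights $w_g$ are expenditure share over |own-price elasticity|,
rescaled to mean 1: foods that absorb much of the budget but respond little
to price are expensive to move. Squaring percentage changes penalises
increases and decreases alike.

**The common level $L$.** Targets are equitable: every pattern faces the
same per-person level $L = (1-r)\sum_i s_i\,\mathrm{bwf}_i$, where $s_i$
are population shares and $r$ the scenario reduction. High-footprint
patterns therefore cut more. The water constraint is an *inequality*
(`bwf <= L`), matching the "minimum X% reduction" framing: a pattern
already below $L$ is not forced up to it, so the population-weighted mean
reduction can exceed $r$; it equals $r$ exactly when the constraint binds
everywhere. A low-footprint pattern can still *gain* water when the
fruit-and-vegetable floor forces new consumption — the behaviour the
low-diversity pattern shows under the milder scenario.

**Solver.** With energy pinned, every constraint is linear in $c$ and the
objective is a positive-diagonal quadratic, so the problem is a convex QP.
It is solved in percentage-change coordinates $u_g = 100(c_g-b_g)/b_g$
(where the objective Hessian is the identity-scaled weight vector, i.e.
perfectly conditioned) by an augmented Lagrangian with an L-BFGS-B inner
loop and analytic gradients. Once the outer violation falls below $10^{-2}$
the active set is solved exactly through its KKT system; the polished point
is accepted only if it passes the full KKT test (primal feasibility,
non-negative inequality multipliers, non-negative reduced gradients at
bounds), in which case convexity makes it the global optimum. Feasibility
is declared at $10^{-6}$ relative tolerance per constraint, re-checked
independently of the solver. The multi-start loop (default 20 starts:
baseline first, then log-normal jitter with sd 0.2 on the log scale)
guards against inner-solver failures; duals from the first certified solve
warm-start the rest. Food groups with zero baseline are frozen at zero,
since a percentage change from zero is undefined.

Genuinely infeasible instances (the sampled water target below what the
rules allow) stall at a positive minimal violation; the solver detects the
stall, stops early and reports `feasible = FALSE` with the best attempt and
a full constraint report.

## The health model

Dietary change feeds three exposures — red meat, fruit, vegetables
(g/day differences of tagged food groups). Exposure–response functions are
log-linear: a change $\Delta$ multiplies an outcome's risk by
$\mathrm{RR}^{\Delta/u}$, and multiple exposures on one outcome multiply.
Outcomes are CHD, stroke, type 2 diabetes, and cancers of the
mouth/pharynx/larynx, oesophagus, lung, stomach and colorectum. The shipped
coefficients (`default_exposure_responses()`) are configuration
placeholders on the scale of the published evidence (e.g. fruit 0.95 per
100 g/day for CHD), not estimates of record; any catalogue can be supplied
through the YAML config.

Risk changes phase in along normal-CDF lag curves,
$f(t)=\Phi((t-\mu)/\sigma)$, anchored to zero at adoption. Defaults:
$\mu=5,\sigma=2.5$ years for cardiometabolic outcomes, $\mu=15,\sigma=5$
for cancers, evaluated mid-year. Setting `lags = NULL` applies the full
effect immediately; the lagged model converges to it as $\mu,\sigma \to 0$.

The life table is an IOMLIFET-style closed single-sex cohort, ages 0–100
with an open final class, no births, immediate full adoption of the diet at
baseline. Mortality is projected from three historical years by
least-squares quadratics in calendar time per age (exact through three
points), floored at zero; cause-specific rates are rescaled proportionally
wherever projection would push their sum past the all-cause rate. Annual
survival uses the mid-interval actuarial transform $s=(2-M)/(2+M)$, and
life-years are mid-year person-years summed over the horizon (40 years by
default). An outcome's impact enters as
$M' = M_{\mathrm{all}} + M_{\mathrm{cause}}(\mathrm{RR}_t - 1)$, floored at
zero. Results are scaled to a baseline population of 100 000.

Per-outcome results apply one outcome's risk at a time;
`life_years_total` is their sum and `life_years_joint` applies all
outcomes together. The joint run is the headline (the two agree within a
few percent at realistic risk sizes because the model is nearly linear in
$\mathrm{RR}-1$); both are reported so the decomposition rule is never
hidden.

## Uncertainty propagation

`run_mc()` repeats the whole chain (default 1000 repetitions; each
repetition re-optimises every pattern best-of-20): consumption is drawn
Normal(mean, between-person SD) truncated at zero; water footprints
Normal(mean, spatial SD) truncated at zero; expenditure shares
Normal(share, SE) truncated to [0, 1]; log relative risks Normal with SD
$(\log \mathrm{ci_{high}} - \log \mathrm{ci_{low}})/(2 \times 1.96)$; and
nutrient composition, GHG factors and elasticities Uniform within ±10% of
centre (signs preserved; energy is recomputed from the perturbed
macronutrients so Atwater consistency survives sampling). The common level
$L$ and all reductions are recomputed per repetition against that
repetition's own sampled baselines, keeping each repetition internally
consistent; comparing against the central baselines instead is a one-line
change in the caller. Repetitions with any infeasible pattern are counted
and excluded. Summaries are means, medians and empirical 2.5/97.5
percentiles (interpolated order statistics, R type 7); the intervals are
percentile intervals and labelled as such. Child seeds derive
deterministically from the master seed, so `(seed, n_reps)` fixes the
output bit-for-bit.

## The synthetic study

No public microdata exist for the survey behind the five Indian dietary
patterns, so `generate_study()` builds inputs with the statistical
structure the analysis assumes. Choices, made once:

* **Food groups (36).** Twelve categories (cereals, legumes, vegetables,
  fruits, red meat, poultry, dairy, fish, egg, oils, sugar, other) with
  per-gram attributes drawn uniformly within category plausibility ranges;
  energy is exactly the Atwater value of the drawn macronutrients. Water
  footprints span nearly two orders of magnitude (vegetables ~0.02–0.12 L/g
  to irrigated cereals ~0.45–1.0 L/g), so water-driven substitution has
  room to work; one cereal is always drawn near the top of the range to
  play irrigated rice. Spatial water SDs default to 20% of the mean
  (the source data report state-level spread without numbers); expenditure
  shares normalise to 0.95 with 10% SEs; elasticities are uniform in
  [−1.5, −0.3].
* **Patterns (5).** Archetypes echo the published pattern families
  (rice-dominated low diversity, rice and fruit, wheat and pulses, wheat
  rice and oils, rice and meat). Consumption is drawn log-normally around
  category archetypes, rice-leaning archetypes concentrate cereal intake on
  the thirstiest cereals, and each draw is scaled to an energy target and
  rejection-sampled (≤1000 attempts) until pattern-level energy
  (2300–3400 kcal/day), blue water (550–900 L/day) and GHG
  (1.8–3.5 kgCO2e/day) all sit inside the magnitudes of the baseline study
  population. Between-person SDs are 25% of the mean with a 1 g/day floor —
  the survey's individual-level SDs are not published, so this placeholder
  is treated as data by the Monte Carlo stage.
* **Life tables.** Three historical years (1990/2000/2010), Gompertz-like
  adult hazard rising monotonically above age 30, an infant component, a
  gently declining secular trend, and cause fractions within [0.005, 0.15]
  of the all-cause rate with mild cardiometabolic drift.

What the generator does *not* emulate: the actual food list and
footprints, regional heterogeneity beyond a single spatial SD, correlation
between consumption and footprints, seasonal or socio-economic structure.
Passing tests therefore certify the *machinery* — constraint attainment,
oracle agreement, propagation laws — not the published point estimates,
which depend on unreleased microdata.

A three-food analytic fixture (`make_analytic_fixture()`) reduces the
optimisation to two equality constraints with unit weights; its exact
optimum follows from a 2×2 Lagrange system (`analytic_fixture_optimum()`)
and anchors the solver tests at 1e-4 relative objective tolerance. A
closed-form LP bound (`min_bwf_at_energy()`: all energy from the food with
the least water per kcal) certifies declared infeasibility.

## Numerical choices and limitations

* Atwater factors 4/9/4 kcal/g (4 for free sugars, counted inside
  carbohydrate and reported separately as their own energy fraction).
* Fraction constraints are expressed against baseline energy $E_0$; the
  energy equality makes this equivalent to bounds on realised fractions.
* Equality tolerance $10^{-6}$ relative (configurable); inequality
  tolerance $10^{-6}$ relative with constraint scales $\max(1, |b|)$.
* Percentile type 7 (R default) for Monte Carlo intervals.
* Scenario reductions (0.180, 0.303) are taken as printed constants rather
  than recomputed from rounded population projections, which do not
  reproduce them exactly.
* Single-sex life tables: outputs are per 100 000 total population, so sex
  stratification would only re-weight inputs the synthetic generator does
  not resolve anyway.
* The default test and example problem sizes (50-repetition constraint
  checks, 200-repetition interval comparisons) were chosen as the smallest
  sizes at which the stochastic properties under test are stable; the
  shipped defaults for real analyses remain 1000 repetitions × 20
  restarts.

Known limitations: no green/grey water, no land use, no morbidity/DALYs,
no age-specific dietary change, closed population without births, and
exposure–response coefficients treated strictly as configuration. Reported
intervals propagate input uncertainty only — structural uncertainty (model
form, lag shapes, decomposition rule) is not sampled.
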