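---
title: "Methods: a Markov cohort cost-utility model for PCSK9 inhibitor regimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model for PCSK9 inhibitor regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsk9cua)
```

## Scientific problem

PCSK9 inhibitors (the monoclonal antibodies evolocumab, alirocumab and
tafolecimab, and the siRNA inclisiran) lower LDL cholesterol substantially when
added to statins, but at drug prices that may not justify the cardiovascular
events avoided. `pcsk9cua` implements a Markov cohort state-transition model
that compares nine PCSK9-inhibitor dosing regimens added to statin therapy
against statins alone in a hypercholesterolemia cohort (start age 60.6 years,
baseline LDL-C 3.13 mmol/L), over a 30-year horizon with 1-year cycles and 5%
annual discounting of both costs and QALYs.

## Model structure

Eleven health states in fixed order:

```{r}
health_states()
```

`MI_y1`, `MI2_y1`, `IS_y1`, `IS2_y1` are *tunnel states*: they carry the
first-year cost and utility of an acute myocardial infarction (MI) or ischemic
stroke (IS) and, absent a new event, are left after exactly one cycle for the
corresponding post-event state. `CVDeath` and `NonCVDeath` are absorbing.

### Event rates and treatment effect

Baseline annual event rates $r_0$ (nonfatal MI 0.009, nonfatal IS 0.004,
revascularization 0.012 per person-year) are population-adjusted and then
translated into treated rates through per-mmol/L rate ratios:

$$
r_a = r_0 \cdot \mathrm{HR}_{\text{age}}^{\Delta \text{age}} \cdot
      \mathrm{RR}^{\Delta \text{LDL,pop}}, \qquad
r_{tx} = r_a \cdot \mathrm{RR}^{\Delta \text{LDL,tx}}, \qquad
P = 1 - e^{-r t}.
$$

In the base case the population adjustment is an identity
($\mathrm{HR}_{\text{age}} = 1$, reference age and LDL-C equal to the cohort's),
so the treated rate reduces to $r_0 \cdot \mathrm{RR}^{\Delta\text{LDL}}$ with
$\Delta\text{LDL}$ the regimen's absolute LDL-C reduction in mmol/L. Rate
ratios per 1 mmol/L: MI 0.74, IS 0.80, revascularization 0.76, vascular death
0.86.

### Competing risks and event routing

Within a cycle, all exit rates from a state compete: the total exit
probability is $1 - \exp(-\sum_j r_j t)$, apportioned across destinations in
proportion to the rates. One event is modelled per cycle. A first MI from any
MI-naive state enters `MI_y1`; an MI with MI history enters `MI2_y1`
(analogously for stroke). Cross-pathway events are allowed: a post-stroke
patient's first MI goes to `MI_y1`, and vice versa. Event rates in post-event
states are scaled by history multipliers (recurrent MI 1.13, MI after 2+ MIs
1.19, recurrent IS 1.13, IS after 2+ IS 1.36), and all event rates in tunnel
states carry an additional 1.50 multiplier for an event in the past year.
A repeat event occurring inside a 2+ tunnel re-enters that tunnel, restarting
its one-year clock.

Revascularization is an *expected-event overlay*, not a state: each cycle,
start-of-cycle alive occupancy accrues expected revascularizations at the
treated rate, contributing a one-off cost and disutility.

### Mortality

Cardiovascular and all-cause mortality come from a life table indexed by
integer age (floor lookup, clamped at the last row). The LDL-C effect on
vascular death ($\mathrm{RR} = 0.86$ per mmol/L) applies to the CV component
only, with a 1.31 multiplier during the first post-event year; non-CV
mortality (all-cause minus CV) is untreated. A rate ratio for any-cause death
(0.90) is registered and sampleable for completeness but is intentionally not
wired into the engine: the mortality contract routes treatment benefit through
vascular death alone, so varying it leaves the ICUR unchanged.

## Economics

Costs (2021 USD): statins 846.1/year for all alive states; MI 3275.3 first
year then 2332.7/year; IS 2569.3 then 1352.1/year; revascularization 10187.1
per event; CV death 2332.7 once, on the incremental mass entering `CVDeath`.
Drug costs are per-pen prices times pens per administration times
administrations per year (e.g. evolocumab 140 mg Q2W: 1 pen × 26; inclisiran
300 mg Q6M: 3 administrations in year 1, 2 thereafter). Utilities: baseline
0.964; event-year and post-event decrements per state; one-off disutilities
for injections and revascularizations.

Half-cycle correction is trapezoidal: continuous payoffs accrue on the average
of start- and end-of-cycle occupancy, discounted at $(1+d)^{-k}$; one-off
payoffs (CV-death cost, revascularization overlay) are discounted mid-cycle at
$(1+d)^{-(k-0.5)}$.

```{r}
params <- base_case_parameters()
out <- run_strategies(params, c("Statins alone", "Evolocumab 140 mg Q2W"))
icur(out[["Statins alone"]], out[["Evolocumab 140 mg Q2W"]])
```

## Frontier and uncertainty analyses

`frontier()` removes strictly dominated strategies, then iteratively removes
extended-dominated ones until frontier ICURs are non-decreasing; it is tested
against an exhaustive convex-hull oracle. `one_way_sa()` produces tornado
ranges (distribution bounds where defined, ±20% otherwise; discount rates
jointly over 0–8%). `run_psa()` draws full parameter sets (normal, lognormal,
gamma-on-magnitude, beta families fitted by method of moments from base and
95% interval; sd = width/3.92) and `ceac()` computes acceptability as the
per-draw argmax of net monetary benefit. `scenario_horizons()` re-runs at
shorter horizons; `price_threshold()` exploits the affinity of lifetime cost
in the per-pen price to solve the willingness-to-pay-constrained price in
closed form, cross-checked by bisection.

```{r}
fr <- frontier(run_strategies(params), reference = "Statins alone")
fr
```

## Synthetic data and its limits

`make_life_table()` generates a Gompertz–Makeham table (all-cause rate
$0.001 + 2\times10^{-5} e^{0.095 \cdot \text{age}}$, CV fraction linear from
0.2 at age 40 to 0.45 at age 100). This is a plausible stand-in, not a
national life table: absolute costs, QALYs and ICURs therefore depend on it,
while the model's comparative structure (which regimens are dominated, how
ICURs move with horizon and price) does not. `make_test_parameters()` exposes
three difficulty tiers — `paper_like` (full problem), `simple` (3 strategies,
3 cycles, hand-checkable) and `degenerate` (no events, constant mortality),
the last matching an analytic annuity closed form to 1e-10.

Typical sizes: one 30-year cohort trace runs in ~5 ms; a 10-strategy,
1000-draw PSA in about a minute.
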