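---
title: "The evocea cohort model: structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evocea cohort model: structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evocea)
```

## The decision problem

`evocea` models secondary cardiovascular prevention in survivors of
acute myocardial infarction (AMI): does adding the PCSK9 inhibitor
evolocumab to background statin therapy buy enough quality-adjusted
life years (QALYs) to justify its cost, from the perspective of the
Chinese healthcare system (direct medical costs) or of a private payer
(direct plus indirect costs such as caregiver wage loss and informal
care)?  The package answers this with a discrete-time Markov cohort
state-transition model and the standard decision-analytic summaries:
incremental cost-effectiveness ratios (ICERs), net monetary benefit,
tornado-style one-way sensitivity analysis, probabilistic sensitivity
analysis (PSA) with cost-effectiveness acceptability curves, and
scenario sweeps.

## State space

A living patient is described by an event history — how many
myocardial infarctions and how many strokes they have survived, each
counted 0, 1 or "2+" — and a phase: the one-year *acute tunnel* after a
new non-fatal event, or the *chronic* post-event phase.  Tunnel states
are occupied for exactly one cycle.  States carrying both an MI and a
stroke history are the *composite* states that preserve the memory of
both sequelae.  Two absorbing states, cardiovascular (CV) death and
non-CV death, complete the space: 8 chronic, 12 acute and 2 death
states.

```{r}
sp <- build_state_space()
table(sp$phase)
```

Three structural rules are enforced by construction and checked by the
test suite:

* every transition matrix row sums to one (to $10^{-12}$);
* a new event always routes through the corresponding acute tunnel —
  no transition skips it, and tunnel states never self-loop;
* death states only transition to themselves.

Histories deeper than two events of a type collapse onto the 2+ level;
a same-type recurrence *during* a 2+ tunnel year is folded into the
tunnel exit rather than allowed to self-loop (the patient is already in
the "year after ≥2 events" state, and strict tunnel semantics are worth
more than the numerically negligible distinction).  Which
acute-over-post composites exist is configurable
(`build_state_space("minimal")`), since published diagrams of this
model family differ on exactly this point; in the minimal set, deeper
cross-history events collapse onto the pure acute 2+ states.

Coronary revascularization (RV) is deliberately *not* a health state:
it is a procedure, charged as an expected per-cycle event cost at its
own (treated or baseline) rate.

## Risks and treatment effects

Baseline event rates are annual rates per 100 patient-years; the
constant-hazard conversion $p = 1 - e^{-r/100}$ turns them into cycle
probabilities.  States with a prior-event history have their rates
scaled by multiplicative adjustment factors (prior stroke 1.5, 2+
events 1.4 by default, stacking multiplicatively across distinct
histories).  These defaults are **synthetic**: the source analyses keep
their values in unpublished supplements, so the packaged values are
plausible round numbers held in a parameter block explicitly named
`adjustment_synthetic`, with ranges so that sensitivity analyses
exercise them.

Two interchangeable engines translate trial evidence into treated-arm
rates:

* **Clinical-endpoint engine** (`endpoint_HR`): each event rate is
  multiplied by its hazard ratio, with separate first-year
  (model cycle 0) and later-year values.  The combined MI/stroke
  mortality HR is not published; the engine therefore defaults to a
  *null* CV-death effect (HR 1.0), stored as an ordinary parameter row
  so users with better evidence can override it.  This is the single
  most consequential default in the package: it makes the
  endpoint-engine QALY gains, and hence its ICERs, conservative.
* **LDL-C-reduction engine** (`ldl_RR`): each rate is multiplied by
  $\mathrm{RR}^{\Delta\mathrm{LDL}}$, the meta-analytic rate ratio per
  1 mmol/l of LDL-C reduction raised to the achieved absolute
  reduction, with CV death at RR 0.86 in all years.  At
  $\Delta\mathrm{LDL} = 1$ the two engines coincide exactly when fed
  the same ratios — a machine-precision identity the acceptance tests
  assert.

The only modelled adverse event is the mild injection-site reaction:
2.1% over 26 months, annualized by constant hazard, with a one-off
disutility of 0.0003 per event in the evolocumab arm.

### Mortality

Non-CV mortality comes from a life table; CV mortality is anchored to
the cohort's observed CV death rate at the starting age and follows the
life table's age trend thereafter:
$p_{cv}(a) = p_{cv}^{0} \cdot m_{cv}(a)/m_{cv}(a_0)$, and likewise for
the non-CV component (anchored to all-cause minus CV when the cohort
reports an all-cause rate).  This keeps cycle 0 exactly on the cohort's
published rates while letting mortality age realistically.  Ages
outside the table are a hard error — the model never extrapolates
mortality silently.  When competing probabilities in a row would exceed
one, death keeps priority and the non-fatal event probabilities are
rescaled proportionally; the residual stays in (or, for tunnels, exits
to) the appropriate chronic state.

## Economics

Costs attach to states and events in CNY (2022 values; USD appears only
in summaries at 6.726 CNY/USD):

* acute tunnel states carry the year-1 (hospitalization) event costs,
  chronic states the beyond-year-1 maintenance costs;
* a composite state takes the **highest** cost and the **lowest**
  utility of its components — except where the input table prints an
  explicit combined-state row, which then overrides the max rule;
* terminal CV-death costs are charged once, on the transition into CV
  death, attributed by the departing state's history (acute phase
  decides; mixed chronic histories take the mean of the MI and stroke
  death costs — a documented choice, since the single CV-death rate
  carries no cause label);
* both arms pay the statin cost while alive; the evolocumab arm adds
  the regimen's annual drug cost until death or horizon end (no
  discontinuation model — persistence is considered internal to the
  trial-derived effects);
* death states accrue nothing; non-CV deaths are costless.

The published annual evolocumab costs (CNY 7405 for 140 mg every two
weeks, 10365 for 420 mg monthly) are carried as the package defaults.
`annual_drug_cost()` reproduces them within 0.05% from the 283.8
CNY/140 mg list price under a 14-day / 30-day dosing calendar and
exists for price sweeps; the printed values are kept as inputs because
no stated dosing calendar reproduces both exactly.

Hospital-tier scenarios scale the *hospitalization* (acute-year and RV)
direct costs by a tier multiplier; the packaged tier multipliers
(0.55–1.45 from county to national referral hospitals) are synthetic
placeholders spanning the reported relative cost spread.

## Accrual, discounting, summary

Rewards use the half-cycle correction: each cycle accrues on the mean
of start- and end-of-cycle occupancy, including cycle 0 and including
drug costs (a config switch, `drug_hcc`, reverts drug cost to
start-of-cycle occupancy since the convention is not universal).
Cycle-$t$ rewards are discounted by $1/(1+d)^t$ (annual-start
convention; 5% for both costs and QALYs in the base case).  The cohort
enters in the chronic Post-MI state — the population is AMI survivors
starting therapy after their index event — and the entry state is
configurable.

ICER classification against GDP per capita (CNY 85,698) follows the
three-band rule: below 1× GDP highly cost-effective, between 1× and 3×
GDP (boundaries *inclusive*) cost-effective, above not; the
willingness-to-pay (WTP) threshold is 3× GDP = CNY 257,094.  Dominance
is reported as a label, never as a negative ratio.

## Sensitivity analysis machinery

**One-way DSA** re-runs the model at each parameter's bounds:
efficacy, utility and baseline-rate parameters at their 95% intervals,
costs at ±25%, the discount rate over 0–8%.  The tornado table is
sorted by absolute ICER spread with name-alphabetical tie-breaking, so
output order is deterministic.

**PSA** draws all parameters independently: lognormal rows by matching
the median to the point value and the 95% quantiles to the interval;
gamma and beta rows by moment matching with
$\sigma = (\text{high} - \text{low})/3.92$; disutility rows are fitted
on their magnitude and negated; infeasible fits (a beta mean outside
(0,1), variance too large) are errors naming the parameter.  No
correlation structure is imposed because none is reported.  The CEAC
grid runs from 0 to 3× the WTP in 101 steps and always contains the
WTP itself.  Draws are seed-deterministic; a model failure on a draw is
recorded and skipped, never silently imputed.

**Scenarios** sweep horizon (5–35 years), starting age, discount rate
(3/5/6%), statin annual cost at the centralized-procurement bounds
(118.86 / 5470.28 CNY), evolocumab price factors and hospital tiers.

## The synthetic data module

Every input is generated in code so the full pipeline runs with no
download:

* `gen_life_table()` — Gompertz all-cause mortality,
  $q(a) = 1 - \exp(-Ae^{B(a-40)})$, calibrated so all-cause mortality
  near age 61 matches the post-AMI cohort's 3.1 per 100 patient-years,
  with a CV fraction rising from 0.3 at age 40 to 0.5 at 90.  The seed
  jitters level and slope by ±2%.  It emulates the *shape* of a
  national life table for a sick cohort; it is not a population life
  table, and the package treats it as a stand-in.
* `gen_default_parameters()` — the complete published input table
  (rates, effects, costs, utilities, distributions, ranges), keyed by
  its verbatim row labels, plus the synthetic adjustment factors and
  threshold constants.
* `gen_population()` — the four cohort profiles: the registry cohort
  (start age 61, endpoint engine), the two hospital-database cohorts
  (start age 69, LDL engine with a lifetime 66% LDL-C reduction from
  synthetic baseline means of 2.8 and 2.2 mmol/l), the Chinese trial
  cohort (start age 61, measured reductions 1.88 / 1.69 mmol/l per
  regimen), and a full-trial profile (start age 63, trial event rates,
  runnable under either engine) for the engine comparison.  Baseline
  event rates for the database and trial-LDL cohorts reuse the registry
  rates as stand-ins, since their own rates are unpublished.

What passing tests on these inputs shows — and does not show: the
engine conserves probability mass, matches an independent
individual-level microsimulation, responds to horizon, discounting and
prices in the published directions, and reproduces every piece of
self-contained published arithmetic.  It does **not** certify the
absolute ICER levels, which depend on the unpublished supplementary
baselines (cohort event-rate tables, the real life table, the combined
CV-death HR); with the conservative null CV-death HR the endpoint
engine's incremental QALYs sit well below the published ones, and its
ICERs correspondingly above.

## Numerical choices and degenerate inputs

* Cycle length is one year, matching the one-year acute states and the
  per-patient-year rates.
* Probability normalization: death first, then proportional rescaling
  of event probabilities; rows failing to sum to one within $10^{-12}$
  abort with the state named.
* Zero-mortality life tables (used in degenerate tests) leave the
  age-trend scaling at one instead of dividing by zero.
* `rate_to_prob` saturates at double precision for enormous rates.
* All internal arithmetic is full precision; rounding is presentation
  only (2 decimals for CNY, nearest integer for headline USD).
* The microsimulation oracle propagates state *counts* with multinomial
  sampling — the exact aggregate of independent patient-level paths —
  and is compared at 3 Monte-Carlo standard errors plus one patient of
  mass (binomial counts are integers, so a state whose expected
  occupancy is a fraction of one patient cannot be matched closer than
  $1/N$).

## Problem sizes in the test suite

The packaged checks run a 22-state space over 25-year horizons; the
conservation property is exercised over 1,000 randomized
configurations at horizons of 3–10 years, the microsimulation oracle
at 100,000 patients, and the PSA reproducibility checks at 1,000
draws (the analysis default is 10,000).  These sizes keep the whole
suite under a minute of compute while leaving every property
statistically sharp.

## Known limitations

* The combined CV-death HR of the endpoint engine is a null default,
  not an estimate; results under that engine are conservative and
  should be read as such.
* History adjustment factors, hospital-tier multipliers, database
  cohort baselines and the life table are synthetic stand-ins,
  clearly flagged, and replaceable through the workspace files.
* All parameters are drawn independently in PSA; correlated draws are
  out of scope.
* No treatment discontinuation, sub-annual cycles, or budget-impact
  analysis; costs are accepted as already-2022 CNY (no CPI engine).

## A minimal run

```{r, eval = FALSE}
params <- gen_default_parameters()
lt <- gen_life_table(seed = 1)
res <- run_cea(gen_population("PEACE"), params, lt,
               run_config(perspective = "healthcare",
                          regimen = "Q2W_140"))
print(res)
```
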