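# evocea

A Markov cohort state-transition model for the cost-effectiveness of
adding the PCSK9 inhibitor **evolocumab** to statin therapy in
survivors of acute myocardial infarction (AMI), from the Chinese
healthcare and private-payer perspectives.

The package is for health economists and HTA analysts who want a
fully scriptable, testable implementation of this model family:
every input is a plain-text parameter file, every analysis is a
function, and a synthetic-data module generates a complete default
workspace (life table, cohort profiles, parameter table) so the whole
pipeline runs self-contained.

## The model in brief

A cohort of AMI survivors moves through annual cycles over 22 health
states defined by event history — myocardial infarctions and strokes
counted 0 / 1 / 2+ — and phase: a one-year **acute tunnel** after each
new non-fatal event, a **chronic** post-event phase, and absorbing
cardiovascular / non-cardiovascular death.  Composite states preserve
the memory of both an MI and a stroke history; they take the *lowest*
utility and the *highest* cost of their components.  Coronary
revascularization is a costed procedure, not a state.

Treatment benefit enters through one of two engines:

* **clinical endpoints**: per-event hazard ratios *HR* (first year vs
  later years), treated rate `r_tx = r0 · HR`;
* **LDL-C reduction**: meta-analytic rate ratios per 1 mmol/l of LDL-C
  lowering, treated rate `r_tx = r0 · RR^ΔLDL-C`.

Per cycle the model rebuilds the transition matrix at the cohort's
current age (life-table mortality), advances occupancy, and accrues
half-cycle-corrected costs and QALYs discounted at rate *d*:
`PV = Σ_t x_t / (1+d)^t`.  The headline summary is the incremental
cost-effectiveness ratio `ICER = ΔC/ΔE`, classified against GDP per
capita (CNY 85,698) with willingness-to-pay 3×GDP = CNY 257,094 per
QALY, plus net monetary benefit `NMB = λ·ΔE − ΔC`.  One-way DSA
(tornado), probabilistic SA (Monte Carlo over lognormal/gamma/beta
parameter distributions, CEAC, CE-plane) and scenario sweeps (horizon,
starting age, discount, drug prices, hospital tier) complete the
apparatus.  See the vignette in `vignettes/evocea-model.Rmd` for the
full model description and every numerical convention.

## Worked example

```r
library(evocea)

params <- gen_default_parameters()   # published inputs + synthetic defaults
lt     <- gen_life_table(seed = 1)   # synthetic Gompertz life table
res    <- run_cea(gen_population("PEACE"), params, lt,
                  run_config(perspective = "healthcare",
                             regimen = "Q2W_140"))
print(res)
```

```
CEA: PEACE, Q2W_140, healthcare perspective
  cost (CNY)  statins 224025.29 | +evolocumab 271885.22 | delta 47859.93
  QALYs       statins 8.2738 | +evolocumab 8.4086 | delta 0.1348
  ICER: 355004.05 CNY/QALY (not_cost_effective)
```

Reading this: over a 25-year horizon at 5% discounting, statins alone
cost ~224k CNY and yield 8.27 discounted QALYs; adding biweekly
evolocumab costs ~47.9k CNY more and buys 0.135 extra QALYs, i.e.
~355k CNY per QALY — above the 257,094 CNY/QALY threshold under this
configuration.  The endpoint engine here runs with a deliberately
conservative *null* CV-death hazard ratio (the combined MI/stroke
mortality HR is unpublished; set the `effect_hr` /
`Cardiovascular-related death` parameter row to use an estimate),
which is why the QALY gain is modest.

Comparing the two effect engines on the shared trial cohort:

```r
compare_effect_engines(params, lt)
```

```
    perspective regimen icer_endpoint_hr icer_ldl_rr ratio
1    healthcare Q2W_140           712513      212496 3.353
2    healthcare  QM_420          1066014      318423 3.348
3 private_payer Q2W_140           698835      207922 3.361
4 private_payer  QM_420          1052335      313849 3.353
```

The endpoint-based engine yields systematically higher ICERs than the
LDL-C-based engine on identical inputs — the choice of
effect-modelling methodology is itself a first-order driver of the
conclusion.

Other entry points: `one_way_dsa()` (tornado table), `run_psa()`
(scatter + CEAC), `run_scenarios()` (horizon/age/discount/price
grid), `write_workspace()` / `load_workspace()` (plain-text parameter
files with manifest digests), and a thin command-line wrapper in
`inst/cli/evocea.R` with `generate`, `basecase`, `dsa`, `psa`,
`scenarios` and `compare-engines` subcommands.

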