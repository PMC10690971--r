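Package: evocea
Title: Markov Cohort Cost-Effectiveness Model of Evolocumab Added to
    Statins After Acute Myocardial Infarction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort state-transition model for the
    cost-effectiveness of adding the PCSK9 inhibitor evolocumab to statin
    therapy in survivors of acute myocardial infarction, from the Chinese
    healthcare and private-payer perspectives. The model tracks acute and
    post-event health states with memory of prior myocardial infarction
    and stroke, competing cardiovascular and non-cardiovascular
    mortality from a life table, and revascularization as a costed
    procedure. Treatment benefit can be modelled from clinical-endpoint
    hazard ratios or from rate ratios per mmol/l of LDL cholesterol
    reduction. The package computes half-cycle-corrected discounted
    costs and QALYs, incremental cost-effectiveness ratios and net
    monetary benefit, one-way deterministic sensitivity analysis
    (tornado), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and scenario sweeps over
    horizon, starting age, discount rate and drug prices. A synthetic
    data module generates the life table, cohort profiles and the full
    default parameter set so every analysis runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
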