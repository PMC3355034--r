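Package: azolecea
Title: Cost-Effectiveness Model of Posaconazole Versus Standard Azole
    Prophylaxis of Invasive Fungal Infection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing
    posaconazole with standard azole therapy (fluconazole or itraconazole)
    for prophylaxis of invasive fungal infection (IFI) in high-risk
    neutropenic patients with acute myelogenous leukaemia or
    myelodysplastic syndrome.  A 100-day decision tree is combined with a
    lifetime monthly-cycle Markov cohort projection driven by relative
    survival, producing expected IFI events, discounted life-years, total
    costs, incremental cost-effectiveness ratios and dominance verdicts.
    Includes deterministic (one-way) and probabilistic (second-order Monte
    Carlo) sensitivity analysis with moment-matched Beta and Gamma
    distributions, cost-effectiveness acceptability curves, threshold and
    crossover analysis, and a synthetic two-arm trial generator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
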