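# azolecea

Cost-effectiveness analysis of **posaconazole versus standard azole therapy
(SAT; fluconazole 81% / itraconazole 19%)** for prophylaxis of invasive
fungal infection (IFI) in high-risk neutropenic patients with acute
myelogenous leukaemia or myelodysplastic syndrome, from the perspective of a
national health service (EUR, November-2009 price level).  The package is
aimed at health-economics and biostatistics users who want the model as
tested, configurable code rather than a spreadsheet: every parameter lives
in a YAML/JSON config, every analysis is a function, and every published
cost cell is reproduced by the test suite.

## The model

Two integrated parts:

1. **100-day decision tree.** Per arm, a patient develops a proven/probable
   IFI with probability *p*<sub>IFI</sub>, then survives or dies of it
   (*p*<sub>d|IFI</sub>); patients without an IFI face other-cause death
   (*p*<sub>d,o</sub>).  Expected cost per patient is the full prophylaxis
   course plus *p*<sub>IFI</sub> · *c*<sub>IFI</sub> (one IFI episode costs
   €67,984).
2. **Lifetime Markov extension.** 100-day survivors enter a monthly-cycle
   cohort model; AML and MDS sub-cohorts die at constant monthly
   probabilities *q* = 1 − *rs*<sup>1/60</sup> derived from 5-year relative
   survival (0.21 / 0.08) and are mixed by the cohort's AML fraction.
   Person-time is half-cycle corrected and discounted at 3%/year after the
   first year, yielding discounted life-years saved (LYS).

On top: incremental cost per IFI avoided and per LYS with dominance
classification, net monetary benefit against a €30,000/LYS threshold,
one-way deterministic sensitivity analysis, probabilistic sensitivity
analysis (second-order Monte Carlo over moment-matched Beta/Gamma
distributions), cost-effectiveness acceptability curves, a
crossover/threshold analysis, and a synthetic two-arm trial generator with
parameter-recovery tooling.

A subtlety worth knowing before reading results: the published base-case
probabilities are rounded, while the one-way sensitivity ranges are exact
75%/125% multiples of the values actually used.  `effective_base_case()`
back-calculates those *effective* values (e.g. posaconazole
*p*<sub>IFI</sub> = 0.0458, not 0.05) — only they reproduce the published
cost cells.

## Worked example

```r
library(azolecea)

cfg <- base_case_config()
run_base_case(cfg)
#> Base-case cost-effectiveness analysis
#>      strategy total_cost ifi_events  lys icer_per_ifi_avoided icer_per_lys
#>  posaconazole       6121       0.05 2.55
#>           sat       7928       0.11 2.47
#>    difference      -1807      -0.06 0.08             Dominant     Dominant
```

Posaconazole prophylaxis costs more up front (€3,007 vs €450 per patient)
but avoids 0.06 IFI episodes per patient, saving €1,807 overall while adding
life-years — it *dominates* SAT, so no ICER is quoted.

```r
psa <- run_psa(cfg, n_draws = 1e5, seed = 1)
psa
#> <psa_result> 100000 draws (posaconazole vs sat), seed 1
#>   P(cost-saving) = 0.843
#>   P(ICER below 30000 EUR/LYS) = 0.967

crossover_benefit(cfg)
#> <crossover_result> base IFI-risk reduction 0.0642; crossover
#>   ICER = 30000 EUR/LYS at dp* = 0.0225
#>    dp delta_cost  delta_lys icer_per_lys classification cost_effective
#>  0.00   2557.497 0.00000000    Dominated      dominated          FALSE
#>  0.02   1197.817 0.03074403        38961  tradeoff_icer          FALSE
#>  0.06  -1521.543 0.07719259     Dominant       dominant           TRUE
```

So across parameter uncertainty posaconazole is cost-saving in ~84% of
simulations and cost-effective at €30,000/LYS in ~97%; its advantage
survives until the IFI-risk reduction over SAT shrinks below ≈ 0.022
(at a 2% reduction the ICER exceeds the threshold, and with no reduction
SAT dominates).  One-way scenarios via `run_dsa(cfg)`, acceptability curves
via `ceac(psa)` / `plot_ceac(psa)`, synthetic trials via
`simulate_trial()` / `recover()`.

A thin command-line front end is available at `exec/azole-cea`
(`base-case | dsa | psa | ceac | simulate`, with `--config`, `--seed`,
`--n-draws`, `--threshold`, `--out`).

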