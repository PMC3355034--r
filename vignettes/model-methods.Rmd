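---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azolecea)
```

`azolecea` implements a two-part decision-analytic model of antifungal
prophylaxis in high-risk neutropenic patients with acute myelogenous
leukaemia (AML) or myelodysplastic syndrome (MDS): posaconazole against
standard azole therapy (SAT, a fixed 81%/19% fluconazole/itraconazole mix,
mirroring how the comparator arm of the underlying randomised trial was
constituted).  This vignette is the package's account of the model: its
structure, the assumptions behind every tunable parameter, and the numerical
conventions the code commits to.

## The 100-day decision tree

After the decision node (posaconazole vs SAT), each patient either develops
a proven or probable invasive fungal infection (IFI) within 100 days, with
arm-specific probability $p_{\mathrm{IFI}}$, or does not.  IFI patients die
of the infection with probability $p_{d|\mathrm{IFI}}$; patients without an
IFI are exposed to death from other causes with probability $p_{d,o}$.
Terminal branch probabilities are therefore

$$
P(\text{die, IFI}) = p_{\mathrm{IFI}}\,p_{d|\mathrm{IFI}},\qquad
P(\text{die, other}) = (1 - p_{\mathrm{IFI}})\,p_{d,o},\qquad
P(\text{survive}) = 1 - \text{(the two death terms)} .
$$

Two points of this composition were genuinely open:

* **Exposure of IFI survivors to other-cause death.** The default topology
  applies $p_{d,o}$ only to the no-IFI branch.  This choice conserves
  probability exactly and reproduces the posaconazole arm's observed 100-day
  mortality (16%) to within one percentage point; the alternative — exposing
  IFI survivors as well — is available behind the config switch
  `shared$expose_ifi_survivors` but is not the default, since nothing in the
  published tree suggests double exposure.
* **Within-window life-year accrual.** The source model is silent on how
  life-years accrue inside the 100 days.  Convention adopted: survivors
  contribute the full window (100/365.25 y), IFI-related deaths contribute
  the arm's mean time to IFI (41 d posaconazole, 25 d SAT — the trial means),
  other-cause deaths the window midpoint (50 d).  Moving any of these anchors
  across its plausible range changes total life-years by less than 0.03 y
  and no qualitative result.

Costs are prophylaxis (weight × duration × daily total, summed over mixture
components; durations are trial means that already reflect discontinuation,
so the full course accrues on every branch) plus the expected IFI-management
cost $p_{\mathrm{IFI}} \times c_{\mathrm{IFI}}$.  All costs fall inside the
first year and are not discounted.  Monetary values are EUR at the
November-2009 price level; no inflation adjustment is performed.

## The effective base case

The published base-case probabilities are rounded to two decimals, but the
one-way sensitivity ranges are exact 75%/125% multiples of the values the
original model actually used.  Only those range-implied values reproduce the
published cost cells (0.11 × 67,984 = 7,478; 0.0458 × 67,984 ≈ 3,114), so
`effective_base_case()` substitutes them and reports every substitution:

```{r}
cfg <- effective_base_case(base_case_config())
substitution_report(cfg)
```

`base_from_range()` goes one step further than averaging the two
back-calculations `low/0.75` and `high/1.25`: because the printed bounds are
themselves rounded (to four decimals), it searches for the
shortest-decimal value consistent with *both* bounds after rounding.  For
the posaconazole IFI probability this resolves the ambiguity between
0.04587 (from the lower bound) and 0.04584 (from the upper) in favour of
0.0458 — the value that reproduces the published €3,114 cell exactly.  The
substitution deliberately covers only the six acute-phase probabilities:
the cost ranges back-calculate to the printed values anyway, and the
relative-survival ranges (0.16–0.26, 0.06–0.10) are symmetric absolute
bands, not 75/125 multiples, so their printed base values stand.

## The lifetime Markov extension

Patients alive at day 100 enter a monthly-cycle cohort model.  The only
long-term mortality anchor the source provides is *relative survival*: 0.21
for AML and 0.08 for MDS, with no stated horizon or conversion rule.  The
package's reconstruction — the single largest assumption in the model —
reads these as `rs_basis_years`-year cumulative survival (default 5 years,
the convention of the cited cancer-registry statistics) under a constant
hazard, giving the monthly death probability

$$ q = 1 - rs^{1/(12\,\cdot\,\text{basis\_years})} , $$

about 0.0257/month for AML and 0.0412/month for MDS.  Both the basis and an
optional additive background monthly hazard (default 0 — the relative
survival figures are taken to already fold in competing mortality) are
config fields, not constants.  IFI survivors and non-IFI survivors use the
same lifetime mortality, as the parameter table lists identical relative
survival for both.

The AML and MDS sub-cohorts are traced **separately** and mixed by
`aml_fraction`; averaging their hazards first would distort the mixture
survival curve.  The cohort's AML:MDS composition is nowhere printed; the
bundled config sets `aml_fraction = 0.85` as a calibration assumption (the
trial population was AML-dominant), and every qualitative conclusion in the
test suite is checked across the whole admissible range [0, 1].

Numerical conventions:

* **Half-cycle correction** by the trapezoid rule: cycle $k$ contributes
  $(A_{k-1} + A_k)/2$ person-months.  With constant $q$ and no discounting
  this makes life expectancy exactly $(1-q)/q + 1/2$ months — the geometric
  closed form the test suite checks to $10^{-6}$.
* **Discounting** at 3%/year applies after the first year of treatment:
  factor 1 for $t < 1$ and $(1+r)^{-t}$ beyond, evaluated at cycle midpoints
  with $t$ measured from model start (the acute window occupies the first
  0.274 y).  Whether the original applied annual steps or continuous time is
  not stated; the difference is below 0.5% of life expectancy at monthly
  cycles.
* **Termination** at the horizon (default 50 years, ample for these
  hazards) or when the alive fraction falls below $10^{-9}$.

With these choices the base case gives 2.55 vs 2.47 discounted life-years —
the published 2.52 vs 2.43 cannot be reproduced exactly without the
unprinted AML:MDS mix and conversion convention, but the ordering,
magnitude and difference (0.08 vs published 0.09) are recovered, which is
what the tests assert.

## Incremental analysis

Effects are oriented so larger is better (IFIs avoided = comparator −
intervention).  A strategy is *dominant* when more effective and cheaper;
the incremental cost-effectiveness ratio (ICER) is computed only in the
trade-off case and the ICER field otherwise carries the dominance marker,
never a number.  Ties on effect classify by cost sign; ties on both axes are
*equivalent*.  Net monetary benefit, $\lambda\,\Delta\mathrm{LYS} - \Delta
C$, is positive exactly when the intervention is cost-effective at
willingness-to-pay $\lambda$ (default €30,000 per life-year saved, the
Spanish reference threshold).  Tabular output rounds costs to whole euros
and effects to two decimals; internal arithmetic is full precision.

## Sensitivity analyses

**One-way (deterministic).** The default grid holds 12 parameters × 2
bounds: the IFI probabilities at their published wider bands (0.025/0.075
and 0.075/0.15), death probabilities, relative survival, daily costs and
the IFI episode cost at their range bounds, and the discount rate at 0%/5%.
One finding the package reports as computed: in the two scenarios that
narrow the arms' IFI-probability gap below
$\Delta C_{\text{proph}} / c_{\mathrm{IFI}} = 2{,}557.50 / 67{,}984 =
0.0376$ — posaconazole at 0.075 and SAT at 0.075 — the incremental cost is
positive (+€178 and +€572), so posaconazole is *not* dominant there, only
cost-effective (ICERs of roughly €2.8k and €12k per LYS, far below the
threshold).  The original report prints "dominant" for all 24 scenarios,
which is arithmetically incompatible with its own cost inputs; the package
documents the discrepancy rather than forcing agreement.

**Probabilistic (second-order Monte Carlo).** Each parameter with a
non-degenerate spec is sampled independently per draw — Beta for
probabilities, Gamma for the IFI episode cost — with shapes fitted by moment
matching to the published (mean, SD) pairs; the daily treatment costs and
relative survival are printed with SD 0.000 and stay fixed, exactly as
specified.  The IFI-cost row names a Gamma but prints no SD; the default is
CV = 25%, consistent with the ±25% construction of every deterministic
range (with the cost fixed instead, the cost-saving probability rises from
≈0.84 to ≈0.89, which the tests pin to a closed-form normal approximation).
No correlation structure is imposed (none is given).  The default
`n_draws = 1000` mirrors the original analysis; headline probabilities in
the tests use $10^5$ draws for ±0.1pp Monte-Carlo error.  Because the
sampled parameters leave the per-survivor Markov life expectancy untouched
(relative survival is fixed), the engine computes it once and vectorises the
rest, so $10^5$ draws take well under a second; if a config gives a lifetime
parameter a positive SD the engine transparently falls back to per-draw
Markov runs.

**CEAC and crossover.** The acceptability curve is the fraction of draws
with positive net monetary benefit per threshold; at $\lambda = 0$ it equals
the cost-saving probability.  The crossover analysis shrinks the
intervention's clinical advantage linearly towards the comparator
(all four clinical fields interpolated together, so at $\Delta p = 0$ the
arms are clinically identical and only prophylaxis costs differ) and
root-finds the IFI-risk reduction at which the ICER per LYS meets the
threshold — about 0.022 at base case: at a 2% absolute reduction
posaconazole is no longer cost-effective, and with no reduction at all SAT
dominates.

## The synthetic trial generator

`simulate_trial()` emulates the statistical structure the analysis assumes:
per arm, `n_ifi ~ Binomial(n, p_ifi)`, then cause-specific deaths
hierarchically among IFI and non-IFI patients — matching the tree topology.
Defaults are the trial's conditions: arm sizes 304/298 and the effective
base-case probabilities.  `estimate_parameters()` recovers proportions with
binomial standard errors (a +1/2 continuity correction, applied to the SE
only, keeps zero-count cells Beta-feasible), and `recover()` closes the loop
by re-running the cost model on the estimates.  What the generator does
*not* emulate: patient-level time-to-event structure, censoring,
discontinuation dynamics, or between-centre heterogeneity — so passing
recovery tests demonstrate correctness of the estimation and costing
pipeline under the model's own assumptions, not robustness to real-trial
complications.  One residual worth noting: the published SDs for the
death-given-IFI probabilities (0.1247, 0.0857) sit slightly off the
binomial values implied by the printed counts (0.1281 for 5/14, 0.0870 for
16/33); the package uses the binomial formula.

## Problem sizes and limitations

The test suite runs the full model at its native size (600 Markov cycles)
throughout, uses $10^5$ PSA draws for headline probabilities, $10^6$
patients per arm for the large-sample recovery check, and hundreds of
replicates for unbiasedness checks — a few seconds in total, as every
stochastic path is vectorised.  Known limitations: no QALY weighting
(excluded by design in the source), no adverse-event or underlying-disease
costs (common to both arms), no time-varying or cure-point hazards, no
correlated PSA sampling, and no value-of-information analysis.
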