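---
title: "Modelling the cost-effectiveness of endoxifen monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of endoxifen monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoxtdm)
```

## The decision problem

Tamoxifen works through its metabolite endoxifen, and roughly a quarter of
adjuvantly treated ERα-positive breast-cancer patients do not reach the
serum concentration (5.97 ng/mL) associated with the full recurrence-risk
reduction. Therapeutic drug monitoring (TDM) — one serum test about three
months after starting therapy, dose doubling for patients testing low, and
one confirmatory test three months later — moves most of those patients
above the threshold. `endoxtdm` estimates the lifetime value of that
intervention for a cohort entering at age 53, in discounted euros and
quality-adjusted life-years (QALYs), against a no-monitoring comparator.

## Model structure

The model is a partitioned-survival implementation of a three-state cohort
model (disease-free survival, DFS; recurrent disease, RD; death) on a
28-day cycle grid to age 100 (613 cycles). Rather than inventing per-cycle
transition matrices, state occupancy is read directly from survival curves
at every cycle boundary:

* `OS(t) = S_bc(t) × S_bg(t)`: lognormal breast-cancer mortality
  (intercept 3.71, log-scale 0.40) times life-table background survival,
  treated as independent competing hazards. OS is identical under both
  strategies — monitoring changes *which* living state patients occupy, not
  how long they live. This is deliberately conservative: all benefit flows
  through the cost and utility differences between DFS and RD.
* Each strategy is a mixture of exposure subcohorts on the lognormal DFS
  curve (intercept 3.28, log-scale 0.61 for low exposure). Adequate
  exposure multiplies the recurrence hazard by HR = 0.74. Subcohort DFS is
  depleted by background mortality (`S_dfs × S_bg`) and capped at OS
  *within each subcohort*; the per-subcohort cap is slightly tighter than
  capping the mixture and makes the microsimulation oracle (below) agree
  with the cohort trace exactly in expectation.
* `RD = OS − DFS`; death occupancy is `1 − OS`.

**Hazard-ratio window.** The hazard ratio was estimated among women on
active tamoxifen, and the meta-analytic curves underlying the model reflect
a five-year adjuvant course, so by default the HR acts on the recurrence
hazard only during `treatment_duration = 5` years; the survival advantage
accrued by then is carried forward as a constant survival ratio rather than
a continuing hazard reduction. Setting `treatment_duration = Inf` applies
the HR over the whole curve; this roughly doubles the incremental QALYs and
we consider it an over-estimate, since it credits a lifelong hazard
reduction to a five-year exposure difference.

**Strategy mixtures.** Without TDM, 76% of patients (`p_high_start`) are on
the high-exposure curve from the start and 24% on the low curve, with no
test costs. With TDM everyone is tested at day 91, the 24% testing low are
escalated and retested at day 182, and `p_high_after_escalation = 0.94` is
the share of the *whole cohort* with adequate exposure once escalation is
complete. The converting subcohort therefore has weight
`0.94 − 0.76 = 0.18` (a 75% conversion rate among the escalated), adopts
the high-exposure hazard at day 182 (`benefit_at_first_test = TRUE` moves
this to day 91), and reverting to low exposure is modelled as impossible —
so the weight is floored at zero when a sensitivity draw puts
`p_high_after_escalation` below `p_high_start`. This reading is what makes
the published range endpoints produce exactly five zero-benefit scenarios
(equal utilities twice, HR = 1, everyone adequate at the first test, nobody
converting), which the one-way sensitivity analysis reproduces.

## Economics

Annual DFS and RD state costs and the state utilities accrue per cycle with
half-cycle (trapezoidal) occupancy correction, prorated by 28/365.25. The
one-off death cost applies to each cycle's new deaths, and the €113 test
cost applies at the scheduled test cycles to the tested fraction still
alive. Everything is discounted at the cycle midpoint: 4%/year for costs
(the guideline value stated in the source's text; its parameter table
prints 0.045, and the rate is configurable) and 1.5%/year for effects.
Comparisons report incremental cost, incremental QALYs, the ICER
(`NA` when ΔQALY = 0 — a dominance label is reported instead) and net
monetary benefit `NMB = WTP × ΔE − ΔC` at a default willingness to pay of
€20,000/QALY.

## Sensitivity analysis

`run_dsa()` re-evaluates the comparison at each parameter's published
low/high endpoint, ordering the tornado by the incremental-cost swing (the
ordering metric is not dictated by the source; cost swing is the quantity
decision-makers read first here because the intervention is cost-saving).

`sample_psa()` draws all uncertain inputs at once: beta distributions for
the two proportions and two utilities, gammas for the four costs, the
hazard ratio as the exponential of a normal on the log scale (mean −0.301,
SE 0.153), and the two (intercept, log-scale) survival pairs as joint
normals via the Cholesky factor of their covariance. The survival standard
errors are back-computed from the published ranges as `(high − low)/3.92`
and the pairs are independent by default — the original correlation matrix
is unpublished and we do not invent one; `survival_correlation` accepts a
scalar correlation or full 2×2 covariances (for example from
`fit_parametric()`'s covariance on reconstructed data).

Truncation is by **clipping, not rejection**: HR draws above 1.00 are set
to 1.00, RD-utility draws above the paired DFS-utility draw are set equal,
and draws with `p_high_after_escalation ≤ p_high_start` leave nobody to
convert. Clipping concentrates a point mass of "no benefit demonstrated"
trials (HR clipped or no converters ⇒ ΔE = 0 with only the test costs
paid), which is exactly why the acceptability curve plateaus below 100%
instead of converging to it; rejection sampling would erase that plateau.
The CEAC reports `P(WTP × ΔE − ΔC > 0)` per willingness-to-pay value, and
the NMB table the mean with 2.5/97.5 percentiles. With 10,000 trials the
whole PSA takes on the order of ten seconds.

## Synthetic inputs

Two study inputs are not deposited and are generated in code:

* **Background mortality.** A Gompertz–Makeham law
  (`h(a) = 3×10⁻⁴ + 1.2395×10⁻³ · e^{0.125 (a − 53)}`) tabulated to annual
  death probabilities. It is calibrated so female remaining life expectancy
  at 53 is 33.0 years and the old-age slope matches recent Dutch female
  tables (qx ≈ 0.12 at 90, ≈ 0.36 at 100). It ignores infant and
  young-adult excess mortality, which the model never sees (entry at 53).
  It remains a stand-in: exact replication requires the real national
  table, supplied as an `age,qx` CSV through `read_life_table()`.
* **Serum endoxifen cohorts.** Occasion-1 concentrations at 20 mg/day are
  lognormal with median 8.50 ng/mL and log-SD 0.5 (≈50% CV, typical for
  steady-state endoxifen), chosen so that 24% fall below 5.97 ng/mL — the
  model's low fraction. Patients below threshold escalate to 40 mg/day (23
  of 113 to 30 mg, mirroring the clinical split) and are remeasured with
  concentration scaled by `(dose/20)^0.7` times lognormal inter-occasion
  noise (SD 0.3). The sub-proportional exponent reflects the blunted
  endoxifen response to dose doubling and yields ≈66% of escalated patients
  reaching target, the clinically observed rate. The generator matches
  these threshold proportions, not the (unpublished) full concentration
  distribution.

## The microsimulation oracle

`microsimulate()` is a deliberately different implementation used to check
the cohort arithmetic: each simulated patient draws a subcohort by weight
and a single uniform `u` inverted through both the subcohort's all-cause
DFS curve and the OS curve. Sharing `u` (a comonotone coupling) guarantees
recurrence never follows death and reproduces the partitioned occupancies
exactly in expectation — independent event times would not, because the
partitioned identity RD = OS − DFS links the two margins. Patients then
accrue the same per-cycle costs, utilities, death and test costs with the
same discounting, so strategy means must agree with `run_trace()` totals
within Monte-Carlo error; the test suite checks 3 standard errors at
100,000 patients.

## Numerical choices and edge cases

* Cycle-boundary survival uses `plnorm()` directly; fractional-year
  background survival uses constant hazard within each year of age.
* Test times are mapped to the nearest cycle start (`round(t/28)`); a test
  scheduled beyond the horizon is a configuration error.
* `km_reconstruct()` rounds implied event counts to nearest integers,
  absorbs the remaining at-risk decline into censorings, and rejects
  sequences implying negative counts; survivors at the last boundary are
  right-censored there. Parametric fits on such data use an
  interval-censored likelihood (`survival::survreg`), exact event times an
  uncensored one; model selection is minimum AIC with BIC, then parameter
  count, as tie-breakers.
* ΔQALY is compared to zero at 1e−10 when classifying no-benefit PSA
  trials: hazard-ratio and conversion clipping give exact zeros, utility
  clipping zeros up to floating-point accumulation.
* Horizon residue: survivors at age 100 accrue no terminal value; the
  death cost is discounted at the midpoint of the cycle of death.

## What the synthetic results do and do not show

With the bundled life-table stand-in the base case yields ≈0.0089
incremental QALYs and ≈€1,050 saved per patient (monitoring dominates; ICER
≈ −€118,000/QALY), and the acceptability curve runs from ≈89% at €0/QALY to
≈90% at €80,000/QALY with the characteristic no-benefit plateau. The
published analysis reports 0.0115 QALYs and €1,564 saved with totals a
fifth lower; the gap is dominated by the recurrent-disease occupancy
implied by `RD = OS − DFS` under the printed curve parameters and by the
five-year hazard-ratio window, and does not change any qualitative
conclusion (dominance, the plateau, the zero-benefit scenarios). Passing
tests therefore demonstrate internal consistency and faithful mechanics on
synthetic inputs, not agreement with unpublished patient-level data.

Known limitations: locoregional recurrences stay in RD (no re-treatment
modelling), no adverse-event disutility from dose doubling, no
aromatase-inhibitor sequencing, no EVPI, and the 5.97 ng/mL threshold and
HR 0.74 rest on a single retrospective cohort — which is precisely the
uncertainty the PSA propagates.
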