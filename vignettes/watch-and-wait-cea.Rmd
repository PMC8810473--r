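---
title: "A Markov microsimulation for watch-and-wait versus radical resection in rectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov microsimulation for watch-and-wait versus radical resection in rectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwcea)
```

## The decision problem

Some locally advanced rectal cancer patients have a complete clinical
response (cCR) after neoadjuvant chemoradiation. Two management strategies
then compete: immediate radical resection — abdominoperineal resection (APR,
permanent ostomy) or low anterior resection (LAR, temporary ostomy) — or a
*watch-and-wait* (WW) surveillance program that reserves salvage resection for
local regrowth. Surgery buys a lower local-recurrence risk at the price of a
perioperative mortality risk, months of reduced quality of life, ostomy care,
and substantial upfront cost. `wwcea` reimplements a published
cost-effectiveness comparison of these strategies as a patient-level Markov
microsimulation, from the payer perspective, in 2019 US$ and
quality-adjusted life-years (QALYs), at a willingness-to-pay (WTP) threshold
of $100,000/QALY. Because quality of life differs sharply between the two
operations, APR and LAR are compared with WW in two separate models.

## Model structure

Six health states, monthly cycles, a five-year horizon (60 cycles):

* **stable disease** — disease-free. Context distinguishes WW surveillance
  (pre-salvage) from the post-operative stable state (after initial
  resection, or after salvage resection with the state clock reset);
* **local recurrence, salvaged** — pelvic recurrence after resection treated
  with a second radical operation;
* **local recurrence, unsalvaged** — pelvic recurrence managed palliatively;
* **distant recurrence**;
* **local and distant recurrence** — combined state fed by concurrent
  diagnoses and by distant progression from a local state;
* **death** (absorbing), from perioperative, cancer, or natural causes.

Surgical-arm patients face a one-time perioperative death draw (p = 0.035) at
entry; survivors accrue the resection cost, two months of acute
post-operative utility (0.110), four 28-day cycles of adjuvant chemotherapy,
and ostomy care (LAR: six months, then takedown and the ostomy-free utility
0.78; APR: permanent, long-term utility 0.75). WW patients enter surveillance
directly at utility 0.80. On local regrowth, a concurrent-distant draw
(p = 0.056) may send them to the combined state; otherwise salvage succeeds
with p = 0.94, repeating the surgery cost and perioperative risk and starting
a post-operative stable period (salvage disutility 0.69 for the recovery
window) governed by the surgical-arm ("TME") transition schedule. Post-operative
local recurrence is salvaged with p = 0.59 into the salvaged-recurrence
state (with re-irradiation), otherwise managed palliatively. Any distant
event triggers a concurrent-local draw (p = 0.17). Local states carry a
monthly distant-progression hazard derived from a 3-year cumulative
probability of 0.11. Recurrence states accrue their own utilities, palliative
chemotherapy costs (capecitabine in unsalvaged local recurrence, mFOLFOX6 in
any distant state) and cancer mortality converted from 5-year cumulative
probabilities. Every alive state faces the life-table background mortality
each cycle. Within a cycle, events resolve in a fixed order: natural death,
cancer/perioperative death, progression draws (local before distant), then
accrual in the post-transition state — a determinism choice whose effects at
monthly granularity are second-order.

## From interval evidence to monthly probabilities

The evidence arrives as cumulative probabilities over stated horizons
(e.g. 2-year regrowth 0.19, 5-year distant recurrence 0.10). Within an
interval we assume a constant hazard, so a cumulative `P` over `n` cycles
becomes the monthly probability `p = 1 - (1 - P)^(1/n)`
(`per_cycle_from_cumulative()`); `P = 1` is rejected as an infinite hazard.

Local recurrence/regrowth has *two* evidence rows — 2-year and 5-year
cumulatives from different studies — and the interpolation between them is
the one genuinely open structural choice. `piecewise_local_schedule()`
implements both candidate rules:

* **`row_horizon`** (the packaged default): months 1–24 use the 2-year value
  converted over 24 cycles; months 25–60 use the 5-year value converted over
  its own 60-cycle horizon. Each row is treated as its own per-cycle
  transition probability, the common convention when evidence rows are
  entered independently into decision-modeling software. Under it the
  realized 5-year regrowth from (0.19, 0.24) is
  `1 - 0.81 * 0.76^(36/60) = 0.313` before competing risks — matching the
  published realized regrowth proportions (31.25%/30.83%), which *exceed* the
  5-year input and are unreachable under any single-curve reading.
* **`conditional_residual`**: months 25–60 use the conditional residual
  `R = max(0, (P5y - P2y)/(1 - P2y))` over 36 cycles, treating the two rows
  as points on one cumulative-incidence curve (the realized cumulative is
  then exactly `P5y`). The surgical-arm inputs are non-monotone as printed
  (2-year 0.016 > 5-year 0.010), so this rule clamps their residual to zero;
  a load-time warning flags the non-monotone rows either way.

The choice is a per-model configuration key (`timeline.local_interpolation`),
and the package's base-case fixtures use `row_horizon` because it reproduces
the published realized outcome proportions; the conditional-residual rule is
retained, tested, and arguably the better *de novo* science.

## Background mortality and baseline age

Natural-cause mortality comes from a sex-averaged annual life table,
converted to monthly probabilities at the attained age
(`baseline_age + floor((cycle-1)/12)`). The packaged table
(`life_table_2015_synthetic.tsv`) is an abridged, log-linear-interpolated
*reconstruction* of a 2015 US period life table — synthetic, as the filename
says, accurate to roughly the first two significant digits, which is ample
given the one-way sweep shows conclusions are insensitive to background
mortality below extreme levels. The baseline age is not stated by the
original analysis; we use **65 years** (configurable), the median age at
rectal-cancer diagnosis in the US and typical of the registry cohorts behind
the transition probabilities. It back-solves correctly: 5-year natural
mortality from age 65 (~7.4%) plus the simulated cancer-specific mortality
reproduces the published overall mortality within a percentage point.

## Accrual and discounting

Costs and QALYs are discounted at 3% per year with a half-cycle correction:
recurring accruals (state utility/12, surveillance, monthly drugs, ostomy
care) are discounted at the cycle midpoint, `(1+r)^(-(t-0.5)/12)`; one-time
transition costs (surgery, restaging, re-irradiation, terminal death costs)
at their event cycle, `(1+r)^(-t/12)`, with model-entry costs undiscounted.
The LAR ostomy takedown, a scheduled rather than transition cost, is folded
into the month-6 recurring accrual (mid-cycle discounting); the difference is
under a dollar. Patients who die in a cycle forfeit that cycle's accrual.
Restaging costs attach to the triggering event (local event → local
restaging, distant event → distant restaging, concurrent diagnosis → both);
re-irradiation applies once, on entry to the salvaged post-operative
recurrence state. The distant-recurrence state is absorbing apart from death:
no evidence row supplies a subsequent-local rate beyond the concurrent draw.

## Adjuvant chemotherapy and surveillance

All strategies assume perfect adherence to 4 months of adjuvant
chemotherapy: the surgical arms (and WW patients after salvage) start it on
the post-operative state clock, WW patients on the surveillance clock
(`ww_adjuvant_chemo`, a config switch, is on in the base case, consistent
with the original analysis's stated all-arms adherence assumption — and the
published WW arm cost sits one full chemotherapy course above the
chemo-off variant). The start offset is configurable at 1, 2 or 3 cycles
(4/8/12 weeks); the base case uses 8 weeks, and `adjuvant_timing_scenarios()`
re-runs the model at the alternatives — dominance is unaffected.

Surveillance is an explicit calendar (cost item → billing cycles on the
disease-free state clock) in the config, since the source program cites
surveillance guidelines without printing frequencies. The default WW calendar
bills an office visit, digital rectal exam, flexible sigmoidoscopy and CEA
every 3 months in years 1–2 and every 6 months thereafter, pelvic MRI every
6 months in years 1–2 then annually, CT chest/abdomen-pelvis and colonoscopy
annually; the post-operative calendar drops the proctologic items (office
visit + CEA cadence, annual CTs, colonoscopy — through the stoma after APR).
The one-way analysis shows cost items cannot change the conclusion, so the
calendar's exact cadence is not load-bearing.

## Engine, oracle, and randomness

`simulate_cohort()` simulates all patients in lockstep: each cycle consumes a
fixed block of uniform draws (one row per patient, one column per decision),
from a single `set.seed(master_seed)` stream. Results are therefore
bit-reproducible given `(spec, arm, n, seed)`, and a patient's path depends
only on their row — `simulate_patient()` is the n = 1 slice of the same
machinery. A 10,000-patient arm runs in about a quarter of a second.

`cohort_expected_value()` is the same event logic propagated as state-occupancy
probabilities (the post-operative stable state expanded by entry cycle, since
its schedules depend on the state clock), giving exact expected accruals.
Both consume one shared table object (`build_model_tables()`), so the two
routes share substance but not sampling; the test suite requires them to
agree within four standard errors at n = 10,000, the occupancy rows to sum
to one, and degenerate scenarios (zero risk, certain perioperative death,
zero costs, perfect utility) to hit closed-form values to 1e-9. The
deterministic oracle also drives the one-way sensitivity analysis, where
bisection to 1e-3 (probabilities/utilities) or $1 (costs) needs noise-free
classifications.

## Sensitivity analyses

**One-way (deterministic).** Each parameter sweeps its range (packaged
fixture for probabilities/utilities; 5%–195% of base for costs) with all
others fixed; each grid point is classified from the surgery-versus-WW
viewpoint (WW dominates / surgery not cost effective / surgery cost
effective, by dominance quadrant and net monetary benefit at $100k/QALY) and
band boundaries are refined by bisection. Cumulative-probability sweep uppers
are capped at 0.999 (a cumulative 1 implies an infinite monthly hazard). In
our reconstruction the 2-year WW regrowth threshold above which APR (LAR)
becomes cost effective computes to ~0.91 (~0.87) and the 5-year WW distant
threshold to ~0.60 (~0.59) — a few points above the published 0.86/0.83 and
0.57/0.56, consistent with the residual structural unknowns. One caveat worth
stating plainly: at the very bottom of the *surgery*-cost sweep (below
roughly a tenth of base cost) surgery becomes marginally cheaper than WW —
the same parameter prices WW's salvage resections — so strict dominance gives
way there, although surgery still never becomes cost effective anywhere on
any cost sweep.

**Probabilistic.** Each outer iteration redraws every non-fixed parameter —
method-of-moments β for probabilities and utilities
(`beta_params_from_moments()`), γ for costs (`gamma_params_from_moments()`) —
and evaluates both arms by microsimulation. A printed sd at or above the β
feasibility bound `sqrt(m(1-m))` is clipped to 95% of the bound with a
warning. The death utility is structurally fixed and never sampled.

A candid divergence: the original analysis reports WW optimal in 100% of 100
iterations across WTP $0–200k. Under per-iteration parameter draws this is
mathematically out of reach with the stated distributions — the long-term WW
and surgery utilities (0.80 ± 0.16 and 0.75 ± 0.15, independent β draws) give
surgery the higher draw in roughly 40% of iterations, and its own one-way
thresholds (WW utility below ~0.68 flips the result) lie well inside ±1 sd.
Our PSA yields WW optimal at every WTP in roughly 60–80% of iterations
(seed-dependent), and WW strictly dominant in roughly two thirds. The likely explanation for the
original figure is distribution sampling at the individual-patient level
inside each 10,000-patient run, which averages parameter uncertainty away and
collapses every iteration onto the base case. We implement the standard
outer-draw PSA and report what it computes.

## Problem sizes and runtime

Packaged analyses use the original scale: 10,000 patients per arm for base
cases, 100 outer × 10,000 inner for the PSA (a full PSA of both models runs
in a few minutes on one core; the test suite uses 2,000-patient inner cohorts
for the same check). All analyses are reproducible from a single integer
seed per run, recorded with every report in a JSON manifest alongside any
warnings (β-sd clips, non-monotone input flags).

## Known limitations

The model inherits the original analysis's scope: a five-year horizon (no
extrapolation of the clearly different long-term trajectories), no
individual-level covariates (age/sex mixes, compliance), a single WW
surveillance protocol, payer-perspective costs only, and two-strategy
comparisons rather than a three-way frontier. The synthetic scenario
generator randomizes parameters inside their legal domains to exercise the
engine's invariants; passing those property tests demonstrates internal
consistency of the simulation, not external validity of any parameter set.
Where the published tables are internally inconsistent (realized post-operative
recurrence above its own cumulative inputs; a PSA result its own one-way
analysis contradicts), we reproduce what the stated inputs imply and document
the difference rather than forcing the printed number.
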