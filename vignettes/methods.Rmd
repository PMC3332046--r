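---
title: "Model and methods: cost-effectiveness of early Alzheimer's diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of early Alzheimer's diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcea)
```

## The decision problem

`adcea` implements a Markov cohort decision-analytic model comparing three
diagnostic strategies for Alzheimer's disease (AD): a standard cognitive
work-up (specialist consultation, MMSE, laboratory tests), the same work-up
plus non-enhanced MRI, and MRI enhanced with a hypothetical amyloid-binding
contrast agent able to detect the disease at an asymptomatic early stage.
Two settings are modelled:

* **Memory-clinic (primary) analysis** — 70-year-old patients consulting
  for mild cognitive impairment, tested once and followed for 3 years.
* **Screen-and-treat analyses** — systematic screening of 60-year-olds
  (population-wide, or restricted to ApoE4 carriers whose incidence is
  doubled), rescreened every 5 years over a 15-year horizon, in a
  hypothetical future where a drug (here "treatment T") slows progression
  out of early-stage AD.

Outcomes are discounted societal costs (euros, 2009 level) and
quality-adjusted life years (QALYs). Strategies are ranked by dominance and
incremental cost-effectiveness ratios (ICERs) against a willingness-to-pay
of 76 171 €/QALY (three times the per-capita gross national product).

## Disease model

The cohort occupies states (stage × care setting × clinical status): stages
no-AD, early (screening scenarios only), mild, moderate, severe, plus an
absorbing death state; settings home or institution (no return home);
statuses undetected, standard treatment (donepezil at mild/moderate,
memantine at severe), treatment T, or false-positive under follow-up.
Improvement transitions (moderate→mild, severe→moderate) exist only under
standard treatment, tying symptom lessening to drug exposure. Cycles are
six months; each cycle composes stage transitions, incident AD out of
no-AD (a fixed 10%/year in the memory-clinic cohort; age-band-specific
rates when screening), all-cause mortality by five-year age band plus an
additive stage excess, and home-to-institution transitions by stage.

### Annual-to-cycle conversion

Six-month probabilities are the principal square root of the annual
transition matrix. Two numerical points matter:

* **Root algorithm.** The cohort matrices contain structurally parallel
  rows (the same stage dynamics repeated across statuses), hence repeated
  eigenvalues, and are typically *defective*; an eigendecomposition-based
  root is numerically unreliable here. `annual_to_cycle()` therefore uses a
  Denman–Beavers iteration, which converges quadratically to the same
  principal root (reconstruction error ~1e-16 on the packaged matrices) and
  is verified in the tests against an independent square-root routine.
* **Embeddability.** An annual matrix with exact zeros on two-stage jumps
  (e.g. mild→severe in one year) has *no* non-negative square root: the
  root must generate the missing two-step mass with negative entries. Since
  the packaged annual stage matrix is a stand-in anyway (the original
  supplementary values are unpublished), `build_annual_matrix()` composes
  all components on the half-year scale — each annual probability `q`
  enters as `1 − (1 − q)^(1/2)` — and returns the square of that
  composition. The annual matrix then carries the correct one-year
  two-step mass and its principal root is exactly non-negative, which is
  the property the square-root method presumes. The round-trip invariant
  `‖root² − annual‖∞ ≤ 1e-6` holds for all base-case and sampled matrices.

### Treatment effects

Standard treatment acts through lower progression and positive improvement
probabilities in treated rows. Hypothetical better drugs scale these by
multipliers: `f_mM`, `f_MS` in [0.5, 1] on progression and `f_Mm`, `f_SM`
in [1, 2] on improvement, collapsed to one scalar `f` by
`expand_f(f)` = (1 − 0.5 f, 1 − 0.5 f, 1 + f, 1 + f) — a linear
interpolation between the neutral element and the extreme multipliers,
chosen here because only the endpoints of the ranges are published.
Treatment T multiplies progression out of the treated stage by `f_T`
(base case 0.5). In the memory-clinic variant with T, the drug goes to
diagnosed patients with high MMSE scores — modelled as the false positives
plus a fixed fraction (default 0.5, a stand-in) of true mild positives,
with `f_T` applied to their mild→moderate progression; the alternative
reading (a sixth early stage among clinic patients) was rejected because
the clinic cohort's printed stage split covers symptomatic stages only.

## Diagnostic pathway

A test declares each individual positive with probability: 1 − specificity
(no AD), the stage sensitivity (early/mild/moderate), or 1 (severe:
dementia symptoms allow direct diagnosis over a consultation, at
consultation cost only). The standard work-up performs in asymptomatic
early AD exactly as in healthy subjects (sensitivity = 1 − specificity);
the amyloid-targeted test has one stage-independent sensitivity. Staging by
MMSE after a positive result is assumed exact (no published staging error
rate). False negatives are re-evaluated when they reach severe stage
(always) and, in screening scenarios, immediately on developing dementia
symptoms (entering mild), at the full strategy test cost; undetected
individuals are retested at every scheduled screen. False positives stay
under follow-up and drug until, in screening scenarios, a scheduled screen
re-evaluates them (reverting on a negative result); in the memory-clinic
scenario they remain treated to the horizon, since nobody is un-diagnosed
outside a screening round.

## Costs, utilities, discounting

All printed unit values are used exactly: consultations 55 € (diagnosis)
and 41 € (six-monthly follow-up), MMSE 69 €, laboratory tests 50 €,
contrast agent 250 €/injection, donepezil 572 € and memantine 286 € per
six-month cycle, treatment T 500 €/cycle; 1034 caregiving hours per cycle
at 13 €/h (professional) or 8.4 €/h (informal opportunity cost); 35% of
informal caregivers incur a health-burden cost; patient productivity loss
values 63.8 h of informal volunteering at 7.7 €/h plus 36 h of non-profit
activity at 7.9 €/h, scaled by a 0.7 efficiency coefficient, counted in
full at moderate/severe and at 0.6 at mild. The disease-free utility
weight is 0.826/year; stage-and-setting weights are HUI:2-scale stand-ins
decreasing with stage. Costs and QALYs accrue on cycle-start occupancy
with no half-cycle correction (none is used in the source model; a
`half_cycle` switch exists for sensitivity checks) and discount at
5%/year, i.e. `(1.05)^(−k/2)` at cycle `k`.

Two scope choices shape absolute cost levels: disease-free individuals
(including false positives) accrue no baseline living costs, and
institutionalized patients keep their stage-dependent productivity loss.
The first lowers total per-person costs relative to the published tables —
which include control-level home expenditures — but cancels exactly out of
every between-strategy difference, hence out of ICERs, dominance and PSA
results.

## Ranking and sensitivity analysis

`build_icer_table()` sorts by cost, flags plain dominance, prunes extended
dominance (not exercised by the three published strategies but required for
correctness on arbitrary inputs), and computes frontier ICERs; exact ties
stay on the frontier with an undefined increment. `preferred_strategy()`
takes the most effective frontier strategy whose ICER is under the
threshold and provably coincides with maximal net monetary benefit — a
property the tests check on 1 000 random instances.

The PSA draws each swept parameter independently from a triangular
(low, mode, high) prior — published ranges where printed, e.g. contrast
cost 0–500 €, specificity 0.70–1.00, transitions ±10% via a single speed
multiplier — and runs all three strategies on the identical draw (one
transition-matrix set per draw, shared across strategies). After a draw the
symptomatic stage split is renormalized around the drawn mild share at a
fixed moderate:severe ratio. Acceptability curves report the fraction of
draws in which each strategy attains maximal net benefit. PRCC
rank-transforms draws and the ICER response, residualizes each parameter
and the response on all other parameters, and correlates the residuals;
significance uses `t = r √(df/(1−r²))` with `df = n − 2 − (k − 1)` (the
conventional PRCC t-approximation; the source analysis states only a 5%
confidence level). The ICER response is MRI+CLP versus standard MRI,
falling back to the next frontier comparator when standard MRI is
dominated.

## What the stand-ins can and cannot show

Every value not printed in the source's main text is flagged `STAND_IN` in
the provenance map: the annual stage-transition probabilities (untreated
mild→moderate 0.30/yr and moderate→severe 0.25/yr, within the 0.25–0.35 and
0.2–0.3 bands of the cited progression literature; early→mild 0.20/yr),
treated-row probabilities, stage/setting utilities, care and accommodation
costs, the MRI examination fee (244 €, French procedure-scale magnitude),
the caregiver-health burden (weekly psychiatrist consultation plus an
antidepressant course), age-specific mortality and incidence tables
(five-year bands 60–85+, French-demography magnitudes), per-cycle
institutionalization probabilities (0.01/0.03/0.08 by stage), and the
high-MMSE mild fraction. These were fixed once, from the cited literature
and French scales, and are version-pinned.

With these stand-ins the package reproduces the *structure* of the
published results — the contrast strategy is more costly and more effective
than standard MRI, its screening ICER lies far above any plausible
threshold, the PRCC sign pattern (contrast cost positive; sensitivity,
specificity and prevalence negative) — but not the published ICER
magnitudes or PSA preference probabilities, which depend on the
unpublished supplementary parameter table. The corresponding acceptance
checks are therefore expected to fail until that table is transcribed into
a parameter document; the package's own tests state them at the published
values and tolerances and leave them red rather than recalibrating
stand-ins toward them.

## Problem sizes and numerical settings

Deterministic runs use 6 cycles (memory clinic) or 30 cycles (screening);
PSAs use 10 000 Monte-Carlo trials, as in the source analysis, in both the
acceptance checks and `scripts/acceptance.R`. Property tests use 1 000
random ranking instances and 10 000 triangular draws (Kolmogorov–Smirnov
tolerance 0.02). The Denman–Beavers iteration stops at an update below
1e-14 (at most 60 iterations); validation tolerances are 1e-9 for
row-stochasticity and mass conservation and 1e-12 for the stage-split
simplex. Parameter documents are YAML, chosen over JSON for readable
hierarchical keys and comments; dotted paths address every leaf, unknown
keys are rejected outright so a typo cannot silently leave a base-case
value in place, and serialization emits 17 significant digits so
load–serialize–load round-trips are bit-exact.

## Known limitations

Transition probabilities are time-homogeneous within age bands; no
individual-level simulation, adverse-event or treatment-adherence
modelling, no psychological impact of early diagnosis, and 100% screening
participation — all exclusions shared with the source model. The
embeddability construction makes the half-year scale primary, so the
"annual" stand-in probabilities are one-step half-year rates compounded to
a year rather than the annual marginals themselves; for the magnitudes
involved the difference is second-order, and the published annual matrix
can be substituted directly once transcribed.
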