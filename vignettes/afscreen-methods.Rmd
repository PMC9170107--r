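---
title: "Modeling the effectiveness of AF screening in the elderly"
author: "afscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the effectiveness of AF screening in the elderly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afscreen)
```

## The problem

Atrial fibrillation (AF) is frequently silent, and untreated AF carries a
markedly elevated stroke risk that oral anticoagulation largely removes.
Community screening of people aged 65 and over can surface untreated AF, but
its value hinges on two quantitative questions: *how many cases does one
round of screening find* (detection rate, number needed to screen, and which
subgroups are enriched), and *how much health is gained when a found case is
anticoagulated* (life-years, quality-adjusted life-years, strokes averted).
`afscreen` implements both halves as a reproducible pipeline: screening-
cohort statistics, a Markov cohort model of treated versus untreated AF, a
population-level projection, and a seeded synthetic cohort generator so that
everything runs without access to individual-level study data.

## The cohort model

The model follows a closed cohort from a starting age $a_0 \in [65, 80]$ in
annual cycles through three states: alive pre-stroke, post-stroke, and dead.
Each of three risk profiles — non-AF, anticoagulant-treated AF, untreated AF
— supplies its own age- and sex-banded annual probabilities of incident
stroke $p_s(a)$ and death from any cause $p_d(a)$, transcribed from the
published tables shipped in `inst/extdata/` (5-year bands from 65–69 through
95–99; the 100+ band forces death, closing every cohort by construction).
The post-stroke state has its own *total* annual death probability
$p_{e}(a)$ — it already exceeds the same-band background mortality, so it is
used as-is, not added on top.

Within a cycle at age $a$, death is applied first and stroke among
survivors:

$$\Pr(\text{stroke in cycle}) = (1 - p_d(a))\, p_s(a).$$

Incident strokes split by an acute-stage fatality fraction (5.7% below 75,
10.1% from 75 on, switching exactly at 75) into acute deaths and entrants to
the post-stroke state. The fatality fraction is a property of the stroke
event, so it is applied identically in all three profiles.

Life-years and QALYs accrue per cycle. Utility weights are 1.0 while alive
pre-stroke (only stroke-related utilities are published; the QALY-to-
life-year ratios of the published results, about 0.96, are consistent with a
unit baseline eroded by stroke states), 0.68 (ages 65–74) or 0.56 (75+) in
the post-stroke state, and, in the cycle of an incident stroke, the
post-stroke utility minus a transient acute decrement of 0.14 lasting 0.25
years (i.e. −0.035 for that cycle). By default the post-stroke weight tracks
*current* age — the published utilities are keyed to age bands, not to event
time — with `model_config(poststroke_utility_by = "age_at_stroke")` as the
alternative; internally the post-stroke state is carried as two compartments
(onset before/after 75) so both conventions are exact.

### Accrual and discounting conventions, and their calibration

Two conventions are almost never printed alongside such models: how much of
a cycle members dying during it accrue (half-cycle correction, full cycle,
or none), and whether the first cycle is discounted (0- versus 1-based
exponent). Rather than guess, `calibrate_conventions()` evaluates the 3 × 2
grid against a single published anchor — discounted life-years of 13.585 for
treated men starting at 65 — and freezes the nearest combination:
half-cycle accrual with 0-based discounting (13.690; the runner-up,
half-cycle with 1-based discounting, gives 13.422). Calibration touches only
these two switches, never the transition probabilities or utilities. With
the conventions frozen, all sixteen published life-year/QALY totals are
reproduced within 0.30 and all eight QALY differences within 0.05; both
life-years and QALYs are discounted (at 0% discounting the model's male-65
life expectancy exceeds 16 years, so the published 13.585 can only be a
discounted quantity). The annual discount rate defaults to 2%, validated to
$[0, 0.10]$.

One consequence worth knowing: removing discounting entirely moves the
*difference* between strategies by several tenths of a QALY at the youngest
starting ages (lifetime horizons of 30+ cycles amplify tail-year
differences), so the treatment effect is direction-stable but not
numerically flat across discount rates — `sensitivity_discount()` computes
the exact table.

### Microsimulation cross-check

`simulate()` on a cohort trace (or `microsim_cohort()` directly) re-runs the
identical per-cycle probabilities, accrual rule and discounting as a
vectorised individual-level simulation with a fixed seed, returning
Monte-Carlo means and standard errors. Because it shares no accumulation
code with the deterministic recursion, agreement within Monte-Carlo error
(the test suite uses 3 standard errors at $n = 200{,}000$ per cell) is a
strong end-to-end check of the cohort implementation. At that $n$ a run
takes a few seconds; standard errors on life-years are about 0.013.

## Screening statistics

* **Detection rate** — binomial point estimate with a Clopper–Pearson exact
  interval (`stats::binom.test`); the number needed to screen is the raw
  quotient, rounded only for display.
* **Stratified detection** — the 2×2 of newly detected untreated AF
  (adjudicated AF without a known-AF history) by factor presence. The
  denominator keeps every screened subject with a recorded factor value,
  including those with already-treated AF and uninterpretable recordings:
  that is how the published stratified table is tabulated (its rows total
  the full cohort), and `fixture_table4()` reproduces it exactly. Subjects
  missing the factor drop out of that stratification only — which is also
  how the published hypertension row comes to total 1605 of 1607.
* **Fisher's exact test** — two-sided p as the sum of hypergeometric
  probabilities not exceeding the observed table's (the mainstream-software
  rule), delegated to `stats::fisher.test` and property-tested against a
  brute-force enumeration oracle. For the published hypertension split
  (10/628 vs 5/972) the exact p is 0.03426, which rounds to 0.034; the
  source prints 0.035.
* **Cohen's kappa** — implemented directly from the agreement matrix
  ($\kappa = (p_o - p_e)/(1 - p_e)$); degenerate identical-constant raters
  yield `NA` with a warning.
* **Risk scores** — CHADS2 and CHA2DS2-VASc from their component
  definitions; the age-65–74 point covers all ages in $[65, 75)$, so every
  screened subject (all 65+) scores at least 1 on CHA2DS2-VASc.
* **Diagnostic accuracy** — sensitivity/specificity with Clopper–Pearson
  (default) or Wilson intervals; the published device accuracy cannot be
  re-derived because its raw confusion counts are unpublished, so this
  operation is validated against hand arithmetic and an exact-binomial
  bisection oracle instead.

## Population projection

For each sex and single year of age $a$ (published 5-year band headcounts
divided by 5), with screened prevalence $\pi$ of detected untreated AF at
CHADS2 ≥ 1:

$$b = a_{\text{pop}} \pi, \qquad
  c = S_{10}^{\text{untreated}} - S_{10}^{\text{treated}}, \qquad
  d = 1/c, \qquad e = b\,c,$$

where $S_{10}$ is the model's expected cumulative incident strokes (acute
deaths included, undiscounted) over a 10-year horizon. $c$ is taken as the
per-person cumulative-stroke difference from the cohort model, recomputed at
every single year of starting age by default (`risk_by = "band"` reuses the
band edge); the same prevalence — 12/1607 under the published score
breakdown — applies to every cell, as the single published constant implies.
The identities $e/b = c$ and $d = 1/c$ and exact linearity in the population
are unit-tested; national totals depend on the user-supplied population
table (the shipped `population_synthetic.csv` is a synthetic stand-in, not
vital-statistics data).

## The synthetic cohort generator

`generate_cohort()` emulates the screening campaign's marginal structure:
ages normal (72.4 ± 5.8) truncated at 65 via inverse-CDF sampling, 51.5%
women, independent Bernoulli comorbidities at the published prevalences,
43/1607 known AF, untreated-AF prevalence 15/1607 overall with a threefold
hypertension rate ratio (the non-hypertensive rate is calibrated so the
marginal matches; an infeasible ratio raises an error), two independent
readers with configurable sensitivity/specificity, third-reader tiebreaks
taken as truth, and device unclassified/uninterpretable rates of 33/1607 and
2/1607. What it deliberately does **not** emulate: comorbidity correlations
(only marginals are published), effects of factors other than hypertension
on AF status, per-reader asymmetries, and any ECG waveform content. Passing
tests therefore demonstrate correct recovery of the generating parameters,
not realism of joint clinical structure.

`fixture_table4()` is deterministic, not sampled: it realises the published
stratified counts exactly. The published tables are internally inconsistent
in one particular: the per-component detected counts imply 17 CHADS2 points
across the 15 cases while the published score breakdown sums to 18. The
fixture keeps the stratified counts and the (feasible) CHA2DS2-VASc
breakdown exact, and realises the nearest feasible CHADS2 breakdown
(4, 7, 2, 2 for scores 0–3 instead of 3, 8, 2, 2).

## Numerical choices and test scale

* Occupancy conservation is asserted to 1e-12 per cycle; death is absorbing
  and every trace ends fully dead.
* Probabilities are stored as fractions; CSVs may carry percents behind a
  declared unit flag, and a write/read round trip is exact at the printed
  3-decimal percent precision.
* Age bands are closed on the left (75 belongs to 75–79); ages 100+ use the
  terminal band; the acute-fatality and post-stroke-utility boundaries
  switch exactly at 75.
* Test problem sizes: microsimulation cross-checks at $n = 200{,}000$ per
  effectiveness cell (and 50,000 in unit tests); Fisher-versus-enumeration
  exhaustively at table totals 6, 12 and 16 plus 400 sampled tables up to
  total 60; generator-recovery checks at $n = 100{,}000$. These sizes give
  comfortable statistical resolution while keeping the full suite to about
  half a minute.

## Limitations

No costs are modeled (the source analysis performed none), no incidental AF
detection outside screening, no treatment crossover (the untreated profile
is untreated for life), and no uncertainty intervals around the national
projection. The transition probabilities are taken as published; their
derivation from the underlying registries is out of scope.
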