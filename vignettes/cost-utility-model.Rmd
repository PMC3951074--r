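---
title: "A Markov cohort cost-utility model of cochlear-sparing proton therapy for childhood medulloblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of cochlear-sparing proton therapy for childhood medulloblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonCEA)
```

## The question

Children cured of medulloblastoma by craniospinal irradiation plus
cisplatin chemotherapy frequently develop severe, irreversible (Grade 3–4)
hearing loss, because the cochlea sits next to the boost volume and the
risk rises steeply with its mean radiation dose. Proton beam therapy
delivers the same target dose with a much lower cochlear dose — at roughly
nine times the price of a conventional X-ray course. `protonCEA` asks
whether that price buys enough lifetime quality of life to be worth paying,
from the healthcare payer's perspective, for a cohort treated at age 6.

## The model

### States and cycle structure

The core is a deterministic three-state Markov cohort model in annual
cycles: *alive without hearing loss*, *alive with hearing loss* (aided),
and *dead* (absorbing). The cohort starts at age 6 in the no-hearing-loss
state and is followed until age 100, i.e. 94 one-year cycles. Within each
cycle the annual death probability is applied first and a fraction of the
surviving unaffected members then converts to the hearing-loss state.
Ordering death before conversion makes the plateau hearing-loss prevalence
*among survivors* equal the lifetime risk parameter exactly, which is how
those risks are defined clinically; a test asserts this identity to 1e-9.

Because mortality is the same in both alive states ("hearing loss does not
kill"), the recursion telescopes to a closed form — survival is the running
product of one-year survival factors and hearing-loss occupancy is survival
times cumulative incidence. `run_cohort()` computes that closed form; a
test verifies it equals the explicit transition-matrix recursion cycle by
cycle.

Rewards (costs and QALYs) accrue at cycle end, and cycle 0 carries only the
radiation course cost. No half-cycle correction is applied: the annual
rates the model consumes are themselves end-of-year quantities, and the
convention is shared by both arms, so the incremental comparison is
affected far less than the roughly 1–2% shift in absolute QALY totals such
a correction would make. Both arms and all utility indexes share one
engine evaluation, so the incremental results are exact differences, not
differences of independently rounded runs.

### Two risk groups, two arms

The cohort splits 70% / 30% into an average-risk and a high-risk group,
which differ in 5-year overall survival (85% vs 70%), cochlear dose, and
hearing-loss risk. Each treatment arm is the weighted mixture of the two
group-level cohorts (`mix_cohorts()`); all accounting is linear in cohort
mass, so mixing after running the groups is exact. The arms share
mortality entirely — the treatments are assumed equally curative — so the
comparison isolates ototoxicity.

Lifetime Grade 3–4 hearing-loss risks are the model's four key inputs
(X-ray 39.00% / 47.11%, proton 15.55% / 26.53% for average / high risk).

### Hearing-loss onset timing

Hearing loss appears no earlier than one year after treatment and the
cumulative incidence plateaus from year three. Between those bounds the
model uses equal cumulative increments — for a 39% lifetime risk, 13% / 26%
/ 39% of survivors affected after cycles 1, 2, 3. The increments are
converted to conditional per-cycle conversion probabilities
(`onset_fraction()`). The equal-increment ramp is the least-structured
schedule consistent with the stated one-year delay and three-year plateau;
a step at year 1 would front-load aid purchases by at most two years and
moves discounted results negligibly.

### Mortality

Years 1–5 after treatment use a constant annual disease hazard `q` solving
`(1 − q)^5 = OS5` per risk group — the geometric shape is the simplest
consistent with the single printed constraint, and the trial OS is treated
as all-cause over that window (adding background mortality on top would
double-count). From year 6 the disease contributes no excess mortality
(survival plateau) and the annual death probability comes from a life
table at the attained age.

No official complete life table ships with the package. Instead
`generate_life_table()` synthesizes one from the Gompertz–Makeham law,
hazard `A + B·exp(r·age)`, with defaults `A = 2e-4`, `B = 1.5e-5`,
`r = 0.1` calibrated so period life expectancy at birth is ≈ 82 years — a
modern low-mortality (contemporary-Japan ballpark) population, both sexes
pooled since the cohort's sex split is not an input. The generated table
is committed verbatim as `extdata/lifetable_synthetic_jp.csv` so results
are bit-stable; a test asserts regeneration reproduces the file exactly.

The synthetic table is an approximation, and the package demonstrates that
nothing rides on it: inflating or deflating the hazard-level parameters
(`makeham`, `gompertz_scale`) by 20% — singly or jointly, a ±2-year swing
in life expectancy — moves the incremental cost and QALY results by less
than 2% (tested). The exponential `gompertz_rate` is a different animal:
±20% there moves life expectancy from 82 to 70 or 94 years, far outside
any plausible life-table misfit, and even that extreme shifts the QALY
increment by only ~4–5%. Users with an official table can supply it as a
two-column `age,qx` CSV via `load_life_table()`.

### Utilities and QALYs

Three preference-based indexes value the aided hearing-loss state: EQ-5D
0.807, HUI3 0.644, SF-6D 0.792. HUI3 contains explicit hearing and
cognition attributes and is therefore the most sensitive to the outcome.
The alive-without-hearing-loss state carries utility 1.0 by default. That
choice is not directly observable — only the aided-state utilities are
published — but the resulting QALY totals are consistent with full utility
for unimpaired survivors, and `u_no_hl` is configurable for users who
prefer population norms below 1. QALYs are discounted at 3% per year, the
same rate as costs.

### Costs

Payer-perspective direct medical costs only: the radiation course at
cycle 0 ($3,082.20 X-ray, $26,943.90 proton), and per incident hearing-loss
case a hearing test ($65.40), an aid fitting test ($121.50) and a hearing
aid ($2,086.90) at onset, annual hearing tests in the following two years,
and a replacement aid every 5 years for life (one aid per purchase;
bilateral provision would double that line). Deferred payments are
pro-rated by the onset cohort's survival to the purchase cycle. Follow-up
testing is attached to onset only, not to later replacements — a reading
that may slightly understate hearing costs. No indirect costs, no price
inflation, no currency conversion beyond a fixed reporting rate of
JPY 107/USD.

### Incremental comparison

For each utility index the model reports discounted cost and QALYs per
arm, their differences, and the ICER `ΔCost/ΔQALY` computed from unrounded
values (the printed, rounded ΔQALY would give a visibly different
quotient). A zero QALY difference flags the ICER undefined rather than
dividing. Cost-effectiveness is judged against a willingness-to-pay
threshold of $46,729/QALY (JPY 5 million/QALY), via the net monetary
benefit `WTP·ΔQALY − ΔCost`.

## The dose–response tool

The mechanism linking the two arms is the logistic relation between mean
cochlear dose and Grade 3–4 hearing-loss incidence under fixed cisplatin
co-exposure. The source studies' regression coefficients are not
recoverable from the published anchor values, so the base case feeds the
anchor risks into the Markov model directly, and `fit_logistic()` /
`calibrated_dose_response()` provide a calibrated scenario tool instead:
two-point logit interpolation is exact through each arm's anchors, ≥ 3
anchors are fit by unweighted least squares on the logit scale (the
simplest defensible choice absent any stated weighting), and a model
averages its member curves on the probability scale by default (the
logit-scale mean is an option, since a narrative "average of the two
equations" admits both readings). `risks_at_doses()` rewrites the four
risk inputs from such a model so the whole analysis can be re-run at
alternative cochlear doses.

## Uncertainty analysis

**One-way (tornado).** Each uncertain parameter in turn is set to the ends
of its studied range while the others stay at base, and the ICER is
recomputed: both 5-year survivals, the four hearing-loss risks, the
high-risk share, the index's utility weight, both radiation course prices,
the hearing-aid price, and the discount rate over 0–7%. Parameters whose
published range is a ±25% variability assumption (hearing test, fitting
test) carry that default range. Entries are sorted by ICER spread.

**Probabilistic (PSA).** All ranged parameters are drawn jointly and
independently from triangular distributions `(low, base, high)` —
independence because no correlation structure is published — and the full
model is re-evaluated per draw; 10,000 draws per utility index is the
default. The discount rate is drawn too, Triangular(0, 0.03, 0.07) over
its studied span. That inclusion was a genuine design fork: the published
range table gives the discount a span but not a distribution. Holding it
fixed leaves the acceptability probability at the threshold above 99.9%
for every index, because the Table-range parameters alone cannot push the
ICER past the threshold; propagating discounting uncertainty with
everything else spreads the curves to their expected separation (roughly
96–100% across indexes). "Everything varies simultaneously" is therefore
read as including the discount rate; `vary_discount = FALSE` restores the
fixed-rate variant. Draws where a proton risk exceeds its X-ray
counterpart (possible under independence, since the ranges overlap) are
retained as drawn and flagged, not rejected — rejection would bias the
marginals.

All randomness flows through one integer seed; identical seeds give
bitwise-identical sample tables, and the seed is recorded in the run
manifest.

**Acceptability curves.** `ceac()` reports, for each willingness-to-pay
value on a $0–150,000 grid (the $46,729 threshold always included
exactly), the fraction of draws with strictly positive net monetary
benefit, per index and "integrated" — the three per-index sample sets
pooled with equal weight, which has the same expectation as drawing an
index at random per trial.

## Numerical conventions and degenerate inputs

* State-vector conservation is maintained to 1e-12 per cycle (tested).
* Triangular sampling uses the closed-form inverse CDF; zero-width ranges
  return the mode with probability 1.
* A lifetime risk of exactly 1 makes the conversion denominator vanish at
  the plateau; the conditional probability is defined as 0 there (no one
  is left to convert).
* Life tables must cover ages 0–100 contiguously; an optional terminal
  clamp forces `q = 1` at the last age. The model horizon never looks
  beyond the table because the trace ends at age 100.
* Configuration files are YAML mirroring the parameter structure; unknown
  keys are an error (typos must not silently leave defaults in place),
  and numbers are serialized at 17 significant digits so a save/load round
  trip is bitwise lossless.

## Problem sizes

The deterministic base case (four group-level cohorts of 94 cycles plus
cost accounting) runs in milliseconds. The shipped default of 10,000 PSA
draws — each a full model evaluation shared across the three indexes —
takes well under a minute; the test suite exercises the full-size PSA once
and uses 30–2,000 draws elsewhere.

## Limitations

* The background life table is synthetic; headline results are shown to be
  insensitive to its level, but country-specific absolute QALY totals
  should use an official table.
* The healthy-state utility (1.0) and the exact onset ramp are modelling
  conventions, not published quantities; both are configurable.
* The model has no relapse, second-malignancy or other-toxicity states:
  it isolates ototoxicity, so it understates any additional proton benefit
  from sparing other organs.
* Cohort expectation only — no individual-level microsimulation, hence no
  between-patient variance beyond parameter uncertainty.
* PSA draws are independent; any true correlation (e.g. between the two
  arms' risks, which share source studies) is not modelled, and draws
  violating the dose–risk ordering are only flagged.
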