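---
title: "Modelling the health and economic burden of tobacco smoking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and economic burden of tobacco smoking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobaccoburden)
```

## The model

`tobaccoburden` implements a first-order Markov microsimulation of the
disease and economic burden attributable to tobacco smoking, together with a
policy projection engine for tobacco-control measures. The estimand
throughout is counterfactual: how much death, disease and cost would not
occur if the population had never smoked. Two cohorts of the same simulated
individuals are advanced in annual cycles — one with the observed smoking
profile, one forced to never-smoker status — and the attributable burden is
the difference.

Each simulated individual carries sex, age, a smoking state (never /
current / former), and a disease history over sixteen smoking-related
conditions: four acute, recurrent conditions (acute myocardial infarction,
non-AMI coronary events, stroke, pneumonia) and twelve chronic absorbing
states (COPD, non-ischemic heart disease, ten cancers and leukemia). Within
each annual cycle, events are applied in a fixed, documented order:

1. smoking-state transition (current smokers quit with a constant annual
   probability; the former-smoker relative risk is constant in time since
   quitting, a parameter rather than a hard-coded decay),
2. per-condition event draws with hazard `h * RR(state)` converted to a
   one-cycle probability `1 - exp(-h * RR)`,
3. acute case fatality,
4. chronic in-state mortality,
5. background (non-modelled-cause) mortality from the life table,

after which survivors age by one year. Cycles are one year with no
half-cycle correction, matching annual reporting. The cause of a death is
the first condition (in registry order) whose draw fires in that cycle.

Chronic disease states are seeded at baseline from the steady-state
prevalence approximation `incidence x RR(state) x mean duration`, so the
year-1 snapshot already contains the prevalent cases whose deaths the annual
mortality tables count.

### Common random numbers

Every cycle's uniforms are drawn for all `n` individuals, dead or alive,
from a per-cycle seed derived from the master seed. Factual and
counterfactual runs at the same seed therefore consume identical random
streams: an individual who has an event in the counterfactual arm
necessarily has it in the factual arm (relative risks at or above one), and
the difference between arms isolates the smoking effect with far less
Monte-Carlo variance than independent runs. Death at an acute event reuses
the event uniform (`u < p_event * case_fatality` given `u < p_event`),
which preserves the conditional probability while keeping the number of
draws fixed.

Two consequences are worth knowing. First, dominance is exact for the set
of deaths (every counterfactual death is a factual death) and for acute
event cells, but not for chronic incident-event cells: the factual arm's
larger prevalent pool masks incidence, so attributable counts are defined
as the cell-wise difference floored at zero. Second, over a full lifetime
cause-specific death counts partially re-converge between arms — everyone
dies of something, and never-smokers reach ages where hazards are large —
so attributable fractions are reported from the annual snapshot (year-1
outcomes), while DALYs accrue over the full residual life expectancy and
state duration of the people affected that year.

## Burden accounting

For each condition and sex the annual table reports total deaths and
events, attributable deaths and events, and the attributable fraction
`100 x attributable / total`, rounded half-up to one decimal only at report
time. YLL is the sum of period life-table residual life expectancy at the
age band of death, undiscounted and without age weighting; YLD is
attributable incident cases x disability weight x mean state duration; and
`DALY = YLL + YLD` is enforced as an identity in every report.

Perinatal effects and secondhand smoke are outside the condition set; they
enter as a fixed proportional uplift on the sex-specific attributable
totals (13.6% for men, 12% for women), appended as a separate row whose
event cells stay empty. Counts are rounded half-up to integers at report
time; internal arithmetic is never rounded.

## Costing

Four categories, all reported in millions of 2020 USD:

- **Direct medical**: attributable case-years (incident cases x mean
  duration, the steady-state incidence-prevalence identity) x annual unit
  cost. Unit costs are stored in 2015 local currency, inflated by the
  2015-2020 cumulative factor (10.47%) and converted at PEN 3.3 per USD —
  in that order, which is the convention the rest of the accounting
  follows.
- **Premature mortality**: the human-capital present value of forgone
  labour income, `sum_t wage(age+t) (1+g)^t / (1+r)^t` up to retirement,
  with `r = 5%` and wages from a sex-specific Mincer log-wage equation
  (education, age, age squared) at the stratum mean education. Deaths at or
  after retirement contribute zero by construction, so only pre-retirement
  deaths are costed. Discounting applies to monetary streams only, never to
  health outcomes.
- **Disability / presenteeism**: productivity lost while working ill,
  proportional to the quality-of-life decrement: wage x disability weight x
  state-years, restricted to working ages (before retirement).
- **Informal care**: unpaid caregiving hours per case-year valued at a
  care-worker hourly wage, the opportunity-cost proxy.

The secondhand-smoke group receives the same sex-specific uplift applied to
the sum of the condition groups in each category. Conservation — grand
total = sum of the four categories = sum of the seven condition groups — is
an enforced identity. The GDP used for share-of-GDP reporting defaults to
USD 219,039 million, the denominator consistent with the published
share arithmetic this package reproduces.

## Policy projections

All four measures act through one mechanism: a relative reduction `Em` in
tobacco consumption, of which a share `Ip` (default 0.5) is expressed as
lower smoker prevalence:

```
prev_post = prev_pre * (1 - Em * Ip)
```

Prevalence movers become former smokers — quitting, not history erasure —
and, because movers are the lowest-uniform current smokers, scenarios at
increasing `Em` are nested and avoided burden is monotone by construction.
For tax scenarios `Em = min(1, |elasticity| x price_increase)`, a
constant-elasticity approximation; the default elasticity of -0.4 is a
typical LMIC value, **not** an estimate from the modelled study, and is a
configurable scenario input. The same caveat applies to the packaged `Em`
placeholders for packaging, smoke-free and advertising-ban scenarios: the
study's own effectiveness values live in unavailable supplementary
material.

A scenario run simulates three arms at a common seed over the ten-year
horizon — base case, post-policy, and the never-smoker counterfactual that
defines attributable burden — and accumulates annual differences.
Population, unit costs and wages are held fixed (a steady state in which
only prevalence changes), and the ten-year stream is not discounted.
Smoke-free scenarios additionally scale the secondhand-smoke row by
`1 - shs_risk_reduction`. Tax scenarios add the change in excise revenue,
with the tax absorbing the full price increase:
`(tax + Δprice) x consumption x (1 - Em) - tax x consumption` per year.
Note that this quantity is not guaranteed positive for every combination of
tax share, price rise and elasticity — at a 73.3% tax share it is positive
throughout the realistic grid (|elasticity| ≤ 0.6, rises ≤ 75%) that the
tests cover.

## Calibration

Model-predicted cause- and sex-specific mortality is compared to a
registry-style reference table; a cell passes when its relative deviation
is within 15%. Failing cells receive a damped multiplicative update
`(reference/model)^0.5` of a per-condition, per-sex calibration scale. The
scale acts on the mortality-producing pathway — case fatality for acute
conditions, the baseline onset hazard for chronic ones. The onset pathway
was chosen for chronic conditions because deaths respond linearly through
the prevalent pool, giving geometric convergence of the damped iteration;
scaling the in-state death probability saturates and stalls. Relative
risks are never touched, so the smoking effect survives calibration.

Cells are condition x sex, with age bands pooled: at workable simulation
sizes per-age-band cause-specific death counts are Poisson-noisy enough
that a 15% rule would chase noise rather than signal. For the same reason,
cross-seed validation of a calibrated model can flag rare-condition cells
(tens of deaths) whose sampling noise exceeds 15%; calibration therefore
runs at a fixed seed and the validation report should be read alongside
expected counts.

## The synthetic country generator

No registry inputs ship with the package; `generate_country()` produces a
complete, internally consistent parameter bundle, and
`peru_like_model()` is the packaged default: a population of 10.5 million
adults 35+ over 5-year bands (35-39 ... 95+) with a declining pyramid,
current-smoker prevalence targeting 11.6% (men) and 2.6% (women) — 7.1%
overall — former-smoker prevalence 15% / 6% with an age profile in which
ex-smokers accumulate at older ages, Gompertz-like age growth for all
disease hazards, and relative risks in the ranges epidemiology reports:
cardiovascular 1.5-3, COPD 10, lung cancer 25, laryngeal cancer 14,
pneumonia 2.2 (treated as an infectious condition with a modest RR; the
5-15 band describes COPD). These choices place the fixture's year-1
lung-cancer attributable-death fraction near 75%, inside the 70-90% band
that the published magnitudes suggest, and were fixed once at design time.

What the generator does **not** emulate: cohort smoking histories (risk
depends only on the current state and a constant former-smoker RR), real
registry age patterns, regional heterogeneity, covariance between
conditions, or time trends. Passing tests on this fixture therefore
demonstrate that the machinery is correct — arithmetic identities, oracle
agreement, monotonicities, calibration recovery — not that any particular
country's burden is reproduced. The published headline magnitudes (22,350
deaths; 126,000 events; 515,768 YLL) depend on a national parameter table
that is not publicly deposited, and the package makes no claim to reproduce
them; its printed-table arithmetic layer reproduces the published
percentage cells exactly from the published counts, which is the part that
can be verified.

## Numerical choices and problem sizes

- Hazard-to-probability conversion is `1 - exp(-h)` throughout; hazards and
  probabilities are never mixed.
- Report rounding is half-up (counts to integers, percentages to one
  decimal); ties like 20.45 round to 20.5 as printed tables do.
- Forced terminal death at age 105 bounds every lifetime simulation at 70
  cycles.
- Reproducibility is bit-exact for identical (model, n, seed, mode); the
  per-cycle seed derivation keeps all seeds below 2^31.
- The default problem sizes — 50,000 individuals per arm for burden and
  calibration, 20,000 per arm for scenario projections, 3 x binomial SE
  for oracle agreement — were chosen so the full validation battery runs
  in a few minutes on one CPU while keeping Monte-Carlo error well inside
  the tolerances being asserted.

## Known limitations

- Smoking history is first-order: risk depends on the current state only,
  and the former-smoker RR does not decay with time since quitting (the
  published life-expectancy ordering never > former > current is
  reproduced qualitatively, not its exact year gaps).
- No dynamic demography (births, ageing-in, migration) and no interaction
  between conditions beyond shared mortality competition.
- Annual cycles without half-cycle correction bias person-time slightly
  relative to continuous time.
- The steady-state case-year approximation (incidence x duration)
  understates costs for conditions whose prevalence is far from
  equilibrium.
- Absenteeism, environmental costs, alternative nicotine products, equity
  analysis and policy-combination synergies are out of scope.
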