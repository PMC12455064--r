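---
title: "A tunnel-state Markov model for risk-stratified breast-cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tunnel-state Markov model for risk-stratified breast-cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsscreen)
```

## The decision problem

`prsscreen` evaluates whether polygenic-risk-stratified breast-cancer
screening is good value compared with Taiwan's age-based program, from the
healthcare payer's perspective. The comparator screens every woman
biennially from 45 to 69. The stratified strategy genotypes every
35-year-old (one-time cost: SNP array US$126.40 plus genetic counseling
US$54.17, 2021 US$), classifies her by polygenic risk score percentile
into low (below the 35th percentile, 35% of women), intermediate
(35th–95th, 60%) or high (above the 95th, 5%) risk, and then screens only
the intermediate (from 40) and high (from 35) groups, biennially to 69.
Risk groups differ only through incidence multipliers — 0.6, 1.1 and 1.5
times the population's age-specific incidence — and through their
schedules; the model deliberately consumes group proportions and
multipliers rather than computing a risk score from genotypes.

## States and transitions

The cohort model has ten states: healthy; for each stage *s* ∈ {I, II,
III, IV} a first-year tunnel state and a later-years state; and death.
Tunnel states exist purely to let the first year after diagnosis carry a
lower utility than subsequent years while the process stays Markov: a
woman diagnosed in cycle *t* occupies the tunnel for exactly one cycle and
then moves to the later-years state of the same stage (no remission, no
stage progression after diagnosis).

Out of the healthy state, the annual cancer rate at age *a* for a woman in
group *g* is `inc(a) * m_g`, multiplied by the mammography sensitivity
Se = 0.835 in cycles where her schedule includes a screen — an unscreened
cycle omits Se, so it produces *more* diagnoses per year of exposure but
draws stages from the worse clinically detected mix (stage III+IV share
0.26 vs 0.15 screen-detected). The rate converts to a probability as
`1 - exp(-rate)` *before* the stage split, so the stage mix is preserved
exactly. Death from the healthy state uses the age-band all-cause
mortality (excluding breast cancer). In cancer states, the stage-specific
breast-cancer mortality rate is scaled by an age-adjustment factor —
0.151 (35–44), 1.000 (45–64, reference), 1.739 (65+), derived as ratios
of crude age-specific breast-cancer mortality (5.5, 36.4 and 63.3 per
100,000) to the reference group — and competes with all-cause mortality
under independence: the cause-specific survival probabilities multiply.

Age-band tables are closed intervals looked up by integer age at cycle
start; an age past the last band would clamp to it (none occurs with
start age 35 and a 50-year horizon ending at 84).

## Accrual, discounting, and their switches

Occupancy is measured at cycle start; cycle *t* (with *t* = 0 at age 35)
accrues life years for the alive fraction, utilities per state (healthy
1.0; tunnel utilities 0.85/0.85/0.70/0.52 by stage; later-years
0.95/0.95/0.85/0.60; death 0), stage-specific annual treatment costs
(US$2,444 / 3,039.56 / 4,678.02 / 13,396.20, identical in both tunnel
phases), the US$44.96 mammogram for the full healthy occupancy of a
screened cycle (including the fraction whose cancer that screen detects),
and the one-time testing cost for the alive fraction at the genotyping
age. Everything is discounted by `v^t` with `v = 1/(1+r)`, r = 3%/year.
A no-event cohort therefore earns exactly the 50-term discounted annuity
(26.502 at 3%, 50.000 undiscounted), which the tests pin down.

Three conventions the model class leaves open are explicit switches in
`default_parameters()$options`, with the defaults used everywhere in this
package:

* `discount_timing` — `"start"` (default) uses exponent *t*; `"end"` uses
  *t* + 1. There is no half-cycle correction; with annual cycles and a
  50-year horizon the difference is a near-uniform factor.
* `cancer_allcause_mortality` — `TRUE` (default) applies background
  mortality inside cancer states as an independent competing risk.
  Switching it off makes long-surviving early-stage patients immortal to
  everything but breast cancer, which overstates their life expectancy at
  old ages.
* `psa_source` — `"printed"` (default) samples the probabilistic analysis
  from the distribution parameters as tabulated; `"range"` re-derives
  them from the base values and their stated ranges by method of moments
  (`derive_distribution_from_range()`, sd = half-width/1.96). The two
  agree for costs (the tabulated gamma shape 42.7 *is* the ±30% CV
  reading) but not exactly for utilities and sensitivity, whose tabulated
  beta parameters imply means slightly below the deterministic base
  values (e.g. beta(27.3, 6.4) has mean 0.810, not 0.835). The printed
  parameters are used verbatim by default.

Cancers missed by a screen (the 1 − Se complement) simply remain in the
healthy state facing future hazards; there is no latent-disease
compartment, no overdiagnosis, and no false-positive pathway. New-case
counts ("cases per 1000 women") are undiscounted.

## Scenarios, tornado, and the probabilistic analysis

The bundled scenario preset (`default_scenarios()`) holds nine rows: the
base case; three alternative percentile splits (30/60/10, 35/55/10,
30/65/5 — proportions change, multipliers do not, because no alternative
multipliers are defined for the shifted cutoffs); high-risk start at 40;
risk-stratified stop at 74; the 40–74 comparator (which also extends the
risk-stratified stop to 74 so both strategies share an upper limit); SNP
genotyping at 40 (which moves the one-time cost *and* both screened
groups' start ages to 40); and 40/50/10 population proportions.

The tornado varies seven factors one at a time: the three multipliers and
mammography sensitivity by ±20% (the sensitivity's upper bound capped at
1.0, since 0.835 × 1.2 exceeds the probability scale), the four stage
costs jointly and the genotyping and counseling costs by their tabulated
±30% ranges, and the eight tunnel utilities jointly by ±0.1 capped at
1.0. Stage costs and stage utilities move jointly because each is a
single named factor of the analysis; bars are sorted by |ICER(high) −
ICER(low)|. Note that when an incremental QALY difference crosses zero
inside a factor's range the ICER is discontinuous and the bar width loses
meaning; the table reports the signed endpoint ICERs so this is visible.

The probabilistic analysis draws all 16 uncertain parameters
independently — no correlation structure is specified — with gamma costs
(shape/scale), beta utilities and sensitivity (clipped to [0, 1]),
and normal multipliers resampled until positive. Both strategies are
evaluated on the *same* draw by the unchanged deterministic engine.
The acceptability curve reports the fraction of draws with strictly
positive net monetary benefit, `ΔQALY × WTP − ΔCost > 0`, on a default
grid of 0–1,000 US$/QALY in steps of 10 plus the 30,000 reference
(strict inequality, so a zero-NMB draw does not count as cost-effective).

## The synthetic generator and the microsimulation oracle

`generate_params()` emulates the *structure* of the real inputs — an
age-increasing log-linear incidence curve, Gompertz-like background
mortality, simplex stage mixes with the clinical mix later-stage than the
screened one, stage-monotone costs/mortality/utilities, tunnel utilities
below later-year utilities — without mimicking any registry's values. It
exists so that engine invariants (mass conservation, monotone death
occupancy, QALY ≤ LY, oracle agreement) are tested across a family of
models rather than at one point; passing those tests says the *engine* is
correct, not that any synthetic configuration resembles Taiwanese
epidemiology.

`microsimulate()` walks individual women through exactly the per-cycle
categorical distributions of the transition matrix — one draw per woman
per cycle, no event-time sub-cycling — so its state frequencies are
unbiased estimates of the cohort trace and its mean discounted outcomes
estimate the accumulator's. It is the package's independent check of the
cohort algebra: the test suite compares occupancies at every cycle within
3 standard errors at n = 200,000 for the default configuration (and at
smaller n across random synthetic sets), a size chosen to resolve
occupancy errors of a few parts in 10,000 while keeping the suite fast.
During development this oracle caught a genuine off-by-one-cycle error
(newly diagnosed women being exposed to cancer mortality in their
diagnosis cycle), which is precisely the class of bug it exists to catch.

## Numerical choices and degenerate inputs

Rate-to-probability conversion is `1 - exp(-r)` throughout; probabilities
out of healthy are checked to sum below 1 (they cannot exceed it at
realistic magnitudes). Transition rows must sum to 1 within 1e-12 and
traces conserve mass within 1e-9. Validation is non-throwing and reports
every violated rule at once; loading a config validates and then throws
with the full list. A zero-variance ("point") distribution is a legal PSA
spec and reproduces the deterministic base case; a zero-width one-way
range yields a zero-width tornado bar; schedules degenerate gracefully
(`build_schedule(a, a)` is a single screen). ICERs are reported only when
ΔQALY ≠ 0; cheaper-and-better / dearer-and-worse pairs are labelled
dominant / dominated with the signed ICER retained.

## Known limitations

The model inherits the scope of the analysis it implements: no natural
history or preclinical sojourn, no remission or post-treatment states, no
screening harms (overdiagnosis, false positives, recalls), perfect
adherence, and costs fixed in 2021 US$ with no inflation adjustment.

One further limitation matters for interpretation. The acceptance suite
compares this implementation against the reference results reported for
this screening evaluation, and the deterministic *structure* reproduces
them: every scenario moves the ICER in the reported direction, the
discount-rate analysis is dominant at 0–1% and increasingly unfavourable
at 5%, the risk-multiplier tornado bars dominate with negative low-end
ICERs, and the between-arm case ratio matches to three decimals. The
reported *absolute increments*, however, are not reachable from the
tabulated inputs under any structural switch this package exposes: an
incremental life-year gain near 0.99 per woman alongside 2.65 fewer
cases per 1000 women would require several hundred life years per
avoided case, and the reported incremental costs sit a nearly constant
~US$44 above what the tabulated costs generate across all scenarios.
The package therefore reports what the stated inputs imply — an ICER two
orders of magnitude smaller but the same qualitative conclusion
(cost-effective at any plausible willingness-to-pay) — and the
acceptance tests record the divergence rather than hiding it.

## Problem sizes used by the test suite

Deterministic checks run the full 50-cycle model (milliseconds per
evaluation). The probabilistic acceptance check uses the full 10,000
iterations; distribution-moment tests use 4,000 draws; the oracle runs at
n = 200,000 for the default configuration and n = 4,000–20,000 across
synthetic sets. These sizes make Monte Carlo bounds tight enough to be
meaningful while the whole suite completes in well under a minute.
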