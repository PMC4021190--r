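---
title: "Model and methods: family-history-targeted colorectal cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: family-history-targeted colorectal cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The problem

People with a strong family history of colorectal cancer (CRC) — one
first-degree relative diagnosed before 55, or two first-degree (or one
first- plus one second-degree) relatives diagnosed at any age — carry
roughly a three- to six-fold excess risk relative to the average-risk
population. Australia's National Bowel Cancer Screening Programme (NBCSP)
offers this group the same one-off iFOBT invitations as everyone else, at
ages 50, 55, 60 and 65. `crcscreen` implements a Markov microsimulation that
asks whether more intensive, risk-targeted screening — biennial iFOBT,
ten-yearly colonoscopy, or the NHMRC-recommended five-yearly colonoscopy —
would be cost-effective for this cohort, in incremental cost per life-year
gained (LYG) against the NBCSP baseline, from a third-party-payer
perspective with direct costs only and no quality adjustment.

## State space and cycle structure

A simulated person occupies one of 14 states: `Normal`, small (<10 mm) and
large (>=10 mm) adenoma, post-polypectomy `Surveillance`, undiagnosed CRC at
Dukes' stages A-D, diagnosed/treated CRC at the same stages, and two
absorbing death states (CRC, other causes). The cohort enters at age 50 with
the published initial prevalences and cycles annually to age 90. Each cycle
runs: primary screening round (if invited and eligible), surveillance
colonoscopy (if due), one natural-history transition, then accrual. The
adenoma-carcinoma sequence drives onset: normal bowel grows small adenomas,
small adenomas grow large at the large-adenoma incidence, and 85% of
incident cancers originate in large-adenoma carriers.

Within a cycle, competing risks resolve in a fixed order — other-cause
death, CRC death, symptomatic diagnosis, one-stage progression, then lesion
onset/growth — each event conditioned on the earlier ones not occurring.
The `diagnosis_before_progression` flag swaps diagnosis and progression for
A/B comparison. There is no half-cycle correction: events and accruals fall
at cycle end, so a person's life-year and any treatment cost for a cycle are
credited only if they are alive after its transition, discounted at
$(1+r)^{-t}$ with $t = \text{age} - 50$ and $r = 0.05$ per year.

## Parameters and their interpretation

All published quantities ship as the bundled default profile
(`crc_parameters()`): age-band incidences, stage-specific yearly CRC
mortality and symptomatic-diagnosis probabilities, test characteristics
(iFOBT sensitivity 0.479 for CRC, 0.2119 for polyps, specificity 0.9146;
colonoscopy 0.95 / 0.85 / 1), 40% uptake, 65% diagnostic follow-up
compliance, unit costs, stage-specific annual treatment costs, and the 5%
discount rate. Incidences and age-50 prevalences are stored at average-risk
scale; `apply_risk_multiplier()` scales them by the familial relative risk
(base 4, sensitivity range 3-6), clamping at 1 and renormalising the initial
distribution, which then reproduces the published moderately-increased-risk
prevalences exactly (e.g. small adenoma $0.0417 \times 4 = 0.1668$, normal
0.78).

Four interpretive choices were genuinely open; the package decides them as
follows and exposes each as a flag.

**Adenoma incidence scale.** The published adenoma incidence rows
(0.22-0.32 per year for small adenomas) cannot be annual probabilities for
this model: multiplied by 4 they saturate at 1, every simulated person
carries a large adenoma by about age 55, polypectomy has no durable
preventive effect, and the large-adenoma occupancy exceeds the 85%
origination share, which would make carriers *less* cancer-prone per person
than clean bowel. The default therefore reads them as per-5-year-band
probabilities, converted by $1-(1-p)^{1/5}$ *before* risk multiplication
(`adenoma_incidence_scale = "per_band"`; `"annual"` restores face value).

**CRC onset apportionment.** The stage-specific CRC incidence is treated as
a population rate among persons at risk (alive, cancer-free). Per-occupant
onset rates are derived so that 85% of incident cancers arise in
large-adenoma carriers at every age:
$r_L = f \cdot \mathrm{inc} / s_L(t)$ and
$r_O = (1-f)\cdot \mathrm{inc} / (1 - s_L(t))$, where $s_L(t)$ is the
large-adenoma share of at-risk occupancy under the no-screening law. Since
$s_L$ depends on the law, the rates are solved by a short deterministic
fixed-point iteration at parameter resolution (`derive_onset_rates`). This
preserves the published population incidence in the absence of screening
while letting polypectomy genuinely lower an individual's subsequent risk.

**Mortality attaches to diagnosis.** The stage-specific yearly CRC
mortality derives from survival measured *from diagnosis*, so by default it
applies only in treatment states; preclinical undiagnosed cancer progresses
and presents symptomatically (with certainty at Dukes' D) but carries no
excess mortality (`undiagnosed_crc_mortality = TRUE` restores the cruder
reading, under which usual-care CRC deaths triple and the published death
count is unreachable for any progression rate).

**Bounded treatment phase.** For the same reason — survival data observed
over a bounded follow-up — treated patients exit to cured at `cure_rate`
per year (a Markov transition back to `Normal`). Cured individuals carry no
further CRC mortality or treatment cost and never re-enter screening
(treated individuals take no further part in screening), but remain at risk
of a new primary. Without this phase, lifelong stage-A mortality of
0.034/year alone exceeds the entire published death count.

## Unpublished parameters and the single calibration

Two rates the model needs are not published: `stage_progression` (annual
probability of advancing one Dukes' stage, applied to undiagnosed and
treated disease alike) and `cure_rate`. They were calibrated jointly, once,
on a coarse grid against the four published usual-care/base-case anchors —
6,491 CRC cases and 983 CRC deaths per 10,000 persons, AU$3,441 mean
discounted lifetime cost, and 16.084 discounted life-years under five-yearly
colonoscopy — giving `stage_progression = 0.01` and `cure_rate = 0.35`. At
these defaults a 10,000-person seeded run lands within ±15% of all four
anchors, preserves the published orderings (incidence and mortality
colo5 < colo10 < ifobt2 < usual care; cost usual care < colo10 < colo5) and
keeps every frontier ICER below AU$50,000/LYG; this held on all ten seeds
checked. The defaults were not revisited afterwards.

The other-cause mortality schedule is a bundled *stand-in*: a deterministic
Gompertz law $q(a) = 0.0025\,e^{0.105 (a-50)}$ anchored to plausible
contemporary Australian values ($q$ from 0.0025 at 50 to ~0.17 at 90),
clearly flagged non-authoritative. Supplying the real national life table is
a one-line configuration change (`bundled_life_table("user_supplied", ...)`).

## Screening machinery

Screener status is a single lifetime draw at the uptake probability (40%
for both modalities by default): invited persons either always participate
or never do. iFOBT screeners accrue invitation+kit (AU$10) and pathology
(AU$20) costs; positives proceed to a GP-referred (AU$32.10) diagnostic
colonoscopy with 65% compliance, decliners return to the natural history. A
colonoscopy (AU$1,082; AU$1,606 with polypectomy) removes a detected small
adenoma (return to normal), removes a detected large adenoma (entry to the
five-yearly surveillance pathway, which supersedes primary screening), or
diagnoses cancer into the stage-specific treatment state. False negatives
return to the natural history; colonoscopy specificity is 1. Surveillance
recurs on a fixed five-year clock from entry while the person is alive and
undiagnosed.

## Engine, randomness and the oracle

`run_cohort()` is a vectorised annual-cycle engine. All randomness is
pre-drawn from the seed as fixed-layout per-individual uniform streams (one
stream per purpose: initial state, screener status, natural-history
transition, test result, follow-up, detection), so identical seeds give
bit-identical results and different strategies — and different sweep values
— consume identical randomness wherever their decision paths coincide
(common random numbers). This is why life-years gained are monotone in
participation and CRC cases are monotone in relative risk at modest cohort
sizes: higher uptake produces a nested superset of screeners under the same
draws. The sensitivity module deliberately shares one draw set across all
sweep cells rather than deriving per-value seeds, for exactly this coupling.

`run_individual()` is a readable per-individual twin built from the exported
operations, used in the test suite to cross-check the vectorised engine.
`cohort_matrix_oracle()` is the deterministic expected-value twin for the
no-screening configuration: it propagates occupancy vectors through the same
per-age transition matrices under the same accrual convention, and the test
suite requires microsimulation means to match it within three standard
errors at $n = 10^5$. Screening strategies are not expressible in this
14-state expected-value form (screening history breaks exchangeability
within a state), so the oracle refuses them explicitly.

## Economics

`icer_table()` sorts strategies by effectiveness, removes strongly
dominated options, iteratively removes extendedly dominated ones, and
reports incremental costs/effects and ICERs pairwise along the retained
frontier, where ICERs are strictly increasing by construction. ICERs use
discounted costs and discounted life-years (an undiscounted view is a flag).
Display rounding mimics the published tables (whole AU$, three-decimal
life-years, integer percentages); internal arithmetic is full precision.
`colonoscopies_per_life_saved()` floors its ratio, which reproduces the
published cells exactly. The AU$50,000/LYG threshold is a reporting
annotation, never a computation input. Monetary amounts are R doubles in
AU$: every bundled tariff is a multiple of 0.5 and all sums stay far below
the 2^53 exact-integer range, so integer-cent arithmetic would add
complexity without changing a digit.

## What the synthetic world does and does not establish

The fixtures module supplies closed-form toy models (pure life table,
geometric survival, illness-death, a 5-state mini-cancer model checked by
exhaustive path enumeration) and the matrix oracle. Green tests establish
that the engine simulates *this* stated world correctly and reproduces its
published anchors within the stated bands — not that the world itself is
epidemiologically true. In particular: the life table is a stand-in, not
AIHW data; polyp sojourn time is not modelled beyond annual transition
probabilities; adenomas never regress; screening participation is
persistent rather than per-round (the published 60% incidence reduction
under 40% uptake is arithmetically impossible under persistence if
non-screeners are unaffected, so the package's reductions are smaller —
about 15% for five-yearly colonoscopy — though every published *ordering*
is preserved); and the published colonoscopy volumes (up to 167,031 per
10,000 persons) are likewise not reachable under once-per-lifetime
assignment with five-yearly surveillance, so procedure counts are reported
but were not calibration targets. Colonoscopy complications, indirect
costs, family-history assessment costs and quality adjustment are out of
scope by design.

## Numerical notes

Transition rows sum to one to 1e-12 by construction and are verified
exhaustively over all states and ages. The fixed-point onset-rate solver
runs six iterations (occupancy shares move by <1e-6 after three) and clips
the large-adenoma share away from 0 and from the 85% origination fraction
to avoid degenerate apportionment. Initial-state and transition draws use
inverse-CDF lookup on cumulative rows, so zero-probability states are
unreachable regardless of ties. Degenerate inputs — absorbing sources in
`build_transition()`, screening calls on treated or dead individuals,
relative risks that push initial prevalences past 1 — raise immediate,
named errors rather than propagating silently; an unnormalisable value
inside a relative-risk sweep is recorded as an error row while the sweep
continues.
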