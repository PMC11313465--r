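---
title: "Methods: multiple-baseline analysis of movement behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-baseline analysis of movement behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsced)
```

This vignette is the package's own account of the statistical methods it
implements, the modelling choices that were genuinely open, and what the
test suite does and does not demonstrate.

## The design and its logic

A randomized multiple-baseline design measures each participant's daily
movement behavior through three phases: baseline (A), intervention (B) and
post-intervention (A′). The moment the intervention starts is randomized:
each participant draws one of a set of candidate baseline durations (here
4, 6, 8, 10, 12 or 14 days). Staggering the starts is what makes the design
interpretable at small *n*: a secular time trend or a co-occurring external
event would affect all participants at the same calendar time, whereas a
genuine intervention effect tracks each participant's own randomized start.

`design_spec()` records the design; `allocate_baselines()` performs the
draw. Two allocation modes exist because the literature is ambiguous about
which was used historically:

* `"independent"` — each participant uniform over the candidate set. This
  matches the usual wording of allocation by concealed randomization.
* `"balanced"` — a random permutation of the candidate set itself, which
  guarantees distinct start points and is the configuration under which the
  classical staggered-start permutation test attains its textbook power.

The default is `"independent"`; the simulation studies in the test suite
use `"balanced"` with six participants because that is the design whose
assignment space (6! = 720) gives the test its granularity guarantee.

### Measurement schedule

Published reports of this design rarely state exactly which days were
measured during a 15-week intervention. The package therefore takes the
schedule as configuration, with a default chosen to be realistic for
monitor-based studies: baseline days measured daily, 7-day measurement
blocks in intervention weeks 1, 8 and 15, and a 7-day post-intervention
block. With candidate baselines of at most 14 days and the week-1 block
always measured, every participant's series can be split at every candidate
start — the condition the randomization test needs.

## The randomization test

For participant $i$ with measured series $y_{i1}, y_{i2}, \dots$ indexed by
calendar day and a hypothetical start after day $d$, the participant effect
is

$$\hat\delta_i(d) = \bar y_i^{\,\text{post}}(d) - \bar y_i^{\,\text{pre}}(d),$$

the mean over valid days after day $d$ minus the mean over valid days up to
day $d$. The group statistic under an assignment
$\pi = (d_1, \dots, d_n)$ is the unweighted mean
$T(\pi) = \tfrac1n \sum_i \hat\delta_i(d_i)$. The reference distribution
re-evaluates $T$ under every admissible reassignment of the *realized*
durations across participants (the within-set scheme: all distinct
permutations of the realized multiset). The two-tailed p-value is

$$p = \frac{\#\{\pi : |T(\pi)| \ge |T_{\text{obs}}|\}}{\#\text{assignments}},$$

with the observed assignment always in the numerator, so $p \ge
1/\#\text{assignments} > 0$ and the test is exact by construction. The
"post" period pools B and A′ days by default (phase summaries in this
field conventionally report B+A′ jointly); a B-only analysis is available
through the `post_phases` arguments.

Choices worth stating:

* **Statistic.** The mean difference is the statistic of the classical
  staggered-start construction. Because the test is two-tailed on $|T|$,
  the sign convention (raw differences; improvement is negative for
  sedentary hours, positive for fragmentation) has no effect on p.
* **Exact vs Monte Carlo.** Exact enumeration is auto-selected up to
  $10^6$ assignments; beyond that, assignments are sampled with
  replacement and $p = (1 + k)/(1 + n_{mc})$ with the observed assignment
  included once, preserving validity.
* **Whole-cohort vs stratified.** The overall test permutes all
  participants jointly (default); a `strata` argument permutes within
  groups instead, for designs randomized per group. Subgroup analyses
  simply run the test on the subgroup's own durations.
* **Dropouts.** Following intention to treat, a dropout contributes every
  valid day they have. Under the block schedule, a participant who stops
  early may be unsplittable at the *largest* hypothetical starts (no
  measured day beyond day 14); those participant–assignment cells are
  treated as missing and the group statistic averages over the remaining
  participants, with a logged message. The realized assignment must be
  splittable for everyone — that is checked, and violating it is an error
  at test time rather than something silently patched.
* **Degenerate spaces.** A single-assignment space (all durations equal)
  yields p = 1 with a warning.
* **Numerical comparison.** "At least as extreme" uses a relative
  tolerance of $10^{-9}$ so that ties produced by identical floating-point
  arithmetic count as ties.

## Daily metrics

A **sedentary bout** is a maximal run of consecutive sedentary events:
adjacent sedentary events that abut in time merge; any upright event or
in-window gap terminates the bout. No merging tolerance is applied across
brief interruptions, because posture-monitor event streams are already
smoothed by the device firmware — a recorded 30-second stand-up is a
genuine break in sitting.

The **fragmentation index** is defined as bout count per sedentary hour.
The quantity is often named without being written down as a formula; this
definition is the one consistent with its standard gloss — a 1.1-point rise
at 10 h of daily sitting corresponds to about 10–11 additional
interruptions — and is stated prominently here because alternative
fragmentation metrics exist in the accelerometry literature.

The **prolonged-bout fraction** uses a strict "> 30 min" rule: a bout of
exactly 30:00 does not count, one of 30:01 does.

**MVPA from event data.** Class-based monitors distinguish sitting,
standing and stepping but not intensity, so moderate-to-vigorous activity
is proxied by stepping cadence ≥ 100 steps/min (configurable); slower
stepping and standing are light activity. 100 steps/min is the standard
ambulatory moderate-intensity proxy in adults.

**Valid days.** There is no universally agreed wear-time floor for a valid
day; the default is 10 waking hours of wear, configurable. Invalid days
keep their calendar position but are excluded from every analysis set.

**Eligibility screen.** Weekly MVPA is computed as the sum over valid days
rescaled to 7 days; when all 7 days are valid this is exactly the raw
weekly sum, so the single rule covers both natural readings of "150 min
during the week".

## PEM and visual analysis

PEM is the share of valid B∪A′ days *strictly* better than the baseline
median. Ties go against improvement: "exceeding" is read literally, and
with discrete or rounded data this choice changes the value, so it is
documented and deliberate. Medians over an even number of baseline days use
the midpoint convention. A consequence worth knowing: PEM is invariant
under strictly monotone transforms of the outcome only when the baseline
count is odd (the midpoint median of an even count does not commute with
nonlinear maps).

Category boundaries are ambiguous in the conventional interval notation
(">90 high, 70–90 moderate, 60–70 mild, 50–60 questionable, <50 none"); the
package assigns boundary values to the higher-named bin — exactly 90 and
exactly 70 are moderate, exactly 60 is mild, exactly 50 is questionable —
and exposes the boundaries as an argument for the opposite convention.

Phase summaries use the sample SD (n − 1), and the reported difference is
improvement-signed (positive = improved) so that tables read uniformly
across lower-is-better and higher-is-better outcomes. Report tables round
to one decimal, halves away from zero, matching how such tables are
conventionally printed.

The 2-SD band is the baseline mean ± 2 sample SDs; post days beyond the
band on the improvement side are counted with strict inequality (a day
exactly on the edge is inside). Level, trend and overlap are emitted as
numbers (phase means, OLS slope on day index, share of days inside the
band) — automated prose judgments of single-case graphs are out of scope.

## The synthetic generator

`synthetic_config()` defines the generative model; its defaults are the
study conditions the analysis is built for, chosen once:

| Parameter | Default | Why |
|---|---|---|
| baseline sedentary mean / between-SD | 11.4 / 1.1 h | the screened highly sedentary stroke population |
| within-person day SD | 1.2 h | mid-range of observed within-phase SDs (≈ 0.6–2.3 h) |
| fragmentation mean / between-SD / within-SD | 4.0 / 1.4 / 0.9 breaks/h | observed baseline range ≈ 2.3–7.2 breaks/h |
| waking window | 15.5 h | typical diary-derived waking day |
| intervention effects | −1.3 h sitting, +1.1 breaks/h, +18 MVPA min | the effect sizes the design is powered to detect |
| effect onset | step | matches the two-phase test statistic; a linear `ramp` option reflects gradual behavior change |
| bout lengths | lognormal, sdlog = 1 | long right tail produces the > 30-min bouts characteristic of this population |
| dropout | one NPS participant after week 5 | exercises intention-to-treat handling |

Day-level values are Gaussian around person-level means, truncated to
feasibility (a day cannot be more sedentary than its waking window).
`generate_day()` converts day targets into an event stream that tiles the
waking window exactly: lognormal bout draws rescaled so total sedentary
time matches the target to the second, upright gaps split into standing,
slow stepping and brisk stepping so the MVPA allotment is realized, and the
bout count set to `round(FI × sedentary hours)` (capped so every gap keeps
at least ~30 s).

What the generator does **not** emulate: autocorrelated day-to-day
dynamics, weekday/weekend structure, seasonal trends, posture
misclassification, partial non-wear, or behavioral feedback between
outcomes. Passing simulation checks therefore demonstrates correctness of
the *analysis machinery* under the stated statistical structure, not
robustness of the design to every feature of real accelerometry.

## Problem sizes in the test suite

The simulation-based checks use problem sizes chosen to give tight Monte
Carlo error while remaining quick on a laptop: 2000 null cohorts at the
six-participant/six-duration design for the type-I error check (binomial
SE ≈ 0.005 around 0.05), 200 seeds of the full 14-participant design for
effect recovery and power (Monte Carlo tests with 999 resamples), and
1000 randomized small fixtures for the brute-force oracle comparisons of
PEM and bout metrics.

## Known limitations

* The per-participant effect ignores within-phase trends; a participant
  improving steadily through baseline biases the step-change estimate.
  The phase-descriptor slopes surface this, but the test statistic does
  not model it.
* The fallback wake-window heuristic (longest overnight sedentary event
  treated as sleep) is deliberately crude; diaries are authoritative
  whenever present and every fallback day is logged.
* Exact enumeration materializes the assignment matrix; spaces beyond
  $10^6$ assignments switch to Monte Carlo rather than streaming
  enumeration.
* PEM is undefined without at least one valid day on each side of the
  start; the band requires two baseline days. Both error loudly rather
  than guessing.
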