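---
title: "Methods: person-specific coupling of media use and mental health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: person-specific coupling of media use and mental health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idioscreen)
```

## The analysis in one paragraph

`idioscreen` models one person at a time. Fortnightly occasions are the
sampling unit: each survey time *t* defines a half-open 14-day window
(*t* − 14 d, *t*] over which six media-use metrics are aggregated from the
raw screenshot-metadata stream, and the survey completed at *t* supplies
five mental-health scores. Canonical correlation analysis between the two
occasion blocks finds the linear composites — one of media use, one of
mental health — whose fortnight-to-fortnight fluctuations are maximally
correlated. Because the weights are estimated per person, the same pair of
constructs ("media use", "mental health") may be composed differently for
different people; that person-specific rotation is the point of the
p-technique approach. Significance of the leading canonical correlation is
assessed against a permutation null rather than any parametric reference
distribution, because at *n* = 20–27 occasions with 6 + 5 variables the
leading canonical correlation is far from its asymptotic behaviour.

## Sessionization and the six metrics

A *session* is a continuous screen-on interval. With explicit
`screen_on`/`screen_off` events the sessions are the on→off intervals that
contain at least one screenshot; malformed streams (orphan screenshots,
nested ons, dangling offs) are repaired with implicit opens/closes and the
repair count is reported as a warning rather than silently absorbed.
Streams without on/off events fall back to gap-based runs: consecutive
screenshots at most `gap_threshold` apart belong to one session. The
default `gap_threshold` of 30 s equals six missed captures at the 5-second
cadence — long enough to bridge capture hiccups, short enough not to fuse
genuinely separate pickups. Both the cadence and the threshold are
configuration, since other logging apps sample differently.

Per local calendar day (timezone configurable, default UTC, since the data
format carries UTC instants and the study timezone is a property of the
dataset, not the method):

* **screen time** — screenshots per active day; with one capture per 5 s
  of screen-on time the count is also exposed in hours/day
  (count × 5 / 3600, exact by construction);
* **social screen time** — screenshots whose foreground app maps to the
  `"social"` category in the user-supplied app→category table. Unmapped
  apps count as non-social: the conservative direction for a
  social-media-specific metric;
* **number of sessions** and **session duration** — sessions are counted
  per active day, and duration is the mean screen-on seconds per session
  over the whole fortnight (not a per-day mean of daily means, which would
  weight days unequally);
* **number of unique apps** — distinct apps across the fortnight divided
  by active days;
* **number of app switches** — consecutive screenshot pairs with differing
  apps. By default only within-session pairs count; whether a transition
  *across* a screen-off/screen-on boundary is a "switch" is genuinely
  ambiguous, so both policies are implemented
  (`count_app_switches(..., cross_session = TRUE)`) with within-session as
  the default, which never counts a pickup as fragmentation.

Three conventions had to be fixed where any choice is defensible: a
session (and its screenshots) belongs to the day containing its **start**;
fortnight windows are half-open (*t* − 14 d, *t*] on calendar dates, so a
survey day's own usage is included; and a day is *active* iff it has at
least one screenshot. Occasions whose window has no active day are flagged
missing and dropped listwise together with occasions missing any survey
scale — the missing-at-random assumption of the design.

## Survey scoring

Four instruments per fortnight. CES-D-10 (items 0–3, total 0–30 after
reverse-coding positively worded items; the package's default reverse key
is items 5 and 8, the published short-form key), STAI state (items 1–4,
total 20–80, default reverse key the ten anxiety-absent items), ASRS
(18 items, 0–4; two 9-item subscales, inattention = items 1–4 and 7–11,
hyperactivity = the rest, so the 6-item screener comprises four
inattention and two hyperactivity items), and a 0–100 positive-affect
slider. Risk flags: depression strictly > 16, anxiety strictly > 40, ADHD
screener sum of the first six items ≥ 9 — implemented exactly as stated,
thresholds overridable via configuration. Note the ADHD rule is a plain
sum, not the screener's original per-item shading rule; the plain sum is
what this pipeline commits to, and it is the scanned-threshold property
the acceptance checks verify. A missing item invalidates its scale for
that occasion — no prorating — because prorated totals would blur the
clinical-threshold semantics.

## The pCCA solution

Both blocks are column-standardized (mean 0, sample variance 1,
denominator *n* − 1) before anything else: the blocks mix hours, counts
and scale scores, and loadings/weights are only interpretable on a common
scale (the canonical correlations themselves are scale-invariant). With
*S~xx~*, *S~yy~*, *S~xy~* the within/cross covariance matrices, the SVD of
*K* = *S~xx~^−1/2^ S~xy~ S~yy~^−1/2^* gives the canonical correlations as
singular values; weights are back-transformed singular vectors, rescaled
so every variate has unit sample variance. Numerical choices:

* **Symmetric inverse square roots** via eigendecomposition with a
  relative tolerance of `max(dim) * eps * largest eigenvalue`; a block
  that is rank deficient at that tolerance triggers an error advising a
  ridge, and a condition number above 1e8 triggers an advisory message.
  The `ridge` argument (default 0) adds `ridge * I` to both within-block
  covariances — useful at *n* barely above the variable count, and the
  unit-variance rescaling of the variates is applied *after* the ridge so
  the reported variates are exactly standardized either way.
* **Sign convention.** CCA weights are sign-arbitrary per pair. The
  package flips each weight pair so the mental-health structure loading of
  largest magnitude is positive, making repeated fits byte-identical and
  reports comparable across runs.
* **Loadings are structure correlations** (observed standardized variable
  vs own-block first variate), bounded by ±1, not raw weights — raw
  weights are unbounded and unstable under near-collinearity, structure
  loadings are what a reader can interpret like correlations.
* **Guards.** Fitting refuses *n* ≤ max(*p*, *q*) + 1, constant columns
  are refused by name, and Wilks' Λ is always Π(1 − ρ~k~²) over all
  min(*p*, *q*) pairs.

Only the first canonical pair is interpreted by default (one coupling
strength per person); all pairs are computed and returned.

## Permutation null and the exact P value

`permute_null()` refits the CCA on `B` datasets (default 1000) in which
one block is shuffled across occasions, and the empirical P is the
add-one rule (1 + #{ρ~null~ ≥ ρ~obs~}) / (1 + B), so P ∈ [1/(B+1), 1] and
ties count against the observed value. The default scheme shuffles
**within columns** of the mental-health block independently. That choice
destroys not only the cross-block alignment but also the shuffled block's
internal correlation structure, which makes the null slightly liberal; the
conservative alternative — `row_shuffle`, reordering whole rows jointly —
is provided and differs only in that respect. Each iteration draws its
permutation from a seed derived deterministically from the top-level seed,
so results are independent of execution order.

The calibration test generates 200 independent-Gaussian datasets
(*n* = 27, 6 × 5 variables, B = 200) and requires the rejection rate at
α = 0.05 to land in [0.02, 0.10], the binomial 95% band around the nominal
level — evidence that the liberal/conservative distinction is immaterial
at this block structure.

## The synthetic generator and what passing tests mean

The generator is a single-factor model per block: occasion *t* draws a
latent pair (*f~t~*, *g~t~*) with correlation ρ~fg~, and each observed
variable is `loading * latent + Gaussian noise`, occasions independent.
Its value is that the population first canonical correlation is known in
closed form,

ρ₁ = |ρ~fg~| · √(c~x~/(1+c~x~)) · √(c~y~/(1+c~y~)), c = Σ λ²/σ²,

so recovery can be tested against an analytic target rather than against
the implementation itself. `spec_with_target_rho()` inverts this map.
Defaults: 27 occasions (a year of fortnights), unit loadings, unit noise,
ρ~fg~ = 0.9. The recovery simulations use noise SD 0.8 per column, which
places the attenuation ceiling at ≈0.90 and lets a population ρ₁ of 0.85 —
the strength of coupling this method is designed to detect — be planted
exactly.

Natural-scale rendering maps each column affinely onto realistic daily
magnitudes (≈3 h screen time at 5-s cadence, ≈58 sessions, ≈210 switches
per day, mid-range survey scores) and clips at the variables' attainable
bounds. Clipping is counted and reported because, unlike the affine map,
it perturbs the planted canonical structure. Event-level rendering goes
further: a `person_plan` fixes sessions, durations and per-screenshot app
labels, and `render_event_stream()` emits the raw stream, so
`metrics(render(plan))` must equal the plan **exactly** — an end-to-end
test of the parsing and aggregation path with no tolerance at all.
Survey-item generation likewise round-trips planted totals exactly
through the scorers, reverse-keying included.

What the generator deliberately does *not* emulate: circadian and weekday
structure, autocorrelated occasions (an AR structure would break the
closed-form oracle; occasions are exchangeable by design), app-popularity
distributions, or any specific real participant. Passing tests therefore
demonstrate correctness of the computational pipeline and calibration
under exchangeable noise — not that real screenome data satisfy the factor
model.

## Simulation sizes and pre-registered bands

The validation suite fixes its problem sizes at: 100 random small
instances (*n* ≤ 12, *p*, *q* ≤ 3) for the brute-force oracle comparison
(multi-start BFGS maximization of the variate correlation, agreement
within 1e−6); 200 null datasets for calibration; 500 replicates at
*n* = 27 for recovery of the planted ρ₁ = 0.85, compared against a
large-sample reference fit at *n* = 10⁵; a 20-replicate power spot check
at B = 1000; and 200 randomized plans for the metric round-trip. The
recovery band was fixed in advance of measurement as [ρ~ref~ − 0.02,
ρ~ref~ + 0.10]: the leading sample canonical correlation is positively
biased at these dimensions (order *pq*/*n*, here ≈ 0.05–0.08 at
ρ = 0.85), never materially *below* the population value, hence the
asymmetric band.

## Known limitations

* Listwise deletion discards an entire occasion for a single missing
  survey item; with very sparse data this can push *n* below the refusal
  threshold (12 complete occasions, one more than the 11 variables).
* The within-column permutation null is mildly liberal (see above); for
  borderline P values run `row_shuffle` as sensitivity.
* Metrics treat "no screenshots" as "no use": logger malfunction and true
  non-use are indistinguishable in metadata and are handled identically.
* Canonical weights at *n* ≈ 20–27 with 6 + 5 variables are estimated
  with substantial variance; interpret structure loadings, not weights,
  and treat pair-two-and-beyond correlations as descriptive only.
* The pipeline is strictly per-person by design; it offers no pooled or
  multilevel estimates and no cross-person inference.
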