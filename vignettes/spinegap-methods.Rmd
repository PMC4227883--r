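---
title: "Models and methods behind spinegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinegap)
```

spinegap quantifies the structural dynamics of dendritic spines and axonal
boutons followed across repeated two-photon imaging sessions, and
simulates/analyzes a closed-loop whisker-dependent gap-crossing task. This
vignette describes the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The two-population kinetic model

Chronically imaged spine populations behave as a mixture of a stable
("persistent") pool and a rapidly cycling ("transient") pool. The cohort
simulator draws each day-0 structure from this mixture with probability
`persistent_fraction` of being persistent, and lets every structure
present at session $t$ survive to session $t+1$ as an independent
Bernoulli trial with a type-specific per-interval survival $s_p$ or
$s_t$. Lost structures never reappear, so the expected survival of the
day-0 cohort at offset $k$ intervals has the closed form

$$S(k) = f_p\, s_p^{\,k} + (1 - f_p)\, s_t^{\,k}.$$

This closed form is the oracle for the pipeline's survival estimates:
generate a cohort with known $(f_p, s_p, s_t)$, run
`survival_fraction()`, and the pooled fraction must match $S(k)$ within
binomial error.

New structures are born between sessions with count
$\mathrm{Binomial}(N_t, \texttt{gain\_rate})$, where $N_t$ is the number
of structures currently present. A binomial rather than Poisson birth law
keeps gains bounded by the cohort size, matching the "percent gained"
metric whose denominator is the existing population. Newborns receive
their own type (transient with probability `new_type_mix`) and a
type-specific *first-interval* survival, after which they follow the
standard type survival. This separation matters: in real cohorts newly
formed spines are far more fragile over their first interval than the
population average.

Defaults encode a 4-day imaging cadence over four sessions (days 0, 4,
8, 12). The transient pool's default per-interval survival is
$e^{-4/8} \approx 0.607$, i.e. an 8-day survival time constant, the
canonical value for transient spines in adult cortex; the persistent
pool defaults to 0.99 per interval, gains to 0.15 per structure per
interval, and newborn mixtures to 80% transient with first-interval
survivals of 0.25 (transient) and 0.75 (persistent). All are
overridable, and the calibration tests set them explicitly.

### What the generator does not emulate

The generator produces presence histories, not images: there is no
dendrite geometry, spine density per length, optical point-spread
blurring, registration error, or session-to-session imaging quality
drift. Passing tests therefore demonstrate that the *metrics* are
computed correctly for data with the assumed statistical structure, not
that any upstream image segmentation is accurate. Correlated loss (e.g.
a retracting branch taking its spines with it) is also not modeled;
structures are independent given their type.

## Bouton scoring: two thresholds with hysteresis

Boutons are scored from a brightness ratio (bouton intensity over the
surrounding axon backbone). The field's criterion is asymmetric: a
bouton is *new* when it is at least 3.0 times brighter than the axon,
and *lost* when it falls below 1.3 times. The criterion says nothing
about ratios between 1.3 and 3.0; the only reading that uses both
numbers is a state-preserving hysteresis — a present bouton stays
present until it drops below 1.3, an absent position stays absent until
it reaches 3.0. `classify_bouton_series()` implements exactly this, with
both thresholds configurable. At the very first session no previous
state exists; we use the appearance threshold (presence requires 3.0),
because detection at the first session is what labels a bouton at all. A
first-session ratio inside the band therefore scores absent — a choice,
documented here, since the criterion leaves the case open.

The bouton simulator draws ratios as
`median_ratio * exp(rnorm(1, 0, ratio_noise_sd))` — multiplicative
lognormal noise, because fluorescence ratios are positive and
right-skewed. With the default medians (4.0 present, 0.8 absent) and
noise sd 0.2, state flips through the *wrong* threshold are vanishingly
rare ($>5\sigma$), so classification errors come almost entirely from
first-session band cases; the classifier's accuracy against the hidden
true labels exceeds 95% in the tests.

## Presence matrices, censoring, and no-resurrection

All metrics run on a structures-by-sessions matrix of present/absent/
censored calls. Two scorers annotate independently; agreeing cells pass
through, disagreements take a third scorer's call when available and are
otherwise censored (`reconcile_annotations()` logs every discrepancy).
Censored cells drop out of both the numerator and denominator of any
interval or offset they touch.

A present-after-absent pattern is not allowed: survival-fraction
semantics require that "present at offset k" mean *continuously*
present, and field convention treats a reappearing structure as a new
one. `build_presence_matrix()` enforces this with a `split` policy by
default (each contiguous run of presence becomes its own structure, the
later runs with fresh ids and birth dates) and a `strict` policy that
rejects offenders by name. Split is the default because the bouton
classifier can legitimately produce disappear-reappear call patterns
from noisy ratios, and those are, by the scoring rule, new boutons.

## Turnover and the choice of denominator

For each consecutive session pair the pipeline counts gains and losses
and reports

$$\mathrm{turnover} = \frac{n_\mathrm{gained} + n_\mathrm{lost}}
{n_\mathrm{prev} + n_\mathrm{curr}},$$

the "flanking" denominator standard in the chronic-imaging literature
(equal to the mean of the gain and loss fractions when counts are
stable). A `baseline` variant, $(g+l)/(2\,n_\mathrm{prev})$, is
available, and the choice is recorded in the output's metadata and the
run report. The conservation identity
$n_\mathrm{curr} = n_\mathrm{prev} - n_\mathrm{lost} + n_\mathrm{gained}$
is asserted on every synthetic cohort in the tests.

The unit of statistical analysis is the animal, not the spine: spines
within an animal are pooled (structure-weighted) into the per-animal
counts, per-animal values are averaged across intervals, and group
comparisons are run on per-animal values only. This avoids
pseudoreplication — group sizes are the numbers of mice. Group averages
weight animals equally by default; a spine-weighted average can be
formed from the emitted counts if wanted.

## Rank-sum comparisons

With 4–5 animals per genotype, normality cannot be verified, so groups
are compared with the two-sided Mann-Whitney U test. For
$n_1 + n_2 \le 12$, `mann_whitney()` enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled observed values, which
handles ties exactly by construction; larger samples use the normal
approximation with midranks, tie-corrected variance and continuity
correction. The exact branch reproduces `stats::wilcox.test`'s exact p
values on untied data (the tests assert this), while extending exactness
to tied data. One numerical caveat: at $n_1 = n_2 = 6$ the normal
approximation's absolute error is below 0.01 throughout the
decision-relevant range ($p \lesssim 0.25$) but can reach $\approx$
0.03 near $p = 0.5$ — a property of the approximation itself (shared by
every implementation), immaterial to any accept/reject decision.

### Sensitivity

A power harness in the acceptance tests generates a 5-animal control
group at the default kinetics and a 4-animal group with gain and loss
rates both elevated 25%, and checks that the per-animal rank-sum
comparison detects the difference at $p < .05$ in the majority of
replicates. With ~300 structures per animal over three intervals, the
sampling noise of a per-animal turnover estimate is far smaller than a
25% shift, so detection is limited mainly by the minimum attainable
two-sided exact p at $n = 5$ vs 4 ($2/126 \approx 0.016$).

## The gap-cross controller

The behavioral assay is simulated as the real apparatus runs: a
two-state machine alternating *Exploration* (the animal attempts a
crossing; motion sensors at the back and edge of each platform record
its progress) and *Adjustment* (doors close, the clock advances by the
repositioning dead time, the next distance is chosen). A trial is a
*success* if the target-back sensor fires, a *failure* if an edge sensor
is followed by a return to the home-back sensor, and *incomplete*
otherwise — segmentation is total over event streams, and the recorded
outcome is always recomputed from the stream. Sessions start at 3.0 cm
and end at 20 successes or 20 simulated minutes, whichever comes first;
a trial cut off by the clock is kept as incomplete and excluded from
success-rate denominators.

The staircase draws the next distance from a Gaussian centered 0.5 cm
beyond the previous distance after a success and 0.5 cm short of it
after a failure, clamps to the 3.0–6.0 cm range and quantizes to the
0.5 cm grid on which all reported distances fall (round half up). The
Gaussian spread is not specified by the assay description; the default
`sigma_cm = 0.25` keeps most proposals within one grid step of the
center while preserving the unpredictability that motivates the
Gaussian over a deterministic ladder. Whether the physical platform
quantized its positions is unknown; we quantize because every reported
distance is a multiple of 0.5 cm, and the raw proposals remain
available (`quantize = FALSE`).

Simulated agents cross with probability
$\sigma\!\left((m_s - d)/\beta\right)$, a logistic psychometric curve
with per-session midpoint $m_s$ and slope $\beta$; a rising midpoint
schedule models learning. Distances below 5.0 cm are labeled *nose*
distances (reachable by nose contact) and 5.0 cm and above *whisker*
distances, the boundary implied by which distances are whisker-only in
the assay. Improvement between session blocks (default sessions 1–4 vs
5–8) is reported in percentage points; a relative-change variant is
available, since "percent improvement" is ambiguous between the two.
Trial durations are drawn from a gamma distribution with mean
`attempt_time_s` and a fixed coefficient of variation — the assay
description gives no timing model, and the gamma keeps durations
positive with a deterministic option (`attempt_time_cv = 0`).

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 1,600–2,000
spines, 600 boutons, and single-agent session batches — sizes chosen to
put binomial standard errors near one percentage point, comfortably
below the tolerances asserted, while keeping any single check under a
minute. Every simulator accepts a seed; seeded runs are byte-for-byte
reproducible and restore the caller's RNG state. Parameter sidecar JSON
files written next to every output table record parameters, seed and
package version, so any run can be reconstructed exactly.

## Known limitations

* Structures are independent; no spatial clustering of gains/losses.
* The bouton simulator models brightness as a two-level process plus
  noise; real boutons show graded intensity trajectories.
* The depth-profile tool (`normalize_depth_profile()`) averages raw
  samples into 100 equal-width bins and normalizes to a designated
  white-matter bin; it assumes the input trace is already ordered from
  pia to white matter and spans the cortex.
* The gap-cross simulation covers the controller and statistics, not
  hardware (actuators, door servos) or video tracking.
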