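# spinegap

Quantitative tools for two linked problems in the study of cortical
structural plasticity and tactile learning in the mouse:

1. **Longitudinal synaptic structure dynamics.** Dendritic spines and
   axonal boutons followed through a cranial window across repeated
   two-photon imaging sessions (typically every 4 days for 12 days) are
   scored present/absent per session; from these presence histories the
   package computes per-interval turnover, gained/lost fractions,
   survival curves of the baseline cohort, and fate classes of newly
   formed structures, aggregates them per animal, and compares groups
   with the Mann-Whitney test.
2. **The gap-cross assay.** A whisker-dependent task in which a mouse
   crosses a gap between two platforms in the dark, run by a closed-loop
   controller: a two-state (Exploration/Adjustment) session machine,
   motion-sensor trial segmentation, and an adaptive Gaussian staircase
   that samples the next gap distance around `previous ± 0.5 cm`
   depending on the last outcome. The package simulates the whole loop
   and computes success-rate-by-distance and early/late learning tables.

A seeded synthetic-data generator underpins both halves, so every stage
is testable without raw imaging or behavioral data.

## The core models

**Spines/boutons** follow a two-population kinetic model. Each day-0
structure is *persistent* with probability `f_p` or *transient* with
probability `1 − f_p`, and survives each imaging interval independently
with type-specific probability `s_p` or `s_t`; lost structures never
reappear, so the day-0 cohort's expected survival at offset `k`
intervals is

    S(k) = f_p · s_p^k + (1 − f_p) · s_t^k

New structures arise per interval as `Binomial(N_present, gain_rate)`.
Per-interval turnover is `(gained + lost) / (n_prev + n_curr)`.

**Boutons** are scored from brightness ratios with a two-threshold
hysteresis rule: present when ≥ 3.0× the surrounding axon, lost when
< 1.3×, state-preserving in between.

**Gap-cross agents** cross a `d` cm gap with probability
`plogis((midpoint_session − d) / slope)`; sessions run to 20 successes
or 20 minutes.

## Worked example

Simulate a wild-type-like cohort and a group with 25%-elevated kinetics,
then run the full analysis:

```r
library(spinegap)

wt <- simulate_spine_cohort(spine_kinetics_params(n_animals = 5, seed = 42))
wt
#> <presence_matrix> 2184 structures x 4 sessions (days 0, 4, 8, 12)
#>   animals: 5   kinds: spine   censored cells: 0

ko <- simulate_spine_cohort(spine_kinetics_params(
  n_animals = 4, gain_rate = 0.19, transient_interval_survival = 0.51,
  seed = 43))
ko$structures$animal_id <- sub("^a", "k", ko$structures$animal_id)

res <- run_dynamics(
  rbind(as.data.frame(wt), as.data.frame(ko)),
  groups = setNames(rep(c("wt", "ko"), c(5, 4)),
                    c(paste0("a", 1:5), paste0("k", 1:4))))
res$comparisons[1:4, c("metric", "mean_a", "mean_b", "u", "p_value")]
#>           metric    mean_a    mean_b  u    p_value
#> 1 turnover_ratio 0.1902072 0.1518555  0 0.01587302
#> 2    frac_gained 0.1884912 0.1500634  0 0.01587302
#> 3      frac_lost 0.1911887 0.1528413  0 0.01587302
#> 4       survival 0.7041667 0.7493333 20 0.01587302
```

Per-animal mean turnover of the control group sits near 0.15 per 4-day
interval with ~72–75% of day-0 spines surviving to day 12; the elevated
group separates completely in per-animal ranks, giving the minimal exact
two-sided p for 5-vs-4 animals, 2/126 ≈ 0.016.

A learning agent on the gap-cross task (psychometric midpoint rising
from 4.8 to 5.4 cm over 8 sessions):

```r
trials <- simulate_gap_agent(agent_params(
  seq(4.8, 5.4, length.out = 8), attempt_time_s = 10, seed = 7))
success_rate_by_distance(trials)
#>   distance_cm category n_attempts n_success       rate
#> 1         3.0     nose         10        10 1.00000000
#> 2         3.5     nose         11        10 0.90909091
#> 3         4.0     nose         23        22 0.95652174
#> 4         4.5     nose         67        52 0.77611940
#> 5         5.0  whisker         99        51 0.51515152
#> 6         5.5  whisker         67        14 0.20895522
#> 7         6.0  whisker         19         1 0.05263158

improvement(trials)$mean
#>   distance_cm category improvement
#> 1         3.0     nose    0.000000
#> 2         3.5     nose   16.666667
#> 3         4.0     nose    5.555556
#> 4         4.5     nose   16.571429
#> 5         5.0  whisker   27.306122
#> 6         5.5  whisker   16.388889
#> 7         6.0  whisker    6.250000
```

Success declines with distance across the whisker range, and the
early-to-late improvement (sessions 1–4 vs 5–8, percentage points) is
largest at the shortest whisker distance, 5.0 cm — the signature of
tactile learning in this task.

See `vignettes/spinegap-methods.Rmd` for the models, parameter defaults
and numerical choices in detail.

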