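# Parameter constructors with validation. Every simulator entry point takes
# one of these objects so that invalid settings fail before any random draw.

chk_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  as.numeric(x)
}

chk_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

chk_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  as.numeric(x)
}

#' Kinetic parameters for the two-population spine cohort simulator
#'
#' Dendritic spine populations followed by chronic imaging behave as a
#' mixture of a stable ("persistent") pool and a rapidly cycling
#' ("transient") pool. The simulator draws every day-0 structure from this
#' mixture and lets each one survive successive imaging intervals as an
#' independent Bernoulli trial with a type-specific per-interval survival
#' probability; once a structure is lost it never reappears. New structures
#' are born between sessions at a per-capita rate and receive their own
#' type and first-interval survival.
#'
#' The default transient per-interval survival is `exp(-interval/tau)` with
#' an 8-day survival time constant for the transient pool and a 4-day
#' imaging interval, i.e. `exp(-0.5) ~ 0.607`.
#'
#' @param n_animals Number of simulated animals.
#' @param n_initial_per_animal Structures present at the first session, per
#'   animal.
#' @param persistent_fraction Fraction of day-0 structures of persistent
#'   type.
#' @param persistent_interval_survival Per-interval survival probability of
#'   a persistent structure.
#' @param transient_interval_survival Per-interval survival probability of
#'   a transient structure.
#' @param gain_rate Expected new structures per existing structure per
#'   interval; births are `Binomial(n_present, gain_rate)` so gains never
#'   exceed the current cohort size.
#' @param new_type_mix Probability that a newborn structure is
#'   transient-type.
#' @param new_transient_first_survival,new_persistent_first_survival
#'   Survival probability of a newborn structure over its first interval,
#'   by type. Subsequent intervals use the type's standard survival.
#' @param n_sessions Number of imaging sessions (>= 2).
#' @param interval_days Days between consecutive sessions.
#' @param seed Optional integer seed; when supplied the simulator is
#'   deterministic and leaves the caller's RNG state untouched.
#' @return A `spine_kinetics_params` object (a validated list).
#' @seealso [simulate_spine_cohort()]
#' @export
spine_kinetics_params <- function(n_animals = 5L,
                                  n_initial_per_animal = 300L,
                                  persistent_fraction = 0.70,
                                  persistent_interval_survival = 0.99,
                                  transient_interval_survival = exp(-0.5),
                                  gain_rate = 0.15,
                                  new_type_mix = 0.80,
                                  new_transient_first_survival = 0.25,
                                  new_persistent_first_survival = 0.75,
                                  n_sessions = 4L,
                                  interval_days = 4,
                                  seed = NULL) {
  p <- list(
    n_animals = chk_count(n_animals, "n_animals", 1L),
    n_initial_per_animal = chk_count(n_initial_per_animal,
                                     "n_initial_per_animal", 0L),
    persistent_fraction = chk_prob(persistent_fraction,
                                   "persistent_fraction"),
    persistent_interval_survival = chk_prob(persistent_interval_survival,
                                            "persistent_interval_survival"),
    transient_interval_survival = chk_prob(transient_interval_survival,
                                           "transient_interval_survival"),
    gain_rate = chk_prob(gain_rate, "gain_rate"),
    new_type_mix = chk_prob(new_type_mix, "new_type_mix"),
    new_transient_first_survival = chk_prob(new_transient_first_survival,
                                            "new_transient_first_survival"),
    new_persistent_first_survival = chk_prob(new_persistent_first_survival,
                                             "new_persistent_first_survival"),
    n_sessions = chk_count(n_sessions, "n_sessions", 2L),
    interval_days = chk_pos(interval_days, "interval_days"),
    seed = if (!is.null(seed)) chk_count(seed, "seed", 0L)
  )
  structure(p, class = c("spine_kinetics_params", "kinetics_params"))
}

#' Kinetic parameters for the bouton cohort simulator
#'
#' Axonal boutons are simulated with the same two-population birth/death
#' process as spines, but the observable is a per-session brightness ratio
#' (bouton intensity over the surrounding axon backbone) rather than a
#' direct presence call. A truly present bouton has median ratio
#' `present_ratio_mean`, a truly absent one `absent_ratio_mean`, each
#' perturbed by multiplicative lognormal noise with log-sd `ratio_noise_sd`.
#' Fluorescence ratios are positive and right-skewed, hence the lognormal.
#'
#' `present_ratio_mean` must be at least 3.0 so that a present bouton can
#' satisfy the 3x appearance criterion used by the threshold classifier;
#' `absent_ratio_mean` must fall below the 1.3x retention threshold.
#'
#' @inheritParams spine_kinetics_params
#' @param present_ratio_mean Median brightness ratio of a present bouton
#'   (>= 3.0).
#' @param absent_ratio_mean Median brightness ratio at a position with no
#'   bouton (< 1.3).
#' @param ratio_noise_sd Log-scale standard deviation of the multiplicative
#'   noise on ratios; 0 gives noiseless ratios.
#' @return A `bouton_kinetics_params` object.
#' @seealso [simulate_bouton_series()], [classify_bouton_series()]
#' @export
bouton_kinetics_params <- function(n_animals = 4L,
                                   n_initial_per_animal = 110L,
                                   persistent_fraction = 0.85,
                                   persistent_interval_survival = 0.995,
                                   transient_interval_survival = 0.55,
                                   gain_rate = 0.06,
                                   new_type_mix = 0.80,
                                   new_transient_first_survival = 0.40,
                                   new_persistent_first_survival = 0.80,
                                   n_sessions = 4L,
                                   interval_days = 4,
                                   present_ratio_mean = 4.0,
                                   absent_ratio_mean = 0.8,
                                   ratio_noise_sd = 0.2,
                                   seed = NULL) {
  base <- spine_kinetics_params(
    n_animals = n_animals,
    n_initial_per_animal = n_initial_per_animal,
    persistent_fraction = persistent_fraction,
    persistent_interval_survival = persistent_interval_survival,
    transient_interval_survival = transient_interval_survival,
    gain_rate = gain_rate,
    new_type_mix = new_type_mix,
    new_transient_first_survival = new_transient_first_survival,
    new_persistent_first_survival = new_persistent_first_survival,
    n_sessions = n_sessions,
    interval_days = interval_days,
    seed = seed)
  pr <- chk_pos(present_ratio_mean, "present_ratio_mean")
  ab <- chk_pos(absent_ratio_mean, "absent_ratio_mean")
  if (pr < 3.0)
    stop("`present_ratio_mean` must be >= 3.0: a present bouton below the ",
         "3x appearance threshold could never be scored as new",
         call. = FALSE)
  if (ab >= 1.3)
    stop("`absent_ratio_mean` must be < 1.3 (the retention threshold)",
         call. = FALSE)
  p <- c(unclass(base),
         list(present_ratio_mean = pr,
              absent_ratio_mean = ab,
              ratio_noise_sd = chk_pos(ratio_noise_sd, "ratio_noise_sd",
                                       strict = FALSE)))
  structure(p, class = c("bouton_kinetics_params", "kinetics_params"))
}

#' Psychometric parameters of a simulated gap-cross agent
#'
#' A simulated mouse crosses a gap of width `d` cm with probability
#' `plogis((midpoint - d) / slope)`: `midpoint_cm_by_session` is the
#' distance of 50% crossing probability for each session (a rising midpoint
#' across sessions models tactile learning), `slope_cm` the psychometric
#' steepness. `slope_cm = 0` gives a step-function agent that always
#' crosses at distances up to the midpoint and never beyond.
#'
#' @param midpoint_cm_by_session Numeric vector, one 50%-crossing distance
#'   (cm) per session.
#' @param slope_cm Psychometric slope in cm (>= 0).
#' @param attempt_time_s Mean duration of one trial, seconds; sets how many
#'   trials fit in a capped session.
#' @param attempt_time_cv Coefficient of variation of trial durations;
#'   0 makes every trial last exactly `attempt_time_s`.
#' @param seed Optional integer seed used by [simulate_gap_agent()].
#' @return An `agent_params` object.
#' @export
agent_params <- function(midpoint_cm_by_session,
                         slope_cm = 0.3,
                         attempt_time_s = 30,
                         attempt_time_cv = 0.2,
                         seed = NULL) {
  if (!is.numeric(midpoint_cm_by_session) ||
      length(midpoint_cm_by_session) < 1L ||
      anyNA(midpoint_cm_by_session))
    stop("`midpoint_cm_by_session` must be a non-empty numeric vector",
         call. = FALSE)
  structure(list(
    midpoint_cm_by_session = as.numeric(midpoint_cm_by_session),
    slope_cm = chk_pos(slope_cm, "slope_cm", strict = FALSE),
    attempt_time_s = chk_pos(attempt_time_s, "attempt_time_s"),
    attempt_time_cv = chk_pos(attempt_time_cv, "attempt_time_cv",
                              strict = FALSE),
    seed = if (!is.null(seed)) chk_count(seed, "seed", 0L)),
    class = "agent_params")
}

#' Adaptive staircase sampler settings
#'
#' After a successful trial the next gap distance is drawn from a Gaussian
#' centered one `step_cm` beyond the previous distance; after a failure,
#' one `step_cm` short of it. Draws are clamped to `bounds_cm` and
#' quantized to the `grid_cm` grid (round half up), matching a platform
#' that moves in fixed increments.
#'
#' @param step_cm Center shift per trial outcome, cm.
#' @param sigma_cm Standard deviation of the Gaussian proposal, cm.
#' @param bounds_cm Length-2 numeric, min and max testable distance, cm.
#' @param grid_cm Quantization grid, cm; must divide the bounds span.
#' @param start_cm First distance of every session, cm.
#' @return A `sampler_params` object.
#' @export
sampler_params <- function(step_cm = 0.5,
                           sigma_cm = 0.25,
                           bounds_cm = c(3.0, 6.0),
                           grid_cm = 0.5,
                           start_cm = 3.0) {
  step_cm <- chk_pos(step_cm, "step_cm")
  sigma_cm <- chk_pos(sigma_cm, "sigma_cm", strict = FALSE)
  if (!is.numeric(bounds_cm) || length(bounds_cm) != 2L ||
      bounds_cm[1] >= bounds_cm[2])
    stop("`bounds_cm` must be an ordered pair (min < max)", call. = FALSE)
  grid_cm <- chk_pos(grid_cm, "grid_cm")
  span <- diff(bounds_cm)
  if (abs(span / grid_cm - round(span / grid_cm)) > 1e-9)
    stop("`grid_cm` must divide the span of `bounds_cm`", call. = FALSE)
  start_cm <- chk_pos(start_cm, "start_cm")
  if (start_cm < bounds_cm[1] || start_cm > bounds_cm[2])
    stop("`start_cm` must lie within `bounds_cm`", call. = FALSE)
  structure(list(step_cm = step_cm, sigma_cm = sigma_cm,
                 bounds_cm = as.numeric(bounds_cm), grid_cm = grid_cm,
                 start_cm = start_cm),
            class = "sampler_params")
}

#' Session termination rules for the gap-cross controller
#'
#' A session ends at `max_successes` successful crossings or when the
#' simulated clock exceeds `max_duration_s`, whichever comes first
#' (20 successes / 20 minutes by default). `adjustment_time_s` is the dead
#' time between trials while the doors are closed and the platforms
#' reposition.
#'
#' @param max_successes Successful crossings that end a session.
#' @param max_duration_s Session time cap, seconds.
#' @param adjustment_time_s Platform repositioning dead time per trial,
#'   seconds.
#' @return A `session_config` object.
#' @export
session_config <- function(max_successes = 20L,
                           max_duration_s = 1200,
                           adjustment_time_s = 10) {
  structure(list(
    max_successes = chk_count(max_successes, "max_successes", 1L),
    max_duration_s = chk_pos(max_duration_s, "max_duration_s"),
    adjustment_time_s = chk_pos(adjustment_time_s, "adjustment_time_s",
                                strict = FALSE)),
    class = "session_config")
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
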