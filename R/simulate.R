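# Synthetic cohorts with known kinetics. The generator is the test bed for
# every downstream metric: because the persistent/transient mixture has a
# closed-form survival curve, the pipeline's estimates can be checked
# against the parameters that produced the data.

# Shared birth/death engine. Returns presence calls, per-structure
# metadata, and hidden type labels for one whole cohort.
sim_two_population <- function(params) {
  S <- params$n_sessions
  days <- (seq_len(S) - 1L) * params$interval_days
  surv_of <- c(persistent = params$persistent_interval_survival,
               transient = params$transient_interval_survival)
  first_of <- c(persistent = params$new_persistent_first_survival,
                transient = params$new_transient_first_survival)

  calls <- list(); meta <- list()
  for (a in seq_len(params$n_animals)) {
    n0 <- params$n_initial_per_animal
    type <- ifelse(stats::runif(n0) < params$persistent_fraction,
                   "persistent", "transient")
    pres <- matrix(0L, n0, S)
    if (n0 > 0L) pres[, 1L] <- 1L
    born <- rep(1L, n0)
    for (s in seq_len(S - 1L)) {
      alive <- which(pres[, s] == 1L)
      if (length(alive)) {
        p <- ifelse(born[alive] > 1L & born[alive] == s,
                    first_of[type[alive]], surv_of[type[alive]])
        pres[alive, s + 1L] <- stats::rbinom(length(alive), 1L, p)
      }
      n_new <- if (length(alive))
        stats::rbinom(1L, length(alive), params$gain_rate) else 0L
      if (n_new > 0L) {
        type <- c(type, ifelse(stats::runif(n_new) < params$new_type_mix,
                               "transient", "persistent"))
        add <- matrix(0L, n_new, S)
        add[, s + 1L] <- 1L
        pres <- rbind(pres, add)
        born <- c(born, rep(s + 1L, n_new))
      }
    }
    n <- nrow(pres)
    if (n > 0L) {
      aid <- sprintf("a%d", a)
      meta[[a]] <- data.frame(
        structure_id = sprintf("%s_f1_s%04d", aid, seq_len(n)),
        animal_id = aid, field_id = "f1", kind = "structure",
        birth_day = days[born], type = type,
        stringsAsFactors = FALSE)
      calls[[a]] <- pres
    }
  }
  if (length(calls) == 0L || sum(vapply(calls, nrow, 1L)) == 0L) {
    meta <- data.frame(structure_id = character(), animal_id = character(),
                       field_id = character(), kind = character(),
                       birth_day = numeric(), type = character())
    return(list(calls = matrix(0L, 0L, S), days = days, meta = meta))
  }
  list(calls = do.call(rbind, calls), days = days,
       meta = do.call(rbind, meta))
}

#' Simulate a longitudinal spine cohort with two-population kinetics
#'
#' Generates presence histories for dendritic spines followed over
#' `n_sessions` imaging sessions spaced `interval_days` apart, under the
#' persistent/transient mixture model of [spine_kinetics_params()]. The
#' empirical survival of the day-0 cohort converges (as the cohort grows)
#' to the closed form
#' `f_p * s_p^k + (1 - f_p) * s_t^k` at offset `k` intervals, where `f_p`
#' is the persistent fraction and `s_p`, `s_t` the per-interval survival
#' probabilities. Lost structures never reappear.
#'
#' The per-structure type labels are ground truth for validation; they are
#' attached as the `"truth"` attribute (a data frame of `structure_id`,
#' `type`, `birth_day`) rather than placed in the analysis-facing matrix.
#'
#' @param params A [spine_kinetics_params()] object.
#' @return A `presence_matrix` with hidden `"truth"` attribute.
#' @examples
#' pm <- simulate_spine_cohort(spine_kinetics_params(
#'   n_animals = 2, n_initial_per_animal = 50, seed = 1))
#' survival_fraction(pm)
#' @export
simulate_spine_cohort <- function(params) {
  stopifnot(inherits(params, "kinetics_params"))
  sim <- with_seed_if(params$seed, sim_two_population(params))
  meta <- sim$meta
  meta$kind <- rep("spine", nrow(meta))
  truth <- meta[c("structure_id", "type", "birth_day")]
  rownames(truth) <- NULL
  pm <- new_presence_matrix(sim$calls, sim$days,
                            meta[setdiff(names(meta), "type")])
  attr(pm, "truth") <- truth
  pm
}

#' Simulate bouton brightness-ratio series
#'
#' Underlying bouton presence follows the same two-population birth/death
#' process as spines; the observable is the per-session brightness ratio of
#' the bouton relative to the surrounding axon. A present bouton's ratio is
#' `present_ratio_mean`, an absent position's `absent_ratio_mean`, each
#' multiplied by lognormal noise `exp(rnorm(1, 0, ratio_noise_sd))`. With
#' zero noise the threshold classifier ([classify_bouton_series()])
#' recovers the true presence exactly.
#'
#' @param params A [bouton_kinetics_params()] object.
#' @return A data frame (class `bouton_series`) with one row per bouton x
#'   session: `animal_id`, `field_id`, `structure_id`, `session_day`,
#'   `ratio`. The `"truth"` attribute carries the true presence matrix and
#'   type labels for classifier validation.
#' @examples
#' bs <- simulate_bouton_series(bouton_kinetics_params(
#'   n_animals = 1, n_initial_per_animal = 20, seed = 1))
#' head(bs)
#' @export
simulate_bouton_series <- function(params) {
  stopifnot(inherits(params, "bouton_kinetics_params"))
  out <- with_seed_if(params$seed, {
    sim <- sim_two_population(params)
    n <- nrow(sim$calls); s <- length(sim$days)
    noise <- if (params$ratio_noise_sd > 0 && n > 0L)
      exp(stats::rnorm(n * s, 0, params$ratio_noise_sd)) else 1
    list(sim = sim, noise = noise)
  })
  sim <- out$sim
  sim$meta$kind <- rep("bouton", nrow(sim$meta))
  n <- nrow(sim$calls); s <- length(sim$days)
  base <- ifelse(sim$calls == 1L, params$present_ratio_mean,
                 params$absent_ratio_mean)
  ratio <- as.numeric(base) * out$noise
  df <- data.frame(
    animal_id = rep(sim$meta$animal_id, times = s),
    field_id = rep(sim$meta$field_id, times = s),
    structure_id = rep(sim$meta$structure_id, times = s),
    session_day = rep(sim$days, each = max(n, 0L)),
    ratio = ratio,
    stringsAsFactors = FALSE)
  if (n == 0L)
    df <- df[0, ]
  class(df) <- c("bouton_series", "data.frame")
  truth_pm <- new_presence_matrix(
    sim$calls, sim$days, sim$meta[setdiff(names(sim$meta), "type")])
  attr(df, "truth") <- list(
    presence = truth_pm,
    types = sim$meta[c("structure_id", "type", "birth_day")])
  df
}

#' Simulate a gap-cross agent over multiple sessions
#'
#' Runs the closed-loop session controller ([run_session()]) for
#' `n_sessions` sessions with an agent whose crossing probability at gap
#' distance `d` in session `s` is
#' `plogis((midpoint_cm_by_session[s] - d) / slope_cm)`. Each trial emits a
#' synthetic motion-sensor event stream: a crossing produces
#' `home_back -> home_edge -> target_edge -> target_back`, a failure
#' `home_back -> home_edge -> home_back`.
#'
#' @param agent An [agent_params()] object.
#' @param session_cfg A [session_config()].
#' @param sampler A [sampler_params()].
#' @param n_sessions Number of sessions; defaults to the length of the
#'   agent's midpoint schedule (midpoints recycle if shorter).
#' @param animal_id Label stored in the trial table.
#' @return A `gap_trials` data frame: one row per trial with `animal_id`,
#'   `session`, `trial`, `distance_cm`, `outcome`, `t_start`, `t_end` and
#'   an `events` list-column of per-trial sensor event data frames.
#' @examples
#' trials <- simulate_gap_agent(agent_params(
#'   midpoint_cm_by_session = c(4.8, 5.0, 5.2), seed = 1))
#' success_rate_by_distance(trials)
#' @export
simulate_gap_agent <- function(agent,
                               session_cfg = session_config(),
                               sampler = sampler_params(),
                               n_sessions = length(agent$midpoint_cm_by_session),
                               animal_id = "m1") {
  stopifnot(inherits(agent, "agent_params"),
            inherits(session_cfg, "session_config"),
            inherits(sampler, "sampler_params"))
  n_sessions <- chk_count(n_sessions, "n_sessions", 1L)
  with_seed_if(agent$seed, {
    out <- lapply(seq_len(n_sessions), function(s) {
      tr <- run_session(agent, session_cfg, sampler, session = s)
      tr$animal_id <- animal_id
      tr
    })
    trials <- do.call(rbind, out)
    class(trials) <- c("gap_trials", "data.frame")
    trials
  })
}
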