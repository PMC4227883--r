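# The closed-loop gap-cross assay: adaptive Gaussian staircase, sensor
# event segmentation, and the two-state (Exploration/Adjustment) session
# controller, plus the summary statistics computed from trial logs.

SENSORS <- c("home_back", "home_edge", "target_edge", "target_back")

#' Draw the next gap distance of the adaptive staircase
#'
#' Proposes the next distance from a Gaussian centered `step_cm` beyond the
#' previous distance after a success, or `step_cm` short of it after a
#' failure, then clamps to the sampler bounds and quantizes to the distance
#' grid (round half up). Set `clamp = FALSE, quantize = FALSE` to inspect
#' the raw proposals.
#'
#' @param prev_cm Previous trial distance, cm.
#' @param outcome `"success"` or `"failure"`.
#' @param sampler A [sampler_params()] object.
#' @param n Number of draws (vectorized; default 1).
#' @param clamp,quantize Apply bound clamping / grid quantization.
#' @return Numeric vector of length `n` of proposed distances (cm).
#' @examples
#' s <- sampler_params(sigma_cm = 0)
#' next_distance(4.0, "success", s)   # exactly 4.5
#' next_distance(3.0, "failure", s)   # clamped at 3.0
#' @export
next_distance <- function(prev_cm, outcome, sampler = sampler_params(),
                          n = 1L, clamp = TRUE, quantize = TRUE) {
  stopifnot(inherits(sampler, "sampler_params"))
  outcome <- match.arg(outcome, c("success", "failure"))
  dir <- if (outcome == "success") 1 else -1
  x <- stats::rnorm(n, prev_cm + dir * sampler$step_cm, sampler$sigma_cm)
  if (clamp)
    x <- pmin(pmax(x, sampler$bounds_cm[1]), sampler$bounds_cm[2])
  if (quantize)
    x <- floor(x / sampler$grid_cm + 0.5) * sampler$grid_cm
  x
}

#' Classify a trial from its sensor event stream
#'
#' A trial is `"success"` when the mouse reaches the sensor at the back of
#' the target platform; `"failure"` when it approaches the gap (edge
#' sensor of either platform, without reaching the target back) and then
#' retreats to the back of the home platform; anything else -- including an
#' empty stream -- is `"incomplete"`.
#'
#' @param events A data frame with columns `sensor` (one of `home_back`,
#'   `home_edge`, `target_edge`, `target_back`) and optionally `time`
#'   (seconds, non-decreasing), or a character vector of sensor names.
#' @return `"success"`, `"failure"` or `"incomplete"`.
#' @examples
#' segment_trial(c("home_back", "home_edge", "target_edge", "target_back"))
#' segment_trial(c("home_back", "home_edge", "home_back"))
#' @export
segment_trial <- function(events) {
  s <- if (is.data.frame(events)) as.character(events$sensor)
       else as.character(events)
  if (length(s) == 0L) return("incomplete")
  bad <- setdiff(unique(s), SENSORS)
  if (length(bad))
    stop("unknown sensor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.data.frame(events) && !is.null(events$time) &&
      is.unsorted(events$time))
    stop("event times must be non-decreasing within a trial",
         call. = FALSE)
  if ("target_back" %in% s) return("success")
  edge <- which(s %in% c("home_edge", "target_edge"))[1]
  if (!is.na(edge) && edge < length(s) &&
      any(s[(edge + 1L):length(s)] == "home_back")) return("failure")
  "incomplete"
}

# Event stream for one simulated trial. Crossing reaches target_back;
# retreat returns to home_back. Times interpolate the trial duration.
make_event_stream <- function(crossed, t0, duration) {
  if (crossed)
    data.frame(sensor = SENSORS,
               time = t0 + duration * c(0, 0.4, 0.7, 1))
  else
    data.frame(sensor = c("home_back", "home_edge", "home_back"),
               time = t0 + duration * c(0, 0.5, 1))
}

agent_cross_prob <- function(agent, distance_cm, session) {
  mids <- agent$midpoint_cm_by_session
  mid <- mids[((session - 1L) %% length(mids)) + 1L]
  if (agent$slope_cm == 0) as.numeric(distance_cm <= mid)
  else stats::plogis((mid - distance_cm) / agent$slope_cm)
}

draw_attempt_time <- function(agent) {
  if (agent$attempt_time_cv == 0) return(agent$attempt_time_s)
  cv <- agent$attempt_time_cv
  shape <- 1 / cv^2
  stats::rgamma(1L, shape = shape, rate = shape / agent$attempt_time_s)
}

#' Run one closed-loop gap-cross session
#'
#' Alternates the controller's two states: Exploration (the agent attempts
#' a crossing at the current distance and the sensor stream is segmented
#' into an outcome) and Adjustment (the doors close, the clock advances by
#' the repositioning dead time, and the staircase draws the next
#' distance). The first trial of every session is at the sampler's start
#' distance. The session terminates after `max_successes` successful
#' crossings or once the simulated clock exceeds `max_duration_s`; a trial
#' cut off by the time cap is recorded as `"incomplete"` with its truncated
#' event stream.
#'
#' @param agent An [agent_params()] object.
#' @param session_cfg A [session_config()].
#' @param sampler A [sampler_params()].
#' @param session Session index (selects the agent's midpoint).
#' @return A `gap_trials` data frame (see [simulate_gap_agent()]).
#' @export
run_session <- function(agent, session_cfg = session_config(),
                        sampler = sampler_params(), session = 1L) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(session_cfg, "session_config"),
            inherits(sampler, "sampler_params"))
  clock <- 0; n_succ <- 0L; d <- sampler$start_cm
  rows <- list(); streams <- list()
  repeat {
    if (n_succ >= session_cfg$max_successes ||
        clock >= session_cfg$max_duration_s) break
    duration <- draw_attempt_time(agent)
    crossed <- stats::runif(1L) < agent_cross_prob(agent, d, session)
    events <- make_event_stream(crossed, clock, duration)
    t_end <- clock + duration
    if (t_end > session_cfg$max_duration_s) {
      events <- events[events$time <= session_cfg$max_duration_s, ,
                       drop = FALSE]
      t_end <- session_cfg$max_duration_s
    }
    outcome <- segment_trial(events)
    i <- length(rows) + 1L
    rows[[i]] <- data.frame(session = session, trial = i, distance_cm = d,
                            outcome = outcome, t_start = clock,
                            t_end = t_end)
    streams[[i]] <- events
    if (outcome == "success") n_succ <- n_succ + 1L
    clock <- t_end + session_cfg$adjustment_time_s
    if (outcome %in% c("success", "failure"))
      d <- next_distance(d, outcome, sampler)
  }
  trials <- if (length(rows)) do.call(rbind, rows)
            else data.frame(session = integer(), trial = integer(),
                            distance_cm = numeric(), outcome = character(),
                            t_start = numeric(), t_end = numeric())
  trials$events <- streams
  class(trials) <- c("gap_trials", "data.frame")
  trials
}

#' Success rate per gap distance
#'
#' Counts attempts and successes at each quantized gap distance and labels
#' each distance as a `"nose"` distance (< 5.0 cm, detectable by nose
#' contact) or a `"whisker"` distance (>= 5.0 cm, whiskers only).
#' Incomplete trials (cut off by the session time cap) are excluded from
#' the denominators.
#'
#' @param trials A `gap_trials` data frame.
#' @param whisker_min_cm Boundary between nose and whisker distances.
#' @return Data frame with `distance_cm`, `category`, `n_attempts`,
#'   `n_success`, `rate`.
#' @export
success_rate_by_distance <- function(trials, whisker_min_cm = 5.0) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  t2 <- trials[trials$outcome %in% c("success", "failure"), , drop = FALSE]
  d <- sort(unique(t2$distance_cm))
  out <- do.call(rbind, lapply(d, function(x) {
    sub <- t2[t2$distance_cm == x, ]
    data.frame(distance_cm = x,
               category = if (x < whisker_min_cm) "nose" else "whisker",
               n_attempts = nrow(sub),
               n_success = sum(sub$outcome == "success"))
  }))
  out$rate <- out$n_success / out$n_attempts
  out
}

#' Early-versus-late improvement in crossing success
#'
#' Compares the probability of a successful crossing between an early block
#' of sessions and a late block, per gap distance and per animal, then
#' averages across animals. The default split contrasts sessions 1-4 with
#' sessions 5-8. Improvement is reported in percentage points
#' (`units = "points"`), or as relative change in percent of the early
#' rate (`units = "relative"`). Distances attempted in only one of the two
#' windows are excluded and listed in the `"excluded"` attribute.
#'
#' @param trials A `gap_trials` data frame (multiple animals allowed via an
#'   `animal_id` column).
#' @param early_sessions,late_sessions Session indices of the two windows.
#' @param units `"points"` or `"relative"`.
#' @param whisker_min_cm Nose/whisker boundary passed through to the
#'   per-distance categories.
#' @return A list with `per_animal` (animal x distance rows with early and
#'   late rates and `improvement`) and `mean` (per-distance mean
#'   improvement across animals).
#' @export
improvement <- function(trials, early_sessions = 1:4, late_sessions = 5:8,
                        units = c("points", "relative"),
                        whisker_min_cm = 5.0) {
  units <- match.arg(units)
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  if (is.null(trials$animal_id)) trials$animal_id <- "m1"
  early <- trials[trials$session %in% early_sessions, , drop = FALSE]
  late <- trials[trials$session %in% late_sessions, , drop = FALSE]
  if (nrow(early) == 0L || nrow(late) == 0L)
    stop("both session windows must contain trials", call. = FALSE)

  rate_tab <- function(tr) {
    tr <- tr[tr$outcome %in% c("success", "failure"), , drop = FALSE]
    if (nrow(tr) == 0L)
      return(data.frame(animal_id = character(), distance_cm = numeric(),
                        rate = numeric()))
    agg <- stats::aggregate(outcome ~ animal_id + distance_cm, data = tr,
                            FUN = function(o) mean(o == "success"))
    names(agg)[3] <- "rate"
    agg
  }
  e <- rate_tab(early); l <- rate_tab(late)
  m <- merge(e, l, by = c("animal_id", "distance_cm"),
             suffixes = c("_early", "_late"), all = TRUE)
  excl <- m[is.na(m$rate_early) | is.na(m$rate_late), , drop = FALSE]
  m <- m[!is.na(m$rate_early) & !is.na(m$rate_late), , drop = FALSE]
  m$improvement <- if (units == "points")
    100 * (m$rate_late - m$rate_early)
  else
    100 * (m$rate_late - m$rate_early) / m$rate_early
  m$category <- ifelse(m$distance_cm < whisker_min_cm, "nose", "whisker")
  m <- m[order(m$animal_id, m$distance_cm), ]
  rownames(m) <- NULL
  mn <- stats::aggregate(improvement ~ distance_cm + category, data = m,
                         FUN = mean)
  mn <- mn[order(mn$distance_cm), ]
  rownames(mn) <- NULL
  out <- list(per_animal = m, mean = mn)
  attr(out, "excluded") <- excl[c("animal_id", "distance_cm")]
  attr(out, "units") <- units
  out
}
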