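# Staircase sampler, sensor-event segmentation, the session controller,
# and the session-level summary statistics.

test_that("degenerate Gaussian staircase moves by exactly one step", {
  s <- sampler_params(sigma_cm = 0)
  expect_equal(next_distance(4.0, "success", s), 4.5)
  expect_equal(next_distance(4.0, "failure", s), 3.5)
  # clamped at the bounds
  expect_equal(next_distance(3.0, "failure", s), 3.0)
  expect_equal(next_distance(6.0, "success", s), 6.0)
})

test_that("proposals are centered one step beyond the previous distance", {
  set.seed(41)
  raw <- next_distance(4.0, "success", sampler_params(), n = 20000,
                       clamp = FALSE, quantize = FALSE)
  expect_lt(abs(mean(raw - 4.0) - 0.5), 0.006)  # ~3 SEs at sigma 0.25
  expect_lt(abs(sd(raw) - 0.25), 0.01)
})

test_that("iterated staircase stays in bounds and on grid", {
  set.seed(42)
  s <- sampler_params()
  d <- s$start_cm
  for (i in 1:100000) {
    d <- next_distance(d, if (runif(1) < 0.5) "success" else "failure", s)
    if (d < 3 || d > 6 || abs(d / 0.5 - round(d / 0.5)) > 1e-9)
      stop("off grid or out of bounds at step ", i, ": ", d)
  }
  succeed()
})

test_that("quantization rounds half up on the grid", {
  set.seed(43)
  s <- sampler_params(sigma_cm = 0, step_cm = 0.25, grid_cm = 0.5)
  # 4.0 + 0.25 -> 4.25, half-way: rounds up to 4.5
  expect_equal(next_distance(4.0, "success", s), 4.5)
  # 4.0 - 0.25 -> 3.75: rounds up to 4.0
  expect_equal(next_distance(4.0, "failure", s), 4.0)
})

test_that("sensor streams segment into the three outcomes", {
  expect_equal(segment_trial(c("home_back", "home_edge", "target_edge",
                               "target_back")), "success")
  expect_equal(segment_trial(c("home_back", "home_edge", "home_back")),
               "failure")
  # retreat after reaching the target edge but not the target back
  expect_equal(segment_trial(c("home_back", "home_edge", "target_edge",
                               "home_back")), "failure")
  expect_equal(segment_trial(c("home_back")), "incomplete")
  expect_equal(segment_trial(character(0)), "incomplete")
  expect_error(segment_trial(c("home_back", "nose_poke")), "unknown")
  expect_error(segment_trial(data.frame(sensor = c("home_back",
                                                   "home_edge"),
                                        time = c(2, 1))),
               "non-decreasing")
})

test_that("segmentation is total over generated event streams", {
  set.seed(44)
  trials <- simulate_gap_agent(agent_params(5.0, slope_cm = 0.5,
                                            attempt_time_s = 20,
                                            seed = 44),
                               n_sessions = 3)
  outs <- vapply(trials$events, segment_trial, character(1))
  expect_true(all(outs %in% c("success", "failure", "incomplete")))
  expect_equal(outs, trials$outcome)
})

test_that("always-succeed agent ends a session at exactly 20 successes", {
  agent <- agent_params(100, slope_cm = 0, attempt_time_s = 5, seed = 1)
  set.seed(45)
  tr <- run_session(agent, session_config(adjustment_time_s = 5))
  expect_equal(sum(tr$outcome == "success"), 20L)
  expect_equal(nrow(tr), 20L)
  expect_true(all(tr$distance_cm[1] == 3.0))
  expect_lt(max(tr$t_end), 1200)
})

test_that("never-cross agent runs out the 20-minute clock", {
  agent <- agent_params(0, slope_cm = 0, attempt_time_s = 30,
                        attempt_time_cv = 0, seed = 2)
  set.seed(46)
  tr <- run_session(agent, session_config(adjustment_time_s = 10))
  expect_equal(sum(tr$outcome == "success"), 0L)
  # 30 s trials + 10 s adjustments: exactly 30 trials fill 1200 s
  expect_equal(nrow(tr), 30L)
  expect_lte(max(tr$t_end), 1200)
  # never moves off the start distance after failures at the lower bound
  expect_true(all(tr$distance_cm == 3.0))
})

test_that("controller respects caps with one in-flight trial at most", {
  set.seed(47)
  agent <- agent_params(4.5, slope_cm = 0.3, attempt_time_s = 40, seed = 3)
  cfg <- session_config(max_successes = 10, max_duration_s = 600)
  for (i in 1:5) {
    tr <- run_session(agent, cfg)
    expect_lte(sum(tr$outcome == "success"), 10L)
    expect_lte(max(tr$t_end), 600)
    expect_lte(sum(tr$outcome == "incomplete"), 1L)
  }
})

test_that("sessions are reproducible under the agent seed", {
  agent <- agent_params(c(4.5, 5.0), seed = 48)
  a <- simulate_gap_agent(agent)
  b <- simulate_gap_agent(agent)
  expect_identical(a$distance_cm, b$distance_cm)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$events, b$events)
})

test_that("crossing probability at the midpoint is one half", {
  set.seed(49)
  agent <- agent_params(4.5, slope_cm = 0.3, seed = NULL)
  p <- replicate(4000, runif(1) < spinegap:::agent_cross_prob(agent, 4.5, 1))
  expect_lt(abs(mean(p) - 0.5), 0.03)
})

test_that("success rates per distance count correctly and label categories", {
  tr <- data.frame(
    session = 1, trial = 1:12,
    distance_cm = c(rep(5.0, 10), 4.5, 4.5),
    outcome = c(rep("success", 7), rep("failure", 3), "success",
                "incomplete"),
    stringsAsFactors = FALSE)
  out <- success_rate_by_distance(tr)
  expect_equal(out$rate[out$distance_cm == 5.0], 0.7)
  expect_equal(out$n_attempts[out$distance_cm == 4.5], 1L)  # incomplete excluded
  expect_equal(out$category[out$distance_cm == 4.5], "nose")
  expect_equal(out$category[out$distance_cm == 5.0], "whisker")
})

test_that("improvement arithmetic: identical performance is zero, 40->70 is +30", {
  tr <- expand.grid(session = 1:8, trial = 1:10)
  tr$distance_cm <- 5.0
  tr$outcome <- ifelse(tr$session <= 4,
                       ifelse(tr$trial <= 4, "success", "failure"),
                       ifelse(tr$trial <= 7, "success", "failure"))
  imp <- improvement(tr)
  expect_equal(imp$mean$improvement, 30)
  expect_equal(attr(imp, "units"), "points")
  # relative variant: (0.7 - 0.4) / 0.4 = 75%
  expect_equal(improvement(tr, units = "relative")$mean$improvement, 75)

  tr$outcome <- "success"
  expect_equal(improvement(tr)$mean$improvement, 0)
})

test_that("distances absent from one window are flagged and excluded", {
  tr <- data.frame(session = c(1, 1, 5, 5),
                   distance_cm = c(4.0, 4.5, 4.0, 5.0),
                   outcome = "success", stringsAsFactors = FALSE)
  imp <- improvement(tr)
  expect_equal(imp$mean$distance_cm, 4.0)
  excl <- attr(imp, "excluded")
  expect_setequal(excl$distance_cm, c(4.5, 5.0))
})

test_that("a learning agent improves most at the shortest whisker distance", {
  agent <- agent_params(seq(4.8, 5.4, length.out = 8), slope_cm = 0.3,
                        attempt_time_s = 5, seed = 50)
  cfg <- session_config(max_successes = 100, max_duration_s = 1200,
                        adjustment_time_s = 2)
  trials <- simulate_gap_agent(agent, cfg)
  imp <- improvement(trials)$mean
  whisk <- imp[imp$category == "whisker", ]
  expect_gt(nrow(whisk), 1)
  expect_equal(whisk$distance_cm[which.max(whisk$improvement)], 5.0)
  # static agent: improvement centered on zero
  static <- simulate_gap_agent(agent_params(rep(5.0, 8), slope_cm = 0.3,
                                            attempt_time_s = 5,
                                            seed = 51), cfg)
  imp0 <- improvement(static)$mean
  expect_lt(max(abs(imp0$improvement)), 15)
})
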