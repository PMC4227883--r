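# Interval dynamics, survival curves, fate classes, aggregation and the
# depth-profile normalization.

test_that("interval dynamics match hand enumeration", {
  # day0 {A,B,C,D} -> day4 {A,B,E}: 1 gained, 2 lost
  pm <- pm_from_patterns(list(A = c(1, 1), B = c(1, 1), C = c(1, 0),
                              D = c(1, 0), E = c(0, 1)), days = c(0, 4))
  d <- interval_dynamics(pm)
  expect_equal(d$n_prev, 4L)
  expect_equal(d$n_curr, 3L)
  expect_equal(d$n_gained, 1L)
  expect_equal(d$n_lost, 2L)
  expect_equal(d$turnover_ratio, 3 / 7)
  expect_equal(d$frac_gained, 0.25)
  expect_equal(d$frac_lost, 0.5)
  # baseline variant of the turnover denominator
  d2 <- interval_dynamics(pm, turnover_formula = "baseline")
  expect_equal(d2$turnover_ratio, 3 / 8)
  expect_equal(attr(d2, "turnover_formula"), "baseline")
})

test_that("a static matrix has zero turnover, gains and losses", {
  pm <- pm_from_patterns(list(s1 = c(1, 1, 1, 1), s2 = c(1, 1, 1, 1)))
  d <- interval_dynamics(pm)
  expect_true(all(d$turnover_ratio == 0))
  expect_true(all(d$n_gained == 0) && all(d$n_lost == 0))
})

test_that("conservation holds on every synthetic cohort interval", {
  for (seed in 1:4) {
    pm <- simulate_spine_cohort(spine_kinetics_params(
      n_animals = 3, n_initial_per_animal = 120, n_sessions = 5,
      seed = seed))
    d <- interval_dynamics(pm)
    expect_equal(d$n_prev - d$n_lost + d$n_gained, d$n_curr)
  }
})

test_that("fewer than two sessions is an error", {
  pm <- pm_from_patterns(list(s1 = 1), days = 0)
  expect_error(interval_dynamics(pm), "two imaging sessions")
  expect_error(survival_fraction(pm, baseline_day = 4),
               "not an imaging session")
})

test_that("survival curve matches hand enumeration and is monotone", {
  pm <- pm_from_patterns(list(s1 = c(1, 1, 1, 1), s2 = c(1, 1, 1, 0),
                              s3 = c(1, 1, 0, 0), s4 = c(1, 0, 0, 0)))
  sv <- survival_fraction(pm)
  pooled <- sv[sv$animal_id == "pooled", ]
  expect_equal(pooled$fraction, c(1, 0.75, 0.5, 0.25))
  expect_equal(pooled$offset_day, c(0, 4, 8, 12))
})

test_that("survival is computed per animal as well as pooled", {
  rec <- rbind(records_from_patterns(list(s1 = c(1, 1), s2 = c(1, 0)),
                                     days = c(0, 4), animal_id = "a1"),
               records_from_patterns(list(s3 = c(1, 1)),
                                     days = c(0, 4), animal_id = "a2"))
  sv <- survival_fraction(build_presence_matrix(rec))
  expect_equal(sv$fraction[sv$animal_id == "a1" & sv$offset_day == 4], 0.5)
  expect_equal(sv$fraction[sv$animal_id == "a2" & sv$offset_day == 4], 1)
  expect_equal(sv$fraction[sv$animal_id == "pooled" & sv$offset_day == 4],
               2 / 3)
})

test_that("newborn fate classes match hand enumeration", {
  pats <- c(
    lapply(1:6, function(i) c(0, 1, 0, 0)),        # transient
    list(c(0, 1, 1, 0)),                           # mid (4-8 day)
    lapply(1:3, function(i) c(0, 1, 1, 1)))        # persistent
  names(pats) <- sprintf("s%02d", seq_along(pats))
  ft <- classify_new_structure_fates(pm_from_patterns(pats))
  pooled <- ft[ft$animal_id == "pooled", ]
  expect_equal(pooled$n_cohort, 10)
  expect_equal(pooled$frac_transient, 0.6)
  expect_equal(pooled$frac_mid, 0.1)
  expect_equal(pooled$frac_persistent, 0.3)
  expect_equal(pooled$frac_transient + pooled$frac_mid +
                 pooled$frac_persistent, 1)
})

test_that("all newborns vanishing by the first horizon are transient", {
  ft <- classify_new_structure_fates(pm_from_patterns(
    list(s1 = c(0, 1, 0, 0), s2 = c(0, 1, 0, 0))))
  expect_equal(ft$frac_transient[ft$animal_id == "pooled"], 1)
  expect_error(
    classify_new_structure_fates(pm_from_patterns(
      list(s1 = c(0, 1, 0, 0))), horizon_days = c(8, 16)),
    "imaging sessions")
})

test_that("per-animal aggregation averages intervals and SEM matches the direct formula", {
  rec <- rbind(records_from_patterns(list(s1 = c(1, 1), s2 = c(1, 0)),
                                     days = c(0, 4), animal_id = "a1"),
               records_from_patterns(list(s3 = c(1, 1), s4 = c(1, 1)),
                                     days = c(0, 4), animal_id = "a2"))
  pm <- build_presence_matrix(rec)
  agg <- aggregate_by_animal(interval_dynamics(pm))
  expect_equal(agg$animal_id, c("a1", "a2"))
  expect_equal(agg$frac_lost, c(0.5, 0))

  vals <- c(10, 12, 14, 16, 18)
  gs <- group_summary(vals, rep("wt", 5))
  expect_equal(gs$mean, 14)
  expect_equal(gs$sem, sd(vals) / sqrt(5))
  expect_equal(gs$n, 5L)
})

test_that("single animal aggregation is the identity on its means", {
  pm <- simulate_spine_cohort(spine_kinetics_params(
    n_animals = 1, n_initial_per_animal = 80, seed = 5))
  ints <- interval_dynamics(pm)
  agg <- aggregate_by_animal(ints)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$turnover_ratio, mean(ints$turnover_ratio))
})

test_that("depth profile normalization: constant, ramp and sawtooth", {
  # constant profile -> all bins 1
  expect_true(all(normalize_depth_profile(rep(7, 300))$intensity == 1))
  # linear ramp with reference at the deepest bin ascends to exactly 1
  ramp <- normalize_depth_profile(seq(0, 10, length.out = 200))
  expect_equal(ramp$intensity[100], 1)
  expect_true(all(diff(ramp$intensity) > 0))
  # 200-sample sawtooth: brute-force pairwise means as the oracle
  saw <- rep(c(1, 3), 100) * seq(1, 2, length.out = 200)
  oracle <- vapply(seq_len(100),
                   function(b) mean(saw[(2 * b - 1):(2 * b)]), numeric(1))
  oracle <- oracle / oracle[100]
  expect_equal(normalize_depth_profile(saw)$intensity, oracle)
})

test_that("depth profile rejects short input and a zero reference", {
  expect_error(normalize_depth_profile(rep(1, 50)), "at least 100")
  expect_error(normalize_depth_profile(c(rep(1, 198), 0, 0),
                                       wm_bin_index = 100), "positive")
})
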