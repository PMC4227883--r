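# The synthetic cohort generators: deterministic limits, closed-form
# survival, parameter recovery, and structural invariants.

test_that("deterministic limit: immortal cohort is present everywhere", {
  pm <- simulate_spine_cohort(spine_kinetics_params(
    n_animals = 2, n_initial_per_animal = 40, persistent_fraction = 1,
    persistent_interval_survival = 1, gain_rate = 0, seed = 1))
  expect_equal(n_structures(pm), 80L)
  expect_true(all(pm$calls == 1L))
  sv <- survival_fraction(pm)
  expect_true(all(sv$fraction == 1))
})

test_that("day-12 survival matches the two-population closed form", {
  # f_p = 0.70 never lost, f_t = 0.30 at per-interval survival 0.425:
  # expected day-12 survival 0.70 + 0.30 * 0.425^3 = 0.7230
  pm <- simulate_spine_cohort(spine_kinetics_params(
    n_animals = 1, n_initial_per_animal = 1600,
    persistent_fraction = 0.70, persistent_interval_survival = 1.0,
    transient_interval_survival = 0.425, gain_rate = 0, seed = 11))
  sv <- survival_fraction(pm)
  got <- sv$fraction[sv$animal_id == "pooled" & sv$offset_day == 12]
  expected <- two_pop_survival(3, 0.70, 1.0, 0.425)
  se <- sqrt(expected * (1 - expected) / 1600)
  expect_lt(abs(got - expected), 4 * se)
})

test_that("no resurrection: every structure has one contiguous alive run", {
  for (seed in 1:3) {
    pm <- simulate_spine_cohort(spine_kinetics_params(
      n_animals = 2, n_initial_per_animal = 150, n_sessions = 5,
      seed = seed))
    runs <- apply(pm$calls, 1, function(x) {
      p <- which(x == 1L)
      length(p) > 0 && all(diff(p) == 1L)
    })
    expect_true(all(runs))
  }
})

test_that("identical params and seed give identical cohorts", {
  p <- spine_kinetics_params(n_animals = 2, n_initial_per_animal = 60,
                             seed = 99)
  a <- simulate_spine_cohort(p)
  b <- simulate_spine_cohort(p)
  expect_identical(a$calls, b$calls)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c <- simulate_spine_cohort(spine_kinetics_params(
    n_animals = 2, n_initial_per_animal = 60, seed = 100))
  expect_false(identical(a$calls, c$calls))
})

test_that("generator with a seed leaves the caller's RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_spine_cohort(spine_kinetics_params(
    n_animals = 1, n_initial_per_animal = 20, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("turnover recovers the generating gain/loss rates", {
  # Single-population kinetics: loss = 1 - s and gain = g per interval, so
  # E[n_curr]/E[n_prev] = s + g and the flanking turnover converges to
  # (g + (1 - s)) / (1 + s + g).
  s <- 0.85; g <- 0.15
  expected <- (g + (1 - s)) / (1 + s + g)
  est <- vapply(1:6, function(seed) {
    pm <- simulate_spine_cohort(spine_kinetics_params(
      n_animals = 1, n_initial_per_animal = 400,
      persistent_fraction = 0, transient_interval_survival = s,
      gain_rate = g, new_type_mix = 1,
      new_transient_first_survival = s, seed = seed))
    mean(interval_dynamics(pm)$turnover_ratio)
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - expected), max(2 * mc_se, 0.01))
})

test_that("noiseless bouton ratios are classified exactly as generated", {
  bs <- simulate_bouton_series(bouton_kinetics_params(
    n_animals = 2, n_initial_per_animal = 60, ratio_noise_sd = 0,
    present_ratio_mean = 4, absent_ratio_mean = 0.5, seed = 3))
  truth <- attr(bs, "truth")$presence
  got <- classify_bouton_table(bs)
  expect_identical(dim(got$calls), dim(truth$calls))
  expect_equal(unname(got$calls), unname(truth$calls))
})

test_that("moderate-noise bouton classification stays highly accurate", {
  bs <- simulate_bouton_series(bouton_kinetics_params(
    n_animals = 2, n_initial_per_animal = 100, ratio_noise_sd = 0.2,
    seed = 4))
  truth <- attr(bs, "truth")$presence
  got <- classify_bouton_table(bs)
  # Split-policy renames cannot change cell-level agreement on the
  # original grid, so score against the raw per-bouton classification.
  key <- paste(bs$structure_id, bs$session_day)
  bs_ord <- bs[order(bs$structure_id, bs$session_day), ]
  calls <- unlist(tapply(bs_ord$ratio, bs_ord$structure_id,
                         classify_bouton_series))
  truth_ord <- as.data.frame(truth)
  truth_ord <- truth_ord[order(truth_ord$structure_id,
                               truth_ord$session_day), ]
  acc <- mean(calls == truth_ord$present)
  expect_gt(acc, 0.95)
})

test_that("zero boutons requested gives an empty series without error", {
  bs <- simulate_bouton_series(bouton_kinetics_params(
    n_animals = 1, n_initial_per_animal = 0, gain_rate = 0, seed = 1))
  expect_s3_class(bs, "bouton_series")
  expect_equal(nrow(bs), 0L)
})

test_that("newborn structures appear at the right session with first-interval kinetics", {
  # gain_rate 1 makes births Binomial(n, 1) = n: exactly one newborn per
  # day-0 structure at day 4.
  pm <- simulate_spine_cohort(spine_kinetics_params(
    n_animals = 1, n_initial_per_animal = 500, persistent_fraction = 1,
    persistent_interval_survival = 1, gain_rate = 1, new_type_mix = 1,
    new_transient_first_survival = 0.3,
    transient_interval_survival = 0.9, n_sessions = 3, seed = 21))
  truth <- attr(pm, "truth")
  born4 <- truth$birth_day == 4
  expect_equal(sum(born4), 500L)
  # first-interval survival 0.3 governs day-4 -> day-8
  surv <- pm$calls[match(truth$structure_id[born4],
                         rownames(pm$calls)), 3]
  expect_lt(abs(mean(surv) - 0.3), 4 * sqrt(0.3 * 0.7 / 500))
})
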