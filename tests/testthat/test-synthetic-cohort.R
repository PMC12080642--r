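# trial-sequence generation -------------------------------------------------

count_ak_bigrams <- function(stim) {
  sum(stim[-length(stim)] == "A" & stim[-1] == "K")
}

test_that("generated sequences conserve target count and block balance", {
  spec <- task_spec()
  for (seed in c(1, 17, 3141)) {
    sq <- generate_trial_sequence(spec, seed = seed)
    expect_equal(nrow(sq), 480)
    expect_equal(sum(sq$is_target), 100)
    # exhaustive bigram scan: exactly 100 A->K pairs, intended or not
    expect_equal(count_ak_bigrams(sq$stimulus), 100)
    # 25 targets in each placement block of 120 trials
    expect_equal(as.integer(tapply(sq$is_target, sq$trial_index %/% 120, sum)),
                 rep(25L, 4))
    # every target K is preceded by its A
    expect_true(all(sq$stimulus[which(sq$is_target) - 1] == "A"))
  }
})

test_that("non-default geometries keep the same invariants", {
  spec <- task_spec(n_trials = 240, n_targets = 40,
                    n_placement_blocks = 2)
  sq <- generate_trial_sequence(spec, seed = 5)
  expect_equal(sum(sq$is_target), 40)
  expect_equal(count_ak_bigrams(sq$stimulus), 40)
  expect_equal(as.integer(tapply(sq$is_target, sq$trial_index %/% 120, sum)),
               rep(20, 2))
})

test_that("zero-target spec yields no A->K bigram at all", {
  spec <- task_spec(n_targets = 0)
  sq <- generate_trial_sequence(spec, seed = 2)
  expect_equal(count_ak_bigrams(sq$stimulus), 0)
  expect_false(any(sq$is_target))
})

test_that("sequence generation is deterministic given the seed", {
  s1 <- generate_trial_sequence(task_spec(), seed = 1)
  s2 <- generate_trial_sequence(task_spec(), seed = 1)
  s3 <- generate_trial_sequence(task_spec(), seed = 2)
  expect_identical(s1, s2)
  expect_false(identical(s1$stimulus, s3$stimulus))
})

test_that("infeasible placements and invalid specs are configuration errors", {
  expect_error(task_spec(n_trials = 120, n_targets = 100,
                         n_placement_blocks = 1), "infeasible")
  expect_error(task_spec(n_trials = 100, n_placement_blocks = 3),
               "divisible")
  expect_error(task_spec(n_targets = 10, n_placement_blocks = 4),
               "divisible")
})

# session simulation --------------------------------------------------------

test_that("noiseless degenerate session returns rt_mu exactly", {
  trl <- quick_session(seed = 4, rt_sigma = 0, rt_tau = 0, trend_slope = 0,
                       osc_amplitude = 0, p_miss = 0, p_commission = 0)
  rts <- trl$rt[trl$is_target]
  expect_equal(rts, rep(500, 100))
  expect_true(all(is.na(trl$rt[!trl$is_target])))
})

test_that("sinusoid-only session matches the closed form pointwise", {
  spec <- task_spec()
  sq <- generate_trial_sequence(spec, seed = 6)
  sim <- participant_sim(rt_mu = 500, rt_sigma = 0, rt_tau = 0,
                         trend_slope = 0, osc_amplitude = 100,
                         osc_freq = 0.063, osc_phase = 0.7,
                         p_miss = 0, p_commission = 0, seed = 6)
  trl <- simulate_session(sq, sim, spec)
  tgt <- which(trl$is_target)
  expected <- 500 + 100 * sin(2 * pi * 0.063 * trl$onset_time[tgt] + 0.7)
  expect_equal(trl$rt[tgt], expected, tolerance = 1e-12)
})

test_that("p_miss = 1 silences all target trials", {
  trl <- quick_session(seed = 8, p_miss = 1, p_commission = 0)
  expect_true(all(is.na(trl$rt[trl$is_target])))
})

test_that("spectral ground truth: variance of noise-free sinusoid is A^2/2", {
  # session spans ~472 s; at 0.063 Hz that is ~30 oscillation periods
  trl <- quick_session(seed = 10, rt_sigma = 0, rt_tau = 0,
                       osc_amplitude = 80, osc_freq = 0.063,
                       osc_phase = 1.1, p_miss = 0, p_commission = 0)
  v <- var(trl$rt[trl$is_target])
  expect_lt(abs(v - 80^2 / 2) / (80^2 / 2), 0.05)
})

test_that("simulated RTs respect the floor and the response window", {
  trl <- quick_session(seed = 12, rt_mu = 300, rt_sigma = 150, rt_tau = 100)
  rts <- trl$rt[!is.na(trl$rt)]
  expect_true(all(rts >= 100 & rts <= 1135))
})

# cohort generation ---------------------------------------------------------

test_that("cohort bookkeeping: sizes, schema, determinism", {
  groups <- list(group_spec("HC", 4), group_spec("BPd", 4))
  c1 <- generate_cohort(groups, seed = 99)
  c2 <- generate_cohort(groups, seed = 99)
  c3 <- generate_cohort(groups, seed = 100)
  expect_equal(nrow(c1$covariates), 8)
  expect_equal(nrow(c1$trials), 8 * 480)
  expect_identical(c1$trials, c2$trials)      # same master seed
  expect_identical(c1$covariates, c2$covariates)
  expect_false(identical(c1$trials$rt_ms, c3$trials$rt_ms))
  expect_named(c1$trials, c("participant_id", "group", "age", "sex",
                            "trial_index", "onset_time_s", "stimulus",
                            "is_target", "rt_ms"))
  expect_true(all(c1$covariates$age >= 18 & c1$covariates$age <= 65))
})

test_that("empty group is a configuration error", {
  expect_error(group_spec("HC", 0), "empty")
})
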