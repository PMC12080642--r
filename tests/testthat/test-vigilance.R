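# block-wise CoV ------------------------------------------------------------

test_that("CoV of hand-computable blocks", {
  # constant series -> 0
  s <- toy_session(rep(500, 3))
  expect_equal(compute_block_cov(s)$cov, 0)
  # {400, 600}: sample SD 141.42 / mean 500 = 0.28284 (needs min 2 rts)
  s2 <- toy_session(c(400, 600), trial_index = c(0, 1))
  tab2 <- compute_block_cov(s2, min_rt_per_block = 2)
  expect_equal(tab2$cov, sqrt(2) * 100 / 500, tolerance = 1e-10)
  expect_equal(round(tab2$cov, 5), 0.28284)
})

test_that("noiseless trend-only session has near-zero CoV in every block", {
  trl <- quick_session(seed = 51, rt_sigma = 0, rt_tau = 0,
                       trend_slope = 0.1, p_miss = 0, p_commission = 0)
  tab <- compute_block_cov(classify_responses(trl))
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$cov < 0.01))
})

test_that("CoV is scale invariant", {
  set.seed(61)
  rts <- runif(40, 300, 900)
  s1 <- toy_session(rts, trial_index = seq(0, 478, length.out = 40))
  s2 <- toy_session(rts * 3.7, trial_index = seq(0, 478, length.out = 40))
  expect_equal(compute_block_cov(s1)$cov, compute_block_cov(s2)$cov,
               tolerance = 1e-12)
})

test_that("blocks below the minimum hit count emit no row", {
  # 2 RTs in block 1, 4 in block 2
  s <- toy_session(c(500, 520, 480, 510, 530, 490),
                   trial_index = c(0, 30, 60, 75, 90, 110))
  tab <- compute_block_cov(s, min_rt_per_block = 3)
  expect_equal(tab$block, 2)
  expect_equal(tab$n_rt, 4)
  # block_centered is block - 4.5
  expect_equal(tab$block_centered, 2 - 4.5)
})

# mixed model ---------------------------------------------------------------

test_that("vigilance model recovers structure and reports full inference", {
  q <- quick_cov_table(71, list(
    group_spec("HC", 12, rt_tau = 0, p_miss = 0.02),
    group_spec("BPd", 12, rt_tau = 0, p_miss = 0.02,
               cov_trend = c(0.006, 0.002))))
  fit <- fit_vigilance_model(q$table, reference_group = "HC")
  expect_s3_class(fit, "vigilance_fit")
  expect_equal(fit$omnibus$effect, c("diagnosis", "block",
                                     "diagnosis:block"))
  expect_true(all(is.finite(fit$omnibus$F)))
  # Satterthwaite ddf can never exceed the residual df
  expect_true(all(fit$omnibus$ddf <= nrow(q$table)))
  # R2 sanity: in [0,1], conditional >= marginal
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  expect_gte(fit$r2["conditional"], fit$r2["marginal"])
  # the injected positive slope group should have the larger simple slope
  slopes <- setNames(fit$slopes$slope, fit$slopes$group)
  expect_gt(slopes["BPd"], slopes["HC"])
  # 1 pairwise contrast per 2 groups, Tukey p in [0,1]
  expect_equal(nrow(fit$intercept_contrasts), 1)
  expect_true(all(fit$intercept_contrasts$p_tukey >= 0 &
                    fit$intercept_contrasts$p_tukey <= 1))
})

test_that("interaction and slope estimates are invariant to recentering block", {
  q <- quick_cov_table(81, list(group_spec("HC", 10),
                                group_spec("MDd", 10)))
  f1 <- fit_vigilance_model(q$table, ddf = "none")
  shifted <- q$table
  shifted$block_centered <- shifted$block_centered + 2.25  # arbitrary shift
  f2 <- fit_vigilance_model(shifted, ddf = "none")
  b1 <- lme4::fixef(f1$model); b2 <- lme4::fixef(f2$model)
  sel <- grep("block_centered", names(b1))
  expect_equal(b1[sel], b2[sel], tolerance = 1e-6)
  expect_equal(f1$slope_estimates, f2$slope_estimates, tolerance = 1e-6)
})

test_that("Satterthwaite df approaches classical df in a balanced design", {
  # balanced two-group random-intercept world: the between-group contrast's
  # classical df is n_subjects - n_between_parameters
  set.seed(91)
  ns <- 20; nb <- 8
  dat <- expand.grid(participant_id = sprintf("P%02d", 1:(2 * ns)),
                     block = 1:nb)
  dat$group <- ifelse(as.integer(gsub("P", "", dat$participant_id)) <= ns,
                      "HC", "BPd")
  dat$block_centered <- dat$block - mean(1:nb)
  dat$age <- rep(round(runif(2 * ns, 20, 60)), nb)
  dat$sex <- rep(sample(c("F", "M"), 2 * ns, replace = TRUE), nb)
  u <- rnorm(2 * ns, 0, 0.04)
  dat$cov <- 0.12 + u[as.integer(factor(dat$participant_id))] +
    rnorm(nrow(dat), 0, 0.02)
  fit <- fit_vigilance_model(dat, reference_group = "HC")
  ddf_diag <- fit$omnibus$ddf[fit$omnibus$effect == "diagnosis"]
  expect_gt(ddf_diag, 0.6 * (2 * ns - 4))
  expect_lt(ddf_diag, 1.4 * (2 * ns - 4))
  # within-subject block effect has far larger df than the between effect
  ddf_block <- fit$omnibus$ddf[fit$omnibus$effect == "block"]
  expect_gt(ddf_block, 3 * ddf_diag)
})

test_that("underdetermined designs fail loudly, never silently", {
  q <- quick_cov_table(101, list(group_spec("HC", 1), group_spec("BPd", 1)))
  expect_error(fit_vigilance_model(q$table), ">= 2 participants")
  one_group <- quick_cov_table(102, list(group_spec("HC", 6)))
  expect_error(fit_vigilance_model(one_group$table), "two groups")
  expect_error(fit_vigilance_model(q$table[0, ]), ".")
})
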