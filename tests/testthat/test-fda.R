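make_pg <- function(freqs, power, id = "P1") {
  structure(list(participant_id = id, frequencies = freqs, power = power,
                 f_min = min(freqs), f_max = max(freqs), oversampling = 1,
                 normalized = TRUE, n = 100), class = "periodogram")
}

# synthetic cohort of smoothed spectra with a bump added for some groups
make_spectra_cohort <- function(n_per_group, bump_amp, f0 = 0.063,
                                seed = 1, groups = c("HC", "PAT")) {
  set.seed(seed)
  freqs <- seq(0.004, 0.104, length.out = 50)
  pgs <- list(); covs <- list(); k <- 0
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1
      id <- sprintf("%s_%02d", groups[g], i)
      pw <- rexp(50) + bump_amp[g] * exp(-((freqs - f0) / 0.006)^2)
      pgs[[k]] <- make_pg(freqs, pw, id)
      covs[[k]] <- data.frame(participant_id = id, group = groups[g],
                              age = round(runif(1, 20, 60)),
                              sex = sample(c("F", "M"), 1))
    }
  }
  list(pgs = pgs, covs = do.call(rbind, covs))
}

# smoothing -----------------------------------------------------------------

test_that("cubic polynomials are reproduced exactly by the spline basis", {
  f <- seq(0.002, 0.106, length.out = 49)
  pw <- 3 + 2 * f - 50 * f^2 + 1000 * f^3
  sm <- smooth_spectrum(make_pg(f, pw))
  expect_equal(sm$n_basis, 48)          # 44 interior knots + order 4
  expect_equal(sm$n_interior_knots, 44)
  expect_false(sm$reduced)
  expect_lt(max(abs(sm$smoothed_power - pw)), 1e-8)
})

test_that("all-zero power smooths to all zeros", {
  f <- seq(0.002, 0.106, length.out = 60)
  sm <- smooth_spectrum(make_pg(f, rep(0, 60)))
  expect_equal(sm$smoothed_power, rep(0, 60), tolerance = 1e-12)
})

test_that("a sharp peak survives smoothing within one grid step", {
  f <- seq(0.002, 0.106, length.out = 80)
  pw <- 20 * exp(-((f - 0.063) / (1.5 * diff(f)[1]))^2) + 0.2
  sm <- smooth_spectrum(make_pg(f, pw))
  expect_lt(abs(f[which.max(sm$smoothed_power)] - f[which.max(pw)]),
            diff(f)[1] + 1e-12)
})

test_that("too few points triggers automatic basis reduction with a warning", {
  f <- seq(0.004, 0.1, length.out = 20)
  expect_warning(sm <- smooth_spectrum(make_pg(f, rexp(20))), "reducing")
  expect_true(sm$reduced)
  expect_equal(sm$n_basis, 20)
})

test_that("common grid spans the intersection of participant ranges", {
  p1 <- make_pg(seq(0.002, 0.100, length.out = 49), rexp(49), "A")
  p2 <- make_pg(seq(0.003, 0.106, length.out = 52), rexp(52), "B")
  sm <- smooth_spectra(list(p1, p2), n_eval = 100)
  expect_equal(range(sm$eval_frequencies), c(0.003, 0.100))
  expect_equal(dim(sm$power), c(2, 100))
  expect_equal(rownames(sm$power), c("A", "B"))
})

# pointwise tests -----------------------------------------------------------

test_that("the functional F-test localizes an injected band difference", {
  ch <- make_spectra_cohort(25, bump_amp = c(0, 8), seed = 3)
  sm <- smooth_spectra(ch$pgs, n_eval = 150)
  ft <- pointwise_group_ftest(sm, ch$covs)
  expect_s3_class(ft, "band_test_result")
  expect_gt(nrow(ft$bands), 0)
  covers <- any(ft$bands$f_lo <= 0.063 & ft$bands$f_hi >= 0.063)
  expect_true(covers)
  # period equivalents are reciprocals of the exact endpoints
  expect_equal(ft$bands$period_lo, 1 / ft$bands$f_hi)
  expect_equal(ft$bands$period_hi, 1 / ft$bands$f_lo)
  expect_equal(ft$ndf, 1)
})

test_that("pairwise t-test separates groups inside the band; critical lines ordered", {
  ch <- make_spectra_cohort(25, bump_amp = c(0, 8), seed = 4)
  sm <- smooth_spectra(ch$pgs, n_eval = 150)
  ft <- pointwise_group_ftest(sm, ch$covs)
  b <- ft$bands[ft$bands$f_lo <= 0.063 & ft$bands$f_hi >= 0.063, ][1, ]
  tt <- pairwise_pointwise_ttest(sm, c("PAT", "HC"), ch$covs,
                                 band = c(b$f_lo, b$f_hi))
  expect_true(all(tt$crit_bonferroni >= tt$crit_uncorrected))
  expect_true(any(tt$sig_bonferroni))
  expect_gt(mean(tt$t), 0)  # PAT - HC positive where power was injected
  expect_error(pairwise_pointwise_ttest(sm, c("PAT", "XX"), ch$covs),
               "not present")
})

test_that("band summary reports per-group power and handles the empty case", {
  ch <- make_spectra_cohort(25, bump_amp = c(0, 8), seed = 5)
  sm <- smooth_spectra(ch$pgs, n_eval = 150)
  ft <- pointwise_group_ftest(sm, ch$covs)
  summ <- summarize_band(ft, sm, ch$covs)
  bi <- which(ft$bands$f_lo <= 0.063 & ft$bands$f_hi >= 0.063)[1]
  gp <- summ$group_power[summ$group_power$band == bi, ]
  expect_gt(gp$mean_power[gp$group == "PAT"],
            gp$mean_power[gp$group == "HC"])
  # no significant band -> empty summary, not an error
  empty <- ft; empty$bands <- ft$bands[0, ]
  s0 <- summarize_band(empty, sm, ch$covs)
  expect_equal(nrow(s0$group_power), 0)
})

test_that("permuting group labels destroys the detected band", {
  ch <- make_spectra_cohort(25, bump_amp = c(0, 8), seed = 6)
  sm <- smooth_spectra(ch$pgs, n_eval = 150)
  ft <- pointwise_group_ftest(sm, ch$covs)
  frac_true <- mean(ft$F > ft$critical)
  set.seed(99)
  fracs <- replicate(20, {
    perm <- ch$covs
    perm$group <- sample(perm$group)
    mean(pointwise_group_ftest(sm, perm)$F >
           pointwise_group_ftest(sm, perm)$critical)
  })
  expect_gt(frac_true, 0.05)
  expect_lt(mean(fracs), frac_true / 2)
})

test_that("frequency/period conversion matches the printed equivalences", {
  expect_equal(round(freq_period_convert(15.77), 3), 0.063)
  expect_equal(round(freq_period_convert(20.24), 3), 0.049)
  expect_equal(round(freq_period_convert(12.90), 3), 0.078)
  # reciprocal involution and fixed point
  for (x in c(0.049, 0.063, 0.077, 1.0, 20.24))
    expect_equal(freq_period_convert(freq_period_convert(x)), x)
  expect_equal(freq_period_convert(1.0), 1.0)
  expect_error(freq_period_convert(0), "positive")
  expect_error(freq_period_convert(-3), "positive")
})
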