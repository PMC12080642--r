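#' Smooth a periodogram with a cubic B-spline basis
#'
#' Least-squares projection of the power curve onto an order-4 (cubic)
#' B-spline basis with `n_interior_knots` equally spaced interior knots over
#' the participant's frequency range (44 knots -> 48 basis functions),
#' chosen flexible enough to preserve genuine spectral peaks. If the
#' periodogram has fewer points than basis functions the knot count is
#' reduced automatically (with a warning) so the projection stays
#' determined.
#'
#' @param pg a `periodogram`.
#' @param n_interior_knots interior knot count (flexibility control).
#' @param eval_frequencies frequencies at which to evaluate the smooth;
#'   default the periodogram's own grid. Must lie within the participant's
#'   frequency range.
#' @param order spline order (4 = cubic).
#' @return Object of class `smoothed_spectrum`: `participant_id`,
#'   `eval_frequencies`, `smoothed_power`, and basis metadata (`n_basis`,
#'   `n_interior_knots`, `order`, `reduced`).
#' @export
smooth_spectrum <- function(pg, n_interior_knots = 44L,
                            eval_frequencies = NULL, order = 4L) {
  stopifnot(inherits(pg, "periodogram"))
  f <- pg$frequencies
  npt <- length(f)
  nk <- as.integer(n_interior_knots)
  if (npt < nk + order) {
    nk <- max(npt - order, 0L)
    warning(sprintf(
      "periodogram has %d points < %d basis functions; reducing to %d interior knots (%d basis)",
      npt, n_interior_knots + order, nk, nk + order), call. = FALSE)
  }
  rng <- range(f)
  interior <- if (nk > 0L)
    seq(rng[1L], rng[2L], length.out = nk + 2L)[-c(1L, nk + 2L)]
  else numeric(0)
  knots <- c(rep(rng[1L], order), interior, rep(rng[2L], order))
  B <- splines::splineDesign(knots, f, ord = order)
  coef <- qr.coef(qr(B), pg$power)
  coef[is.na(coef)] <- 0
  if (is.null(eval_frequencies)) eval_frequencies <- f
  if (min(eval_frequencies) < rng[1L] - 1e-10 ||
      max(eval_frequencies) > rng[2L] + 1e-10)
    stop("eval_frequencies outside the participant's frequency range",
         call. = FALSE)
  ef <- pmin(pmax(eval_frequencies, rng[1L]), rng[2L])
  Be <- splines::splineDesign(knots, ef, ord = order)
  structure(list(participant_id = pg$participant_id,
                 eval_frequencies = eval_frequencies,
                 smoothed_power = drop(Be %*% coef),
                 n_basis = nk + order, n_interior_knots = nk,
                 order = order, reduced = nk != as.integer(n_interior_knots)),
            class = "smoothed_spectrum")
}

#' Smooth a collection of periodograms onto a common frequency grid
#'
#' Individual grids differ slightly (spans depend on which targets were
#' hit), so curves are evaluated on `n_eval` equally spaced frequencies over
#' the intersection of all participants' frequency ranges.
#'
#' @param pgs named list of `periodogram` objects.
#' @param n_interior_knots,order passed to [smooth_spectrum()].
#' @param n_eval number of common evaluation frequencies.
#' @return Object of class `smoothed_spectra`: `eval_frequencies`, `power`
#'   (participants x frequencies matrix with participant ids as rownames),
#'   and basis metadata.
#' @export
smooth_spectra <- function(pgs, n_interior_knots = 44L, n_eval = 200L,
                           order = 4L) {
  stopifnot(length(pgs) >= 1L,
            all(vapply(pgs, inherits, TRUE, "periodogram")))
  lo <- max(vapply(pgs, `[[`, 1, "f_min"))
  hi <- min(vapply(pgs, `[[`, 1, "f_max"))
  if (hi <= lo)
    stop("participant frequency ranges do not overlap", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_eval)
  sm <- lapply(pgs, smooth_spectrum, n_interior_knots = n_interior_knots,
               eval_frequencies = grid, order = order)
  pw <- do.call(rbind, lapply(sm, `[[`, "smoothed_power"))
  rownames(pw) <- vapply(sm, `[[`, "", "participant_id")
  structure(list(eval_frequencies = grid, power = pw,
                 n_interior_knots = n_interior_knots, order = order,
                 n_basis = vapply(sm, `[[`, 1L, "n_basis"),
                 reduced = vapply(sm, `[[`, TRUE, "reduced")),
            class = "smoothed_spectra")
}

# covariate-adjusted design matrices shared by the F- and t-tests
fda_design <- function(covariates, ids) {
  m <- match(ids, covariates$participant_id)
  if (anyNA(m))
    stop("missing covariates for: ",
         paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
  d <- covariates[m, , drop = FALSE]
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d
}

#' Pointwise functional F-test for a group effect on spectral power
#'
#' At each frequency of the common grid, fits
#' `power ~ group + age + sex` across participants and computes the partial
#' F for the group factor (numerator df = number of groups - 1). The
#' critical value is the central F quantile at `alpha`; significant bands
#' are maximal contiguous frequency runs where F exceeds it.
#'
#' @param spectra a `smoothed_spectra` object.
#' @param covariates data.frame with `participant_id`, `group`, `age`,
#'   `sex`.
#' @param alpha pointwise significance level.
#' @return Object of class `band_test_result`: `frequencies`, `F`
#'   statistic curve, `critical`, dfs, and `bands` (data.frame with
#'   `f_lo`, `f_hi` in Hz and `period_lo`, `period_hi` in seconds, where
#'   `period_lo = 1/f_hi`).
#' @export
pointwise_group_ftest <- function(spectra, covariates, alpha = 0.05) {
  stopifnot(inherits(spectra, "smoothed_spectra"))
  d <- fda_design(covariates, rownames(spectra$power))
  k <- nlevels(d$group)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  cov_terms <- paste(c("age", if (nlevels(d$sex) > 1L) "sex"),
                     collapse = " + ")
  X1 <- stats::model.matrix(
    stats::reformulate(c("group", "age", if (nlevels(d$sex) > 1L) "sex")), d)
  X0 <- stats::model.matrix(stats::reformulate(strsplit(cov_terms,
                                                        " \\+ ")[[1]]), d)
  if (qr(X1)$rank < ncol(X1))
    stop("rank-deficient design (e.g. a single-sex group confounded with ",
         "a covariate); cannot adjust", call. = FALSE)
  Y <- spectra$power
  q1 <- qr(X1); q0 <- qr(X0)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  ndf <- k - 1L
  ddf <- nrow(Y) - ncol(X1)
  Fstat <- ((rss0 - rss1) / ndf) / (rss1 / ddf)
  crit <- stats::qf(1 - alpha, ndf, ddf)
  structure(list(frequencies = spectra$eval_frequencies, F = Fstat,
                 critical = crit, ndf = ndf, ddf = ddf, alpha = alpha,
                 bands = runs_to_bands(spectra$eval_frequencies,
                                       Fstat > crit)),
            class = "band_test_result")
}

runs_to_bands <- function(freqs, flag) {
  if (!any(flag))
    return(data.frame(f_lo = numeric(0), f_hi = numeric(0),
                      period_lo = numeric(0), period_hi = numeric(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(f_lo = freqs[starts[sel]], f_hi = freqs[ends[sel]],
             period_lo = 1 / freqs[ends[sel]],
             period_hi = 1 / freqs[starts[sel]])
}

#' @export
print.band_test_result <- function(x, ...) {
  cat(sprintf(
    "Pointwise functional F-test: critical F[%d, %d] = %.2f at alpha = %g\n",
    x$ndf, x$ddf, x$critical, x$alpha))
  if (nrow(x$bands) == 0L) cat("  no significant band\n")
  else for (i in seq_len(nrow(x$bands)))
    cat(sprintf(
      "  band %d: %.4g-%.4g Hz (once every %.2f to %.2f s)\n", i,
      x$bands$f_lo[i], x$bands$f_hi[i], x$bands$period_lo[i],
      x$bands$period_hi[i]))
  invisible(x)
}

#' Post-hoc pairwise pointwise t-test on spectral power
#'
#' Within a frequency band flagged by the functional F-test (or over the
#' full grid), fits `power ~ group + age + sex` on the two groups' data at
#' each frequency and reports the t statistic for the group contrast
#' together with two critical lines: uncorrected (`alpha`) and Bonferroni
#' (`alpha / n_comparisons`, defaulting to the 6 pairwise comparisons among
#' 4 groups).
#'
#' @param spectra a `smoothed_spectra`.
#' @param pair character vector of two group labels; the contrast is
#'   `pair[1] - pair[2]`.
#' @param covariates as in [pointwise_group_ftest()].
#' @param band optional numeric `c(f_lo, f_hi)` restricting the test;
#'   NULL = full grid.
#' @param alpha significance level.
#' @param n_comparisons Bonferroni family size.
#' @return data.frame: `frequency`, `t`, `df`, `crit_uncorrected`,
#'   `crit_bonferroni`, `sig_uncorrected`, `sig_bonferroni`.
#' @export
pairwise_pointwise_ttest <- function(spectra, pair, covariates,
                                     band = NULL, alpha = 0.05,
                                     n_comparisons = 6L) {
  stopifnot(inherits(spectra, "smoothed_spectra"), length(pair) == 2L)
  d <- fda_design(covariates, rownames(spectra$power))
  if (!all(pair %in% levels(d$group)))
    stop("pair not present in data: ", paste(pair, collapse = ", "),
         call. = FALSE)
  keep <- d$group %in% pair
  d2 <- droplevels(d[keep, , drop = FALSE])
  d2$group <- stats::relevel(d2$group, ref = pair[2L])
  Y <- spectra$power[keep, , drop = FALSE]
  freqs <- spectra$eval_frequencies
  if (!is.null(band)) {
    sel <- freqs >= band[1L] & freqs <= band[2L]
    if (!any(sel)) stop("band contains no grid frequencies", call. = FALSE)
    Y <- Y[, sel, drop = FALSE]
    freqs <- freqs[sel]
  }
  X <- stats::model.matrix(
    stats::reformulate(c("group", "age", if (nlevels(d2$sex) > 1L) "sex")),
    d2)
  jj <- match(paste0("group", pair[1L]), colnames(X))
  qX <- qr(X)
  if (qX$rank < ncol(X)) stop("rank-deficient pair design", call. = FALSE)
  cf <- qr.coef(qX, Y)
  rss <- colSums(qr.resid(qX, Y)^2)
  df <- nrow(X) - ncol(X)
  xtxinv_jj <- chol2inv(qr.R(qX))[jj, jj]
  se <- sqrt(rss / df * xtxinv_jj)
  tval <- cf[jj, ] / se
  cu <- stats::qt(1 - alpha / 2, df)
  cb <- stats::qt(1 - alpha / (2 * n_comparisons), df)
  data.frame(frequency = freqs, t = tval, df = df,
             crit_uncorrected = cu, crit_bonferroni = cb,
             sig_uncorrected = abs(tval) > cu,
             sig_bonferroni = abs(tval) > cb, row.names = NULL)
}

#' Summarize significant frequency bands
#'
#' For each band flagged by [pointwise_group_ftest()], reports the band
#' endpoints in Hz and their period equivalents in seconds, plus each
#' group's mean smoothed power within the band (mean over band frequencies,
#' then over the group's participants).
#'
#' @param result a `band_test_result`.
#' @param spectra the `smoothed_spectra` the test was run on.
#' @param covariates as in [pointwise_group_ftest()].
#' @return A list with `bands` (endpoints and periods) and `group_power`
#'   (data.frame band x group mean power); both empty when no band is
#'   significant.
#' @export
summarize_band <- function(result, spectra, covariates) {
  stopifnot(inherits(result, "band_test_result"),
            inherits(spectra, "smoothed_spectra"))
  if (nrow(result$bands) == 0L)
    return(list(bands = result$bands,
                group_power = data.frame(band = integer(0),
                                         group = character(0),
                                         mean_power = numeric(0))))
  d <- fda_design(covariates, rownames(spectra$power))
  gp <- do.call(rbind, lapply(seq_len(nrow(result$bands)), function(i) {
    sel <- spectra$eval_frequencies >= result$bands$f_lo[i] &
      spectra$eval_frequencies <= result$bands$f_hi[i]
    per_part <- rowMeans(spectra$power[, sel, drop = FALSE])
    data.frame(band = i, group = levels(d$group),
               mean_power = as.numeric(tapply(per_part, d$group, mean)),
               row.names = NULL)
  }))
  list(bands = result$bands, group_power = gp)
}

#' Convert between frequency (Hz) and period (seconds)
#'
#' The reciprocal map, its own inverse: 0.063 Hz corresponds to one
#' oscillation every 15.87 s, and a 20.24 s period to 0.049 Hz.
#'
#' @param x positive frequency in Hz (returns seconds) or period in seconds
#'   (returns Hz).
#' @return `1/x`.
#' @export
freq_period_convert <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("input must be positive and finite", call. = FALSE)
  1 / x
}
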