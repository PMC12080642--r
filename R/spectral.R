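#' Correct-response RT series
#'
#' Light container pairing hit onset times (seconds from session start) with
#' hit RTs (ms) for one participant — the unevenly sampled series the
#' spectral analysis operates on. Sampling times are the onsets of the "K"
#' stimuli that elicited the responses.
#'
#' @param times strictly increasing onset times, s.
#' @param values RTs, ms.
#' @param participant_id identifier.
#' @return Object of class `rt_series`.
#' @export
rt_series <- function(times, values, participant_id = NA_character_) {
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(participant_id = participant_id,
                 times = as.numeric(times), values = as.numeric(values),
                 n = length(times)), class = "rt_series")
}

#' @rdname rt_series
#' @param session a `session_result`.
#' @export
as_rt_series <- function(session) {
  stopifnot(inherits(session, "session_result"))
  rt_series(session$rt_series$onset_time, session$rt_series$rt,
            session$participant_id)
}

#' Remove the linear time-on-task trend
#'
#' Subtracts the ordinary-least-squares line in time from the RT values so
#' the periodogram reflects fluctuations around the trend, not the trend
#' itself. Times are unchanged.
#'
#' @param series an `rt_series` with at least 3 points.
#' @return The detrended `rt_series` (mean ~ 0, OLS slope ~ 0).
#' @export
detrend <- function(series) {
  stopifnot(inherits(series, "rt_series"))
  if (series$n < 3L) stop("need at least 3 points to detrend", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, series$times), series$values)
  rt_series(series$times, fit$residuals, series$participant_id)
}

#' Frequency grid for the Lomb-Scargle periodogram
#'
#' Standard data-driven construction for uneven sampling: frequencies from
#' `1/T` (one cycle over the observation span `T`) up to the pseudo-Nyquist
#' `n/(2T)`, in steps of `1/(oversampling * T)`. With the Vigil geometry
#' (about 100 hits over about 473 s) this spans roughly 0.002-0.106 Hz,
#' covering the infraslow band.
#'
#' @param series an `rt_series`.
#' @param oversampling grid densification factor (>= 1).
#' @return Ascending numeric vector of frequencies, Hz.
#' @export
frequency_grid <- function(series, oversampling = 1) {
  stopifnot(inherits(series, "rt_series"))
  T <- series$times[series$n] - series$times[1L]
  if (!is.finite(T) || T <= 0) stop("time span must be positive",
                                    call. = FALSE)
  if (oversampling < 1) stop("oversampling must be >= 1", call. = FALSE)
  step <- 1 / (oversampling * T)
  f_max <- series$n / (2 * T)
  seq(1 / T, f_max, by = step)
}

# "zero" variance up to floating point: catches exactly constant series and
# series that detrend to numerical noise (pure lines)
zero_variance <- function(s2, s2_raw) {
  !is.finite(s2) || s2 <= 0 || s2 < 1e-12 * max(s2_raw, 1)
}

#' Lomb-Scargle periodogram of an unevenly sampled RT series
#'
#' Classical normalized Lomb-Scargle power. For each frequency `f`
#' (`omega = 2*pi*f`), with the phase origin `tau` defined by
#' `tan(2*omega*tau) = sum(sin(2*omega*t)) / sum(cos(2*omega*t))`,
#' \deqn{P_N(f) = \frac{1}{2\sigma^2}\left\{
#'   \frac{[\sum_j x_j \cos\omega(t_j-\tau)]^2}{\sum_j \cos^2\omega(t_j-\tau)}
#'  +\frac{[\sum_j x_j \sin\omega(t_j-\tau)]^2}{\sum_j \sin^2\omega(t_j-\tau)}
#'  \right\}}
#' where \eqn{\sigma^2} is the sample variance of the values. Under
#' Gaussian white noise the normalized power has expectation ~ 1; an
#' injected sinusoid of amplitude A peaks near `n A^2 / (4 sigma^2)`.
#'
#' @param series an `rt_series`; detrended internally unless
#'   `detrend = FALSE`.
#' @param frequencies evaluation frequencies, Hz; default
#'   [frequency_grid()].
#' @param oversampling passed to [frequency_grid()] when `frequencies` is
#'   NULL.
#' @param detrend remove the OLS line first (recommended; the normalization
#'   assumes a centered series).
#' @param normalize if FALSE, return raw (not variance-scaled) power.
#' @return Object of class `periodogram`: `participant_id`, `frequencies`,
#'   `power`, and grid metadata (`f_min`, `f_max`, `oversampling`,
#'   `normalized`, `n`).
#' @export
lomb_scargle <- function(series, frequencies = NULL, oversampling = 1,
                         detrend = TRUE, normalize = TRUE) {
  stopifnot(inherits(series, "rt_series"))
  s2_raw <- stats::var(series$values)
  if (detrend && series$n >= 3L) series <- detrend(series)
  x <- series$values - mean(series$values)
  s2 <- stats::var(series$values)
  if (normalize && zero_variance(s2, s2_raw))
    stop("zero-variance series: normalized power undefined", call. = FALSE)
  if (is.null(frequencies))
    frequencies <- frequency_grid(series, oversampling)
  t <- series$times
  pw <- vapply(frequencies, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    cc <- sum(ct^2); ss <- sum(st^2)
    xc <- sum(x * ct); xs <- sum(x * st)
    (if (cc > 1e-12) xc^2 / cc else 0) +
      (if (ss > 1e-12) xs^2 / ss else 0)
  }, 1) / 2
  if (normalize) pw <- pw / s2
  structure(list(participant_id = series$participant_id,
                 frequencies = frequencies, power = pw,
                 f_min = min(frequencies), f_max = max(frequencies),
                 oversampling = oversampling, normalized = normalize,
                 n = series$n), class = "periodogram")
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf(
    "Lomb-Scargle periodogram (%s): %d frequencies in [%.4g, %.4g] Hz, peak %.2f at %.4g Hz\n",
    x$participant_id, length(x$frequencies), x$f_min, x$f_max,
    max(x$power), x$frequencies[which.max(x$power)]))
  invisible(x)
}

#' Independent least-squares oracle for Lomb-Scargle power
#'
#' Computes the power at a single frequency by explicitly least-squares
#' fitting `a*cos(2*pi*f*t) + b*sin(2*pi*f*t)` to the centered values and
#' applying the variance-explained identity: the explained sum of squares
#' of that two-parameter fit, divided by `2*sigma^2`. Algebraically
#' identical to the tau-shifted Lomb-Scargle formula (the tau rotation is an
#' orthogonalization of the same two-dimensional regression), but computed
#' through a different route — kept as an independent check, not used by
#' [lomb_scargle()].
#'
#' @param series an `rt_series` (detrended internally unless
#'   `detrend = FALSE`).
#' @param f a single frequency, Hz.
#' @param detrend,normalize as in [lomb_scargle()].
#' @return Scalar power.
#' @export
lomb_scargle_oracle <- function(series, f, detrend = TRUE,
                                normalize = TRUE) {
  stopifnot(inherits(series, "rt_series"), length(f) == 1L, f > 0)
  s2_raw <- stats::var(series$values)
  if (detrend && series$n >= 3L) series <- detrend(series)
  x <- series$values - mean(series$values)
  s2 <- stats::var(series$values)
  if (normalize && zero_variance(s2, s2_raw))
    stop("zero-variance series: normalized power undefined", call. = FALSE)
  X <- cbind(cos(2 * pi * f * series$times), sin(2 * pi * f * series$times))
  coef <- tryCatch(solve(crossprod(X), crossprod(X, x)),
                   error = function(e) MASS::ginv(crossprod(X)) %*%
                     crossprod(X, x))
  ess <- drop(crossprod(x, X %*% coef))   # x'X(X'X)^-1 X'x
  pw <- ess / 2
  if (normalize) pw / s2 else pw
}
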