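#' Participant-level simulation parameters
#'
#' Encodes the generative reaction-time model assumed by the downstream
#' analyses: on each target trial the (pre-truncation) RT is
#' \deqn{rt = \mu + \beta \cdot i + A \sin(2\pi f t_i + \phi) + N(0, \sigma_i)
#'   + Exp(\tau)}
#' with trial index \eqn{i}, onset time \eqn{t_i} (s), a linear time-on-task
#' trend \eqn{\beta}, an infraslow sinusoid (amplitude \eqn{A} ms, frequency
#' \eqn{f} Hz, phase \eqn{\phi}), Gaussian trial-to-trial noise whose SD may
#' drift linearly over analysis blocks (`cov_trend`, the CoV change per
#' block), and an optional exponential tail (\eqn{\tau} ms). Draws outside
#' `[rt_floor, response_window]` are resampled. Target trials are dropped
#' (missed) with probability `p_miss`; non-target trials carry a commission
#' response with probability `p_commission`.
#'
#' @param participant_id identifier.
#' @param group group label (e.g. "HC", "BPe", "BPd", "MDd").
#' @param age years.
#' @param sex "F" or "M".
#' @param rt_mu baseline mean RT, ms (> 0).
#' @param rt_sigma Gaussian noise SD at the session midpoint, ms.
#' @param rt_tau exponential tail scale, ms (0 disables).
#' @param trend_slope change in mean RT per trial, ms.
#' @param cov_trend change in coefficient of variation per analysis block
#'   (dimensionless); implemented as noise SD varying linearly in the
#'   centered block index: `sd(block) = rt_sigma + cov_trend * rt_mu *
#'   (block - (n_blocks+1)/2)`.
#' @param osc_amplitude infraslow oscillation amplitude, ms.
#' @param osc_freq oscillation frequency, Hz; must lie in
#'   `(0, 0.5/soa_seconds]`.
#' @param osc_phase phase, radians.
#' @param p_miss probability a target trial receives no response.
#' @param p_commission probability a non-target trial receives a response.
#' @param seed per-participant RNG seed.
#' @return An object of class `participant_sim`.
#' @export
participant_sim <- function(participant_id = "P001", group = "HC",
                            age = 40, sex = "F",
                            rt_mu = 500, rt_sigma = 55, rt_tau = 0,
                            trend_slope = 0, cov_trend = 0,
                            osc_amplitude = 0, osc_freq = 0.063,
                            osc_phase = 0,
                            p_miss = 0.05, p_commission = 0.01,
                            seed = 1L) {
  if (rt_mu <= 0) stop("rt_mu must be > 0", call. = FALSE)
  if (rt_sigma < 0 || rt_tau < 0)
    stop("rt_sigma and rt_tau must be >= 0", call. = FALSE)
  assert_prob(p_miss, "p_miss"); assert_prob(p_commission, "p_commission")
  if (osc_freq <= 0)
    stop("osc_freq must be > 0", call. = FALSE)
  structure(list(
    participant_id = participant_id, group = group, age = age, sex = sex,
    rt_mu = rt_mu, rt_sigma = rt_sigma, rt_tau = rt_tau,
    trend_slope = trend_slope, cov_trend = cov_trend,
    osc_amplitude = osc_amplitude, osc_freq = osc_freq,
    osc_phase = osc_phase, p_miss = p_miss, p_commission = p_commission,
    seed = as.integer(seed)
  ), class = "participant_sim")
}

#' Simulate one CPT session
#'
#' Applies the generative model of [participant_sim()] to a trial sequence,
#' yielding one trial record per trial: onset time (s), stimulus letter,
#' target flag and a response latency in ms (NA for no response). Hit
#' latencies are measured from the onset of the "K" completing the target
#' pair and may exceed the stimulus-onset asynchrony, up to
#' `response_window` (late responses that spill into the next trial's
#' window).
#'
#' @param sequence output of [generate_trial_sequence()].
#' @param sim a [participant_sim()].
#' @param spec the [task_spec()] the sequence was generated from.
#' @param response_window latest admissible latency after target onset, ms.
#' @param rt_floor minimum plausible motor latency, ms; draws below it (or
#'   above `response_window`) are resampled.
#' @param n_cov_blocks number of analysis blocks over which the noise SD
#'   drifts (matches the 8-block CoV analysis).
#' @return A data.frame of trial records: `participant_id`, `trial_index`,
#'   `onset_time` (s), `stimulus`, `is_target`, `rt` (ms or NA).
#' @export
simulate_session <- function(sequence, sim, spec = task_spec(),
                             response_window = 1135, rt_floor = 100,
                             n_cov_blocks = 8L) {
  stopifnot(inherits(sim, "participant_sim"), inherits(spec, "task_spec"))
  nyq <- 0.5 / spec$soa_s
  if (sim$osc_freq > nyq)
    stop(sprintf("osc_freq must be <= 0.5/soa_s = %.4f Hz", nyq),
         call. = FALSE)
  n <- nrow(sequence)
  idx <- sequence$trial_index
  onset <- idx * spec$soa_s
  old <- local_seed(sim$seed)
  on.exit(restore_seed(old), add = TRUE)

  block <- idx %/% (spec$n_trials %/% n_cov_blocks) + 1L
  block_c <- block - (n_cov_blocks + 1) / 2
  sd_trial <- pmax(sim$rt_sigma + sim$cov_trend * sim$rt_mu * block_c, 0)

  rt <- rep(NA_real_, n)
  tgt <- which(sequence$is_target)
  if (length(tgt)) {
    missed <- stats::runif(length(tgt)) < sim$p_miss
    base <- sim$rt_mu + sim$trend_slope * idx[tgt] +
      sim$osc_amplitude * sin(2 * pi * sim$osc_freq * onset[tgt] +
                                sim$osc_phase)
    noise <- stats::rnorm(length(tgt), 0, sd_trial[tgt]) +
      (if (sim$rt_tau > 0) stats::rexp(length(tgt), 1 / sim$rt_tau) else 0)
    val <- base + noise
    for (iter in seq_len(1000L)) {
      bad <- which(!missed & (val < rt_floor | val > response_window))
      if (!length(bad)) break
      val[bad] <- base[bad] + stats::rnorm(length(bad), 0, sd_trial[tgt][bad]) +
        (if (sim$rt_tau > 0) stats::rexp(length(bad), 1 / sim$rt_tau) else 0)
    }
    val <- pmin(pmax(val, rt_floor), response_window)  # safety clamp
    rt[tgt[!missed]] <- val[!missed]
  }
  ntg <- which(!sequence$is_target)
  if (length(ntg) && sim$p_commission > 0) {
    resp <- stats::runif(length(ntg)) < sim$p_commission
    rt[ntg[resp]] <- stats::runif(sum(resp), rt_floor, spec$soa)
  }
  data.frame(participant_id = sim$participant_id, trial_index = idx,
             onset_time = onset, stimulus = sequence$stimulus,
             is_target = sequence$is_target, rt = rt,
             stringsAsFactors = FALSE)
}

#' Group specification for cohort simulation
#'
#' Each numeric parameter is either a fixed value (length 1) or a
#' `c(mean, sd)` pair sampled per participant from a (truncated) normal.
#' `osc_phase = NA` draws phase uniformly on `[0, 2*pi)` per participant.
#' Defaults describe a healthy-control-like group on the Vigil CPT:
#' baseline RT around 500 ms with ~50 ms between-subject spread, within-
#' subject noise ~55 ms plus a modest exponential tail, ~5% misses, ~1%
#' commissions, no oscillation and no time-on-task trend.
#'
#' @param name group label.
#' @param n number of participants.
#' @param age `c(mean, sd)` in years, truncated to \[18, 65\].
#' @param p_female probability of sex "F".
#' @inheritParams participant_sim
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n,
                       rt_mu = c(500, 50), rt_sigma = c(55, 10),
                       rt_tau = c(50, 20), trend_slope = 0,
                       cov_trend = c(0, 0.002),
                       osc_amplitude = 0, osc_freq = 0.063, osc_phase = NA,
                       p_miss = 0.05, p_commission = 0.01,
                       age = c(40, 12), p_female = 0.5) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L)
    stop(sprintf("group '%s' is empty", name), call. = FALSE)
  structure(list(name = name, n = n, rt_mu = rt_mu, rt_sigma = rt_sigma,
                 rt_tau = rt_tau, trend_slope = trend_slope,
                 cov_trend = cov_trend, osc_amplitude = osc_amplitude,
                 osc_freq = osc_freq, osc_phase = osc_phase,
                 p_miss = p_miss, p_commission = p_commission,
                 age = age, p_female = p_female),
            class = "group_spec")
}

draw_param <- function(par, lower = -Inf, upper = Inf) {
  if (length(par) == 1L) return(min(max(par, lower), upper))
  x <- stats::rnorm(1L, par[1L], par[2L])
  for (i in seq_len(100L)) {
    if (x >= lower && x <= upper) break
    x <- stats::rnorm(1L, par[1L], par[2L])
  }
  min(max(x, lower), upper)
}

#' Simulate a multi-group cohort
#'
#' Draws per-participant parameters from each group's distributions (using
#' reproducible per-participant substreams derived from `seed`), simulates
#' every session on a common trial sequence, and returns a tidy trial table
#' plus a covariate table.
#'
#' @param groups list of [group_spec()] objects (at least one; at least two
#'   for any group-comparison analysis).
#' @param spec a [task_spec()].
#' @param seed master seed; identical seeds give identical cohorts.
#' @param shared_sequence if TRUE (default) all participants see the same
#'   letter sequence, as with a fixed instrument; otherwise each participant
#'   gets an independently generated sequence.
#' @param response_window,rt_floor passed to [simulate_session()].
#' @return A list with class `cpt_cohort`: `trials` (columns
#'   `participant_id, group, age, sex, trial_index, onset_time_s, stimulus,
#'   is_target, rt_ms`), `covariates` (`participant_id, group, age, sex`),
#'   `params` (the drawn per-participant simulation parameters), and `spec`.
#' @examples
#' coh <- generate_cohort(list(group_spec("HC", 3), group_spec("BPd", 3)),
#'                        seed = 42)
#' nrow(coh$trials)  # 6 * 480
#' @export
generate_cohort <- function(groups, spec = task_spec(), seed = 1L,
                            shared_sequence = TRUE,
                            response_window = 1135, rt_floor = 100) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, TRUE, "group_spec")))
  n_total <- sum(vapply(groups, function(g) g$n, 1L))
  seeds <- derive_seeds(seed, n_total + 1L)
  seq_shared <- if (shared_sequence)
    generate_trial_sequence(spec, seed = seeds[n_total + 1L])

  trials <- vector("list", n_total)
  params <- vector("list", n_total)
  cov <- vector("list", n_total)
  k <- 0L
  for (g in groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1L
      sub <- seeds[k]
      old <- local_seed(sub)
      sim <- participant_sim(
        participant_id = sprintf("%s_%03d", g$name, i), group = g$name,
        age = round(draw_param(g$age, 18, 65)),
        sex = if (stats::runif(1) < g$p_female) "F" else "M",
        rt_mu = draw_param(g$rt_mu, lower = 200),
        rt_sigma = draw_param(g$rt_sigma, lower = 5),
        rt_tau = draw_param(g$rt_tau, lower = 0),
        trend_slope = draw_param(g$trend_slope),
        cov_trend = draw_param(g$cov_trend),
        osc_amplitude = draw_param(g$osc_amplitude, lower = 0),
        osc_freq = draw_param(g$osc_freq, lower = 1e-4,
                              upper = 0.5 / spec$soa_s),
        osc_phase = if (is.na(g$osc_phase[1L]))
          stats::runif(1, 0, 2 * pi) else draw_param(g$osc_phase),
        p_miss = g$p_miss, p_commission = g$p_commission,
        seed = sub + 1L)
      restore_seed(old)
      sq <- if (shared_sequence) seq_shared else
        generate_trial_sequence(spec, seed = sub + 2L)
      tr <- simulate_session(sq, sim, spec,
                             response_window = response_window,
                             rt_floor = rt_floor)
      tr$group <- g$name; tr$age <- sim$age; tr$sex <- sim$sex
      trials[[k]] <- tr
      params[[k]] <- sim
      cov[[k]] <- data.frame(participant_id = sim$participant_id,
                             group = g$name, age = sim$age, sex = sim$sex,
                             stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  trials <- data.frame(participant_id = trials$participant_id,
                       group = trials$group, age = trials$age,
                       sex = trials$sex, trial_index = trials$trial_index,
                       onset_time_s = trials$onset_time,
                       stimulus = trials$stimulus,
                       is_target = trials$is_target, rt_ms = trials$rt,
                       stringsAsFactors = FALSE)
  structure(list(trials = trials, covariates = do.call(rbind, cov),
                 params = params, spec = spec, seed = as.integer(seed)),
            class = "cpt_cohort")
}

#' @export
print.cpt_cohort <- function(x, ...) {
  cat(sprintf("CPT cohort: %d participants (%s), %d trial records\n",
              nrow(x$covariates),
              paste(sprintf("%s n=%d", names(table(x$covariates$group)),
                            as.integer(table(x$covariates$group))),
                    collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}
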