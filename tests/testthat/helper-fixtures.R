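# Fixtures are built in code; nothing is read from disk.

# Minimal hand-specified trial records: targets at the given 0-based trial
# indices, with the given response latencies (NA = no response) attached to
# the trial carrying them.
toy_records <- function(n_trials = 10, target_at = c(3, 7),
                        rt = setNames(numeric(0), character(0)),
                        soa_s = 0.985) {
  idx <- 0:(n_trials - 1)
  stim <- rep("B", n_trials)
  stim[target_at + 1] <- "K"   # 0-based trial index -> 1-based position
  stim[target_at] <- "A"
  r <- rep(NA_real_, n_trials)
  if (length(rt)) r[as.integer(names(rt)) + 1] <- unname(rt)
  data.frame(participant_id = "toy", trial_index = idx,
             onset_time = idx * soa_s, stimulus = stim,
             is_target = idx %in% target_at, rt = r,
             stringsAsFactors = FALSE)
}

# A session_result with a prescribed hit-RT series (for CoV unit tests).
toy_session <- function(rts, trial_index = seq_along(rts) - 1,
                        id = "toy", soa_s = 0.985) {
  structure(list(
    participant_id = id,
    counts = list(hits = length(rts), misses = 0, commissions = 0,
                  correct_rejections = 0),
    rt_series = data.frame(trial_index = trial_index,
                           onset_time = trial_index * soa_s, rt = rts),
    n_targets = length(rts), accuracy = 1, min_accuracy = 0.6,
    passed_filter = TRUE), class = "session_result")
}

# Fast noiseless/noisy simulated session for one participant.
quick_session <- function(seed = 1, ...) {
  spec <- task_spec()
  sq <- generate_trial_sequence(spec, seed = seed)
  simulate_session(sq, participant_sim(seed = seed, ...), spec)
}

# Session with exactly n_hits responded targets (rest silenced).
make_session_with_hits <- function(n_hits, id = "P") {
  spec <- task_spec()
  sq <- generate_trial_sequence(spec, seed = 41)
  trl <- simulate_session(sq, participant_sim(participant_id = id,
                                              p_miss = 0, p_commission = 0,
                                              seed = 41), spec)
  tgt <- which(trl$is_target)
  if (n_hits < 100) trl$rt[tgt[seq_len(100 - n_hits)]] <- NA
  classify_responses(trl)
}

# Two-group cohort -> filtered sessions + covariates + CoV table.
quick_cov_table <- function(seed, groups) {
  coh <- generate_cohort(groups, seed = seed)
  filt <- apply_accuracy_filter(classify_cohort(coh$trials))
  list(cohort = coh, filtered = filt,
       table = build_cov_table(filt$retained, coh$covariates))
}
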