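#' Vigil CPT task geometry
#'
#' Describes the structure of the continuous performance task: a stream of
#' letter trials in which the target is an "A" immediately followed by a "K".
#' Defaults encode the Vigil CPT: 480 trials of 85 ms stimulus + 900 ms
#' interstimulus interval (stimulus-onset asynchrony 985 ms), 100 targets
#' placed 25 per placement block of 120 trials.
#'
#' @param n_trials total number of trials.
#' @param stim_duration stimulus duration, ms.
#' @param isi interstimulus interval, ms.
#' @param n_targets number of A-then-K target pairs; the target trial proper
#'   is the "K" completing the pair.
#' @param n_placement_blocks number of equal blocks over which targets are
#'   balanced.
#'
#' @return An object of class `task_spec`: a list with the fields above plus
#'   `soa` (= `stim_duration + isi`, ms) and `soa_s` (seconds).
#' @examples
#' spec <- task_spec()
#' spec$soa      # 985
#' @export
task_spec <- function(n_trials = 480L, stim_duration = 85, isi = 900,
                      n_targets = 100L, n_placement_blocks = 4L) {
  n_trials <- as.integer(n_trials)
  n_targets <- as.integer(n_targets)
  n_placement_blocks <- as.integer(n_placement_blocks)
  if (n_trials <= 0L || n_placement_blocks <= 0L)
    stop("n_trials and n_placement_blocks must be positive", call. = FALSE)
  if (n_targets < 0L)
    stop("n_targets must be non-negative", call. = FALSE)
  if (n_trials %% n_placement_blocks != 0L)
    stop("n_trials must be divisible by n_placement_blocks", call. = FALSE)
  if (n_targets %% n_placement_blocks != 0L)
    stop("n_targets must be divisible by n_placement_blocks", call. = FALSE)
  if (stim_duration <= 0 || isi < 0)
    stop("stim_duration must be > 0 and isi >= 0", call. = FALSE)
  block_len <- n_trials %/% n_placement_blocks
  per_block <- n_targets %/% n_placement_blocks
  # each pair needs 2 trials and pairs cannot share trials; a K must fit
  # inside the block, so starts live in 1..(block_len - 1) with gap >= 2
  if (per_block > 0L && (2L * per_block) > block_len)
    stop("infeasible target placement: too many targets for block length",
         call. = FALSE)
  structure(list(
    n_trials = n_trials, stim_duration = stim_duration, isi = isi,
    n_targets = n_targets, n_placement_blocks = n_placement_blocks,
    soa = stim_duration + isi, soa_s = (stim_duration + isi) / 1000
  ), class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "Vigil-style CPT: %d trials (%g ms stimulus + %g ms ISI, SOA %g ms), %d 'A->K' targets (%d per block of %d trials)\n",
    x$n_trials, x$stim_duration, x$isi, x$soa, x$n_targets,
    x$n_targets %/% x$n_placement_blocks, x$n_trials %/% x$n_placement_blocks))
  invisible(x)
}

# Uniformly sample k sorted start positions from 1..m with pairwise gaps >= 2
# (so A/K pairs never overlap), via the standard combinatorial bijection
# y_i = x_i - 2*(i-1).
sample_pair_starts <- function(k, m) {
  if (k == 0L) return(integer(0))
  y <- sort(sample.int(m - 2L * (k - 1L), k))
  y + 2L * (seq_len(k) - 1L)
}

#' Generate a Vigil-style trial sequence
#'
#' Places `n_targets` "A"-then-"K" pairs semi-randomly: targets are balanced
#' across placement blocks (25 per 120-trial block with defaults), pairs
#' never overlap, and filler letters are drawn uniformly from the alphabet
#' with rejection of any draw that would create an accidental "A->K" bigram,
#' so the emitted sequence contains exactly `n_targets` such bigrams.
#'
#' @param spec a [task_spec()].
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return A data.frame with columns `trial_index` (0-based), `stimulus`
#'   (single letter) and `is_target` (TRUE on the "K" completing a pair).
#' @examples
#' seq1 <- generate_trial_sequence(task_spec(), seed = 1)
#' sum(seq1$is_target)  # 100
#' @export
generate_trial_sequence <- function(spec = task_spec(), seed = 1L) {
  stopifnot(inherits(spec, "task_spec"))
  n <- spec$n_trials
  block_len <- n %/% spec$n_placement_blocks
  per_block <- spec$n_targets %/% spec$n_placement_blocks
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  stim <- character(n)
  is_target <- logical(n)
  for (b in seq_len(spec$n_placement_blocks)) {
    offset <- (b - 1L) * block_len
    starts <- offset + sample_pair_starts(per_block, block_len - 1L)
    stim[starts] <- "A"
    stim[starts + 1L] <- "K"
    is_target[starts + 1L] <- TRUE
  }

  pair_pos <- which(stim != "")              # trials already fixed by a pair
  free <- setdiff(seq_len(n), pair_pos)
  scheduled_K <- which(is_target)
  for (i in free) {
    repeat {
      letter <- sample(LETTERS, 1L)
      # reject a "K" right after any "A", and an "A" right before a
      # scheduled "K" -- keeps the A->K bigram count exact
      if (letter == "K" && i > 1L && stim[i - 1L] == "A") next
      if (letter == "A" && (i + 1L) %in% scheduled_K) next
      # an "A" right before a free trial is fine: the later draw at i+1
      # will reject "K"; an "A" before an already-drawn letter needs a check
      if (letter == "A" && i < n && stim[i + 1L] == "K" &&
          !is_target[i + 1L]) next
      break
    }
    stim[i] <- letter
  }
  data.frame(trial_index = 0:(n - 1L), stimulus = stim,
             is_target = is_target, stringsAsFactors = FALSE)
}
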