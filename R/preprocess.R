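#' Classify CPT responses under an extended response window
#'
#' Applies signal-detection-style categorization to a single participant's
#' trial records: hits (a response after the completed "A->K" target
#' sequence), misses, commission errors (a response after a non-target
#' trial) and correct rejections. The response window is extended beyond the
#' stimulus-onset asynchrony (985 ms) to 1135 ms so that very slow responses
#' — attentional lapses landing within the first 150 ms of the next trial —
#' still count as hits of the eliciting target. A response recorded on a
#' non-target trial at a latency of at most `response_window - soa` ms is
#' attributed to the immediately preceding target if and only if that target
#' has no response of its own; each physical response is attributed to at
#' most one trial. RTs enter the series only for hits, measured from the
#' onset of the "K".
#'
#' @param records trial records for one participant (one row per trial,
#'   sorted by `trial_index`), as produced by [simulate_session()] or read
#'   from a trial log; columns `trial_index`, `onset_time` (s),
#'   `is_target`, `rt` (ms, NA = no response).
#' @param response_window admissible latency after target onset, ms.
#' @param soa stimulus-onset asynchrony, ms.
#' @param min_accuracy stored threshold used by [apply_accuracy_filter()].
#' @return An object of class `session_result`: participant id, the four
#'   response counts, `accuracy` (hits / n targets), `passed_filter`, and
#'   `rt_series` — a data.frame of hit onset times (s) and RTs (ms) in
#'   session order, plus the hit trial indices.
#' @examples
#' spec <- task_spec()
#' seqs <- generate_trial_sequence(spec, seed = 7)
#' trl <- simulate_session(seqs, participant_sim(seed = 7), spec)
#' classify_responses(trl)
#' @export
classify_responses <- function(records, response_window = 1135, soa = 985,
                               min_accuracy = 0.60) {
  cols <- c("trial_index", "onset_time", "is_target", "rt")
  if ("rt_ms" %in% names(records) && !"rt" %in% names(records))
    records$rt <- records$rt_ms
  if ("onset_time_s" %in% names(records) && !"onset_time" %in% names(records))
    records$onset_time <- records$onset_time_s
  if (!all(cols %in% names(records)))
    stop("records must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  if (response_window < soa)
    stop("response_window must be >= soa", call. = FALSE)
  if (is.unsorted(records$trial_index, strictly = TRUE))
    stop("trial records must be sorted by trial_index without duplicates",
         call. = FALSE)
  n <- nrow(records)
  overlap <- response_window - soa
  is_tgt <- records$is_target
  rt <- records$rt

  hit <- logical(n)         # on target rows
  commission <- logical(n)  # on non-target rows
  hit_rt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(rt[i])) next
    if (is_tgt[i]) {
      if (rt[i] > 0 && rt[i] <= response_window) {
        hit[i] <- TRUE
        hit_rt[i] <- rt[i]
      }
    } else {
      # late lapse attribution: response lands in the overlap zone right
      # after an unanswered target
      if (i > 1L && is_tgt[i - 1L] && !hit[i - 1L] &&
          !is.na(rt[i]) && rt[i] <= overlap) {
        hit[i - 1L] <- TRUE
        hit_rt[i - 1L] <- soa + rt[i]
      } else {
        commission[i] <- TRUE
      }
    }
  }
  n_targets <- sum(is_tgt)
  hits <- sum(hit)
  counts <- list(hits = hits, misses = n_targets - hits,
                 commissions = sum(commission),
                 correct_rejections = sum(!is_tgt) - sum(commission))
  accuracy <- if (n_targets > 0) hits / n_targets else NA_real_
  keep <- which(hit)
  structure(list(
    participant_id = as.character(records$participant_id[1L] %||% NA),
    counts = counts,
    rt_series = data.frame(trial_index = records$trial_index[keep],
                           onset_time = records$onset_time[keep],
                           rt = hit_rt[keep]),
    n_targets = n_targets,
    accuracy = accuracy,
    min_accuracy = min_accuracy,
    passed_filter = !is.na(accuracy) &&
      hits >= ceiling(min_accuracy * n_targets)
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "Session %s: %d hits / %d misses / %d commissions / %d correct rejections (accuracy %.1f%%, filter %s)\n",
    x$participant_id, x$counts$hits, x$counts$misses, x$counts$commissions,
    x$counts$correct_rejections, 100 * x$accuracy,
    if (x$passed_filter) "passed" else "FAILED"))
  invisible(x)
}

#' Classify every session in a cohort trial table
#'
#' @param trials tidy trial table (multiple participants), schema of
#'   `generate_cohort()$trials`.
#' @inheritParams classify_responses
#' @return Named list of `session_result`, one per participant, in first-
#'   appearance order.
#' @export
classify_cohort <- function(trials, response_window = 1135, soa = 985,
                            min_accuracy = 0.60) {
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    classify_responses(trials[trials$participant_id == id, , drop = FALSE],
                       response_window = response_window, soa = soa,
                       min_accuracy = min_accuracy)
  })
  names(out) <- ids
  out
}

#' Filter sessions by minimum accuracy
#'
#' Retains sessions with at least `min_accuracy * n_targets` hits (60 of 100
#' with defaults) — low-accuracy sessions leave too few correct-response RTs
#' for a stable spectral estimate.
#'
#' @param sessions list of `session_result` objects.
#' @param min_accuracy required proportion of targets hit.
#' @return A list with `retained` (list of sessions) and `report`, a
#'   data.frame of all sessions with accuracy, retention flag and an
#'   exclusion reason for dropped ones.
#' @export
apply_accuracy_filter <- function(sessions, min_accuracy = 0.60) {
  if (length(sessions) == 0L) {
    warning("no sessions supplied to accuracy filter", call. = FALSE)
    return(list(retained = list(),
                report = data.frame(participant_id = character(0),
                                    hits = integer(0), n_targets = integer(0),
                                    accuracy = numeric(0),
                                    retained = logical(0),
                                    reason = character(0))))
  }
  keep <- vapply(sessions, function(s)
    s$counts$hits >= ceiling(min_accuracy * s$n_targets), TRUE)
  report <- data.frame(
    participant_id = vapply(sessions, `[[`, "", "participant_id"),
    hits = vapply(sessions, function(s) s$counts$hits, 1L),
    n_targets = vapply(sessions, `[[`, 1L, "n_targets"),
    accuracy = vapply(sessions, `[[`, 1, "accuracy"),
    retained = keep,
    reason = ifelse(keep, "",
                    sprintf("accuracy below %.0f%% threshold",
                            100 * min_accuracy)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(retained = sessions[keep], report = report)
}

#' Summarize classified sessions as a table
#'
#' @param sessions list of `session_result`.
#' @return data.frame, one row per participant (counts, accuracy, filter
#'   flag) — the schema written by the `preprocess` pipeline stage.
#' @export
session_summary <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id,
               hits = s$counts$hits, misses = s$counts$misses,
               commissions = s$counts$commissions,
               correct_rejections = s$counts$correct_rejections,
               accuracy = s$accuracy, passed_filter = s$passed_filter,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
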