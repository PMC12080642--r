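# Plain-text tabular interchange: every pipeline stage reads and writes
# tab-separated text so any stage can be run standalone on external data.
# The trial-log schema is the contract: participant_id, group, age, sex,
# trial_index, onset_time_s, stimulus, is_target, rt_ms (empty = no
# response).

#' Write / read a trial log
#'
#' @param trials tidy trial table (`generate_cohort()$trials` schema).
#' @param path file path.
#' @return `read_trial_log` returns the trial data.frame with `is_target`
#'   logical and `rt_ms` numeric (NA for no response).
#' @export
write_trial_log <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  tr <- utils::read.delim(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "onset_time_s", "stimulus",
            "is_target", "rt_ms")
  if (!all(need %in% names(tr)))
    stop("trial log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tr$is_target <- as.logical(tr$is_target)
  tr$rt_ms <- as.numeric(tr$rt_ms)
  tr
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a declarative run configuration (JSON)
#'
#' @param path JSON file; keys as in [default_config()].
#' @return A config list (class `run_config`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  merge_config(default_config(), cfg)
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

merge_config <- function(base, override) {
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  # JSON has no NULL scalar: empty path fields come back as empty lists
  for (nm in c("trial_log", "covariates"))
    if (length(base[[nm]]) == 0L || identical(base[[nm]], ""))
      base[nm] <- list(NULL)
  class(base) <- "run_config"
  base
}
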