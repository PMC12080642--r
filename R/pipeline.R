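#' Default run configuration
#'
#' Every analysis parameter defaults to the task's stated value: 1135 ms
#' response window, 60% accuracy threshold, 8 blocks of 60 trials for the
#' CoV analysis, 44 interior spline knots, pointwise alpha 0.05 and a
#' Bonferroni family of 6 pairwise comparisons. The default simulation block
#' describes a two-group demonstration cohort (controls vs a "patient"
#' group carrying an infraslow oscillation).
#'
#' @return A config list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    trial_log = NULL,            # path to an existing trial log, or NULL
    covariates = NULL,
    simulate = list(
      groups = list(
        list(name = "HC", n = 20),
        list(name = "PAT", n = 20, osc_amplitude = c(75, 10))),
      shared_sequence = TRUE),
    stages = c("simulate", "preprocess", "vigilance", "spectrum", "fda"),
    n_trials = 480L, stim_duration = 85, isi = 900, n_targets = 100L,
    n_placement_blocks = 4L,
    response_window = 1135, min_accuracy = 0.60,
    n_blocks = 8L, block_size = 60L, min_rt_per_block = 3L,
    reference_group = "HC",
    oversampling = 1, detrend = TRUE,
    knots = 44L, n_eval = 200L, alpha = 0.05, bonferroni_m = 6L,
    seed = 1L, out_dir = "vigilcpt_run"
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks ranges and cross-parameter consistency (the response window must
#' cover the stimulus-onset asynchrony; blocks must tile the task; inputs
#' must exist) without running anything.
#'
#' @param config a `run_config` list.
#' @return `character(0)` when valid, otherwise the violations found.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v[[length(v) + 1L]] <<- msg
  soa <- config$stim_duration + config$isi
  chk(is.numeric(config$min_accuracy) && config$min_accuracy >= 0 &&
        config$min_accuracy <= 1, "min_accuracy must be in [0, 1]")
  chk(config$response_window >= soa,
      sprintf("response_window (%s) must be >= soa (%s)",
              config$response_window, soa))
  chk(config$n_trials %% config$n_placement_blocks == 0,
      "n_trials must be divisible by n_placement_blocks")
  chk(config$n_targets %% config$n_placement_blocks == 0,
      "n_targets must be divisible by n_placement_blocks")
  chk(config$n_blocks * config$block_size == config$n_trials,
      sprintf("n_blocks (%s) x block_size (%s) must equal n_trials (%s)",
              config$n_blocks, config$block_size, config$n_trials))
  chk(is.numeric(config$seed) && length(config$seed) == 1L &&
        !is.na(config$seed) && config$seed >= 0,
      "seed must be a non-negative integer")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$oversampling >= 1, "oversampling must be >= 1")
  chk(config$knots >= 0, "knots must be >= 0")
  chk(config$bonferroni_m >= 1, "bonferroni_m must be >= 1")
  if (length(config$trial_log) == 1L && nzchar(config$trial_log))
    chk(file.exists(config$trial_log),
        sprintf("trial_log '%s' does not exist", config$trial_log))
  if (is.null(config$trial_log) && "simulate" %in% config$stages)
    chk(length(config$simulate$groups) >= 1L,
        "simulation config must define at least one group")
  v
}

config_groups <- function(config) {
  lapply(config$simulate$groups, function(g) {
    args <- g[setdiff(names(g), character(0))]
    do.call(group_spec, args)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or ingest a trial log),
#' preprocess, vigilance, spectrum, fda — writing each stage's artifacts as
#' tab-separated text under `config$out_dir` plus a JSON run manifest
#' (config snapshot, seed, package version, per-stage row counts,
#' exclusions, file checksums). Identical config + seed give identical
#' outputs.
#'
#' @param config a `run_config`; see [default_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "vigilcpt",
                   version = as.character(utils::packageVersion("vigilcpt")),
                   seed = config$seed, config = unclass(config),
                   stages = list(), complete = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    write_tsv(x, p)
    files[[length(files) + 1L]] <<- p
    p
  }
  finish <- function() {
    manifest$files <- data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)), row.names = NULL)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  spec <- task_spec(config$n_trials, config$stim_duration, config$isi,
                    config$n_targets, config$n_placement_blocks)

  # --- simulate / ingest ---------------------------------------------------
  trials <- NULL; covs <- NULL
  if (!is.null(config$trial_log)) {
    trials <- read_trial_log(config$trial_log)
    covs <- if (!is.null(config$covariates))
      utils::read.delim(config$covariates, stringsAsFactors = FALSE)
    else unique(trials[, c("participant_id", "group", "age", "sex")])
    manifest$stages$ingest <- list(status = "ok", n_trials = nrow(trials))
  } else {
    run_stage("simulate", function() {
      coh <- generate_cohort(config_groups(config), spec,
                             seed = config$seed,
                             shared_sequence = isTRUE(
                               config$simulate$shared_sequence),
                             response_window = config$response_window)
      emit(coh$trials, "trials.tsv")
      emit(coh$covariates, "covariates.tsv")
      trials <<- coh$trials; covs <<- coh$covariates
      manifest$stages$simulate <<- list(
        status = "ok", n_participants = nrow(coh$covariates),
        n_trials = nrow(coh$trials))
    })
  }
  if (!any(c("preprocess", "vigilance", "spectrum", "fda") %in%
           config$stages))
    return(invisible(finish()))

  # --- preprocess ----------------------------------------------------------
  sessions <- NULL; filtered <- NULL
  run_stage("preprocess", function() {
    sessions <<- classify_cohort(trials,
                                 response_window = config$response_window,
                                 soa = spec$soa,
                                 min_accuracy = config$min_accuracy)
    filtered <<- apply_accuracy_filter(sessions, config$min_accuracy)
    emit(session_summary(sessions), "sessions.tsv")
    emit(filtered$report, "exclusions.tsv")
    manifest$stages$preprocess <<- list(
      status = "ok", n_sessions = length(sessions),
      n_retained = length(filtered$retained),
      excluded = filtered$report$participant_id[!filtered$report$retained])
  })

  # --- vigilance -----------------------------------------------------------
  if ("vigilance" %in% config$stages) run_stage("vigilance", function() {
    tab <- build_cov_table(filtered$retained, covs,
                           n_blocks = config$n_blocks,
                           block_size = config$block_size,
                           min_rt_per_block = config$min_rt_per_block)
    emit(tab, "cov_blocks.tsv")
    ref <- if (config$reference_group %in% tab$group)
      config$reference_group else sort(unique(tab$group))[1L]
    fitv <- fit_vigilance_model(tab, reference_group = ref)
    emit(fitv$fixed, "vigilance_fixed.tsv")
    emit(fitv$omnibus, "vigilance_omnibus.tsv")
    emit(fitv$slopes, "vigilance_slopes.tsv")
    emit(fitv$intercept_contrasts, "vigilance_contrasts_intercept.tsv")
    emit(fitv$slope_contrasts, "vigilance_contrasts_slope.tsv")
    emit(data.frame(metric = names(fitv$r2), value = fitv$r2),
         "vigilance_r2.tsv")
    manifest$stages$vigilance <<- list(
      status = "ok", n_rows = nrow(tab), singular = fitv$singular,
      uncorrelated = fitv$uncorrelated)
  })

  # --- spectrum ------------------------------------------------------------
  pgs <- NULL
  if (any(c("spectrum", "fda") %in% config$stages))
    run_stage("spectrum", function() {
      pgs <<- lapply(filtered$retained, function(s)
        lomb_scargle(as_rt_series(s), oversampling = config$oversampling,
                     detrend = isTRUE(config$detrend)))
      long <- do.call(rbind, lapply(pgs, function(p)
        data.frame(participant_id = p$participant_id,
                   frequency_hz = p$frequencies, power = p$power)))
      emit(long, "periodograms.tsv")
      manifest$stages$spectrum <<- list(status = "ok",
                                        n_participants = length(pgs))
    })

  # --- fda -----------------------------------------------------------------
  if ("fda" %in% config$stages) run_stage("fda", function() {
    sm <- suppressWarnings(
      smooth_spectra(pgs, n_interior_knots = config$knots,
                     n_eval = config$n_eval))
    long <- data.frame(
      participant_id = rep(rownames(sm$power), each = ncol(sm$power)),
      frequency_hz = rep(sm$eval_frequencies, times = nrow(sm$power)),
      power = as.vector(t(sm$power)))
    emit(long, "smoothed_spectra.tsv")
    ft <- pointwise_group_ftest(sm, covs, alpha = config$alpha)
    emit(data.frame(frequency_hz = ft$frequencies, F = ft$F,
                    critical = ft$critical), "ftest.tsv")
    emit(ft$bands, "bands.tsv")
    summ <- summarize_band(ft, sm, covs)
    emit(summ$group_power, "band_power.tsv")
    grs <- sort(unique(covs$group[covs$participant_id %in%
                                    rownames(sm$power)]))
    if (length(grs) >= 2L && nrow(ft$bands) > 0L) {
      pairs <- utils::combn(grs, 2L, simplify = FALSE)
      tts <- do.call(rbind, lapply(pairs, function(pr) {
        tt <- pairwise_pointwise_ttest(
          sm, pr, covs,
          band = c(ft$bands$f_lo[1L], ft$bands$f_hi[1L]),
          alpha = config$alpha, n_comparisons = config$bonferroni_m)
        cbind(pair = paste(pr, collapse = "-"), tt)
      }))
      emit(tts, "ttests.tsv")
    }
    manifest$stages$fda <<- list(status = "ok", n_bands = nrow(ft$bands))
  })

  manifest$complete <- TRUE
  invisible(finish())
}
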