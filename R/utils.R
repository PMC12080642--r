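# Seed handling: functions that consume randomness do so in a local stream,
# restoring the caller's .Random.seed afterwards so simulation code composes
# deterministically.
local_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L)
    stop("seed must be a non-negative integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Master-seed -> per-unit substreams: a fixed-increment counter scheme keeps
# streams distinct and reproducible without consuming the master stream.
derive_seeds <- function(master_seed, n) {
  master_seed <- as.integer(master_seed)
  old <- local_seed(master_seed)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max - 2L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
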