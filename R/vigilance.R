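#' Block-wise coefficient of variation of RT
#'
#' Splits the session's trials into `n_blocks` consecutive blocks of
#' `block_size` trials by trial index (8 blocks of 60 over the 480-trial
#' task) and computes, per block, the coefficient of variation of the hit
#' RTs falling in that block: sample SD (n-1 denominator) divided by the
#' mean. Blocks with fewer than `min_rt_per_block` hits emit no row.
#'
#' @param session a `session_result` (should have passed the accuracy
#'   filter).
#' @param n_blocks number of analysis blocks.
#' @param block_size trials per block.
#' @param min_rt_per_block minimum hit count for a block to contribute.
#' @return data.frame rows: `participant_id`, `block` (1-based),
#'   `block_centered` (block minus the mean block index, 4.5 with
#'   defaults), `cov`, `n_rt`.
#' @export
compute_block_cov <- function(session, n_blocks = 8L, block_size = 60L,
                              min_rt_per_block = 3L) {
  stopifnot(inherits(session, "session_result"))
  rs <- session$rt_series
  center <- (n_blocks + 1) / 2
  if (nrow(rs) == 0L)
    return(data.frame(participant_id = character(0), block = integer(0),
                      block_centered = numeric(0), cov = numeric(0),
                      n_rt = integer(0)))
  block <- rs$trial_index %/% block_size + 1L
  out <- lapply(seq_len(n_blocks), function(b) {
    x <- rs$rt[block == b]
    if (length(x) < min_rt_per_block) return(NULL)
    data.frame(participant_id = session$participant_id, block = b,
               block_centered = b - center,
               cov = stats::sd(x) / mean(x), n_rt = length(x),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(participant_id = character(0), block = integer(0),
                      block_centered = numeric(0), cov = numeric(0),
                      n_rt = integer(0))
  rownames(res) <- NULL
  res
}

#' Assemble the participant-by-block CoV table
#'
#' @param sessions list of filtered `session_result` objects.
#' @param covariates data.frame with `participant_id`, `group`, `age`,
#'   `sex`.
#' @inheritParams compute_block_cov
#' @return Long-format data.frame (class `cov_block_table`):
#'   `participant_id, group, age, sex, block, block_centered, cov, n_rt`.
#' @export
build_cov_table <- function(sessions, covariates, n_blocks = 8L,
                            block_size = 60L, min_rt_per_block = 3L) {
  tab <- do.call(rbind, lapply(sessions, compute_block_cov,
                               n_blocks = n_blocks, block_size = block_size,
                               min_rt_per_block = min_rt_per_block))
  tab <- merge(covariates, tab, by = "participant_id", sort = FALSE)
  tab <- tab[order(match(tab$participant_id, covariates$participant_id),
                   tab$block), ]
  rownames(tab) <- NULL
  class(tab) <- c("cov_block_table", "data.frame")
  tab
}

#' Mixed-effects model of the vigilance decrement
#'
#' Fits `cov ~ group * block_centered + age + sex` with a participant-level
#' random intercept and random slope on the centered block index. Group is
#' dummy-coded against `reference_group`. Omnibus F-tests for diagnosis,
#' block and their interaction use Satterthwaite-approximated denominator
#' degrees of freedom; all 6 pairwise group contrasts (at the mean block,
#' i.e. the model intercepts) and the pairwise slope differences are
#' Tukey-adjusted; per-group simple slopes are reported with unadjusted
#' Satterthwaite t-tests. Marginal and conditional R-squared follow the
#' variance-partition definition (fixed / fixed+random+residual).
#'
#' A singular random-effects fit (perfectly correlated or zero-variance
#' intercept/slope) is refitted with uncorrelated random effects and
#' flagged; non-convergence raises an error carrying the optimizer
#' diagnostics.
#'
#' @param table a `cov_block_table` (or compatible data.frame).
#' @param reference_group baseline level for the dummy coding.
#' @param ddf `"satterthwaite"` (default) for full inference, `"none"` to
#'   return estimates only (fast path for simulation studies).
#' @return An object of class `vigilance_fit`: `fixed` (coefficient table),
#'   `omnibus` (F tests), `slopes` (per-group simple slopes),
#'   `intercept_contrasts` and `slope_contrasts` (Tukey-adjusted pairwise
#'   tables), `r2` (marginal, conditional), flags, and the underlying
#'   `merMod` as `$model`.
#' @export
fit_vigilance_model <- function(table, reference_group = "HC",
                                ddf = c("satterthwaite", "none")) {
  ddf <- match.arg(ddf)
  dat <- as.data.frame(table)
  need <- c("participant_id", "group", "age", "sex", "block_centered", "cov")
  if (!all(need %in% names(dat)))
    stop("CoV table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!reference_group %in% dat$group)
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  dat$group <- stats::relevel(factor(dat$group), ref = reference_group)
  dat$sex <- factor(dat$sex)
  k <- nlevels(dat$group)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  per_id <- table(dat$participant_id)
  if (any(tapply(dat$participant_id, dat$group,
                 function(x) length(unique(x))) < 2L))
    stop("each group needs >= 2 participants for identifiable variance ",
         "components", call. = FALSE)
  if (max(per_id) < 2L)
    stop("participants need >= 2 blocks for slope identifiability",
         call. = FALSE)

  has_sex <- nlevels(dat$sex) > 1L
  rhs <- paste("group * block_centered + age",
               if (has_sex) "+ sex" else "")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fml <- stats::as.formula(paste(
    "cov ~", rhs, "+ (block_centered | participant_id)"))
  environment(fml) <- environment()
  fit <- tryCatch(
    lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e), call. = FALSE))
  uncorrelated <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    fml2 <- stats::as.formula(paste(
      "cov ~", rhs, "+ (block_centered || participant_id)"))
    environment(fml2) <- environment()
    fit2 <- tryCatch(lme4::lmer(fml2, data = dat, REML = TRUE,
                                control = ctrl),
                     error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      uncorrelated <- TRUE
    }
  }
  singular <- lme4::isSingular(fit, tol = 1e-4)
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop("mixed model did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)

  beta <- lme4::fixef(fit)
  cn <- names(beta)
  levs <- levels(dat$group)
  grp_cols <- paste0("group", levs[-1L])
  int_cols <- paste0("group", levs[-1L], ":block_centered")
  p <- length(beta)
  unit <- function(name) {
    l <- numeric(p); l[match(name, cn)] <- 1; l
  }

  res <- structure(list(model = fit, reference_group = reference_group,
                        groups = levs, singular = singular,
                        uncorrelated = uncorrelated, ddf = ddf,
                        r2 = r2_mixed(fit)), class = "vigilance_fit")
  res$fixed <- data.frame(term = cn, estimate = beta,
                          se = sqrt(diag(as.matrix(stats::vcov(fit)))),
                          row.names = NULL)
  # group simple slopes as fixed-effect combinations
  slope_l <- lapply(levs, function(g) {
    l <- unit("block_centered")
    if (g != levs[1L]) l <- l + unit(paste0("group", g, ":block_centered"))
    l
  })
  names(slope_l) <- levs
  res$slope_estimates <- vapply(slope_l, function(l) sum(l * beta), 1)

  if (ddf == "none") return(res)

  prep <- satt_prep(fit)
  Lgrp <- t(vapply(grp_cols, unit, numeric(p)))
  Lint <- t(vapply(int_cols, unit, numeric(p)))
  Lblk <- rbind(unit("block_centered"))
  om <- rbind(
    data.frame(effect = "diagnosis", as.data.frame(satt_ftest(prep, Lgrp))),
    data.frame(effect = "block", as.data.frame(satt_ftest(prep, Lblk))),
    data.frame(effect = "diagnosis:block",
               as.data.frame(satt_ftest(prep, Lint))))
  res$omnibus <- om

  res$slopes <- do.call(rbind, lapply(levs, function(g) {
    ct <- satt_contrast(prep, slope_l[[g]])
    data.frame(group = g, slope = ct$estimate, se = ct$se, df = ct$df,
               t = ct$t, p = ct$p, stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  pair_tab <- function(make_l) {
    do.call(rbind, lapply(pairs, function(pr) {
      l <- make_l(pr[1L]) - make_l(pr[2L])
      ct <- satt_contrast(prep, l)
      data.frame(contrast = paste(pr[1L], "-", pr[2L]),
                 estimate = ct$estimate, se = ct$se, df = ct$df, t = ct$t,
                 p_tukey = tukey_p(ct$t, k, ct$df),
                 stringsAsFactors = FALSE)
    }))
  }
  intercept_l <- function(g) {
    l <- unit("(Intercept)")
    if (g != levs[1L]) l <- l + unit(paste0("group", g))
    l
  }
  res$intercept_contrasts <- pair_tab(intercept_l)
  res$slope_contrasts <- pair_tab(function(g) slope_l[[g]])
  res$satt_ok <- prep$grad_ok
  res
}

#' @export
print.vigilance_fit <- function(x, ...) {
  cat("Vigilance-decrement mixed model: cov ~ group * block_centered",
      "+ age + sex + (block_centered | participant)\n")
  cat(sprintf("  groups: %s (reference %s)%s%s\n",
              paste(x$groups, collapse = ", "), x$reference_group,
              if (x$singular) " [singular fit]" else "",
              if (x$uncorrelated) " [uncorrelated random effects]" else ""))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  if (!is.null(x$omnibus)) {
    cat("  omnibus (Satterthwaite df):\n")
    with(x$omnibus, for (i in seq_along(effect))
      cat(sprintf("    %-16s F[%d, %.1f] = %.2f, p = %.4g\n",
                  effect[i], ndf[i], ddf[i], F[i], p[i])))
  }
  invisible(x)
}

# Marginal/conditional R2 by variance partition: fixed-effect variance over
# fixed + (mean) random-effect + residual variance.
r2_mixed <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- stats::var(drop(X %*% lme4::fixef(fit)))
  Z <- lme4::getME(fit, "Z")
  Lam <- lme4::getME(fit, "Lambda")
  s2 <- stats::sigma(fit)^2
  ZL <- Z %*% Lam
  var_r <- s2 * mean(Matrix::rowSums(ZL * ZL))
  tot <- var_f + var_r + s2
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
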