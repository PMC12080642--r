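# Satterthwaite degrees of freedom for linear mixed models fitted with lme4.
#
# The REML deviance is unprofiled in the variance parameters
# varpar = (theta, sigma): theta are the relative Cholesky factors of the
# random-effects covariance and sigma the residual SD. The asymptotic
# covariance of the variance-parameter estimates is A = 2 * H^{-1}, with H
# the Hessian of the unprofiled deviance at the optimum. For a contrast l of
# the fixed effects with variance v(varpar) = l' V(varpar) l, the
# Satterthwaite df is 2 v^2 / (g' A g) where g = dv/dvarpar. Multi-df F
# tests decompose L V L' by its eigenvectors and combine the per-direction
# dfs through the standard sum-of-(nu/(nu-2)) rule.

# Unprofiled REML/ML deviance as a function of varpar = c(theta, sigma).
devfun_vp <- function(varpar, devfun, reml) {
  m <- length(varpar)
  sigma2 <- varpar[m]^2
  theta <- varpar[-m]
  envir <- environment(devfun)
  devfun(theta)                      # updates pp/resp in the devfun closure
  n <- length(envir$resp$y)
  if (reml) n <- n - ncol(envir$pp$X)
  pwrss <- envir$resp$wrss() + envir$pp$sqrL(1)
  ld <- envir$pp$ldL2() + if (reml) envir$pp$ldRX2() else 0
  ld + n * log(2 * pi * sigma2) + pwrss / sigma2
}

# vcov of the fixed effects as a function of varpar.
covbeta_vp <- function(varpar, devfun) {
  m <- length(varpar)
  theta <- varpar[-m]
  envir <- environment(devfun)
  devfun(theta)
  varpar[m]^2 * as.matrix(envir$pp$unsc())
}

# Precompute everything contrast-level tests need from a fitted lmerMod.
satt_prep <- function(fit) {
  reml <- lme4::isREML(fit)
  devfun <- update(fit, devFunOnly = TRUE)
  varpar <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  h <- numDeriv::hessian(function(vp) devfun_vp(vp, devfun, reml), varpar)
  A <- tryCatch(2 * solve(h), error = function(e) NULL)
  grad_ok <- TRUE
  if (is.null(A) || anyNA(A)) {
    # boundary (singular) fits give an ill-conditioned Hessian; fall back to
    # a pseudo-inverse and flag the dfs as approximate
    A <- 2 * MASS::ginv(h)
    grad_ok <- FALSE
  }
  V <- as.matrix(stats::vcov(fit))
  p <- ncol(V)
  J <- numDeriv::jacobian(function(vp)
    as.vector(covbeta_vp(vp, devfun)), varpar)
  list(fit = fit, beta = lme4::fixef(fit), V = V, p = p,
       A = A, J = J, nvp = length(varpar), grad_ok = grad_ok)
}

satt_df <- function(prep, l) {
  v <- drop(t(l) %*% prep$V %*% l)
  g <- vapply(seq_len(prep$nvp), function(k)
    drop(t(l) %*% matrix(prep$J[, k], prep$p, prep$p) %*% l), 1)
  den <- drop(t(g) %*% prep$A %*% g)
  if (!is.finite(den) || den <= 0) return(Inf)
  2 * v^2 / den
}

# t-type test of a single contrast l'beta.
satt_contrast <- function(prep, l, level_names = NULL) {
  est <- drop(t(l) %*% prep$beta)
  se <- sqrt(drop(t(l) %*% prep$V %*% l))
  df <- satt_df(prep, l)
  tval <- est / se
  list(estimate = est, se = se, df = df, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

# F-type test of a q-row contrast matrix L (rows span the hypothesis).
satt_ftest <- function(prep, L) {
  L <- rbind(L)
  VL <- L %*% prep$V %*% t(L)
  e <- eigen(VL, symmetric = TRUE)
  tol <- max(dim(VL)) * .Machine$double.eps * max(abs(e$values))
  pos <- e$values > tol
  q <- sum(pos)
  if (q == 0L) return(list(F = NA_real_, ndf = 0, ddf = NA_real_,
                           p = NA_real_))
  Lb <- drop(L %*% prep$beta)
  Fstat <- drop(t(Lb) %*% solve(VL, Lb)) / q
  # per-eigendirection Satterthwaite dfs
  U <- e$vectors[, pos, drop = FALSE]
  nus <- vapply(seq_len(q), function(i) {
    li <- drop(t(L) %*% U[, i])
    satt_df(prep, li)
  }, 1)
  contrib <- nus / (nus - 2)
  contrib[!is.finite(contrib) | nus <= 2] <- 1  # nu -> Inf limit is 1
  E <- sum(contrib)
  ddf <- if (E > q) 2 * E / (E - q) else Inf
  list(F = Fstat, ndf = q, ddf = ddf,
       p = stats::pf(Fstat, q, ddf, lower.tail = FALSE))
}

# Tukey (studentized-range) adjusted p for one of a family of all pairwise
# comparisons among k groups, using the contrast's Satterthwaite df.
tukey_p <- function(tval, k, df) {
  stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = df,
                lower.tail = FALSE)
}
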