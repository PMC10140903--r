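# Maximum-likelihood estimation of confirmatory factor / latent difference
# score models with mean structure and equality constraints.
#
# A model is five pattern matrices (loadings Lambda p x m, residual
# covariance Theta p x p, latent covariance Psi m x m, intercepts nu p,
# latent means alpha m), each given as a numeric `value` (fixed values and
# starting values) plus a character `label` of the same shape: "" marks a
# fixed entry, identical labels share one free parameter. Implied moments
# are Sigma = Lambda Psi Lambda' + Theta and mu = nu + Lambda alpha; the
# normal-theory ML discrepancy
#   F = log|Sigma| + tr(S Sigma^-1) - log|S| - p + (m - mu)' Sigma^-1 (m - mu)
# is minimized with S the ML (n-divisor) covariance, so chi2 = n F.

sem_matrix <- function(value, label) {
  stopifnot(all(dim(as.matrix(value)) == dim(as.matrix(label))))
  list(value = as.matrix(value), label = as.matrix(label))
}

sem_model <- function(lambda, theta, psi, nu, alpha) {
  model <- list(lambda = lambda, theta = theta, psi = psi,
                nu = nu, alpha = alpha)
  labs <- character(0)
  starts <- numeric(0)
  for (mt in model) {
    l <- as.vector(mt$label)
    v <- as.vector(mt$value)
    new <- l != "" & !duplicated(l) & !(l %in% labs)
    labs <- c(labs, l[new])
    starts <- c(starts, v[new])
  }
  model$free <- setNames(starts, labs)
  model
}

sem_fill <- function(model, par) {
  fill1 <- function(mt) {
    out <- mt$value
    sel <- mt$label != ""
    out[sel] <- par[mt$label[sel]]
    out
  }
  lambda <- fill1(model$lambda)
  theta <- fill1(model$theta)
  psi <- fill1(model$psi)
  # symmetrize from the upper triangle pattern
  theta[lower.tri(theta)] <- t(theta)[lower.tri(theta)]
  psi[lower.tri(psi)] <- t(psi)[lower.tri(psi)]
  list(lambda = lambda, theta = theta, psi = psi,
       nu = as.vector(fill1(model$nu)), alpha = as.vector(fill1(model$alpha)))
}

sem_implied <- function(mats) {
  sigma <- mats$lambda %*% mats$psi %*% t(mats$lambda) + mats$theta
  mu <- mats$nu + as.vector(mats$lambda %*% mats$alpha)
  list(sigma = (sigma + t(sigma)) / 2, mu = mu)
}

sem_discrepancy <- function(par, model, S, mbar, logdetS) {
  imp <- sem_implied(sem_fill(model, par))
  p <- length(mbar)
  ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  sinv <- chol2inv(ch)
  dm <- mbar - imp$mu
  val <- logdet + sum(sinv * S) - logdetS - p +
    as.numeric(t(dm) %*% sinv %*% dm)
  if (!is.finite(val)) 1e10 else val
}

# Fit by normal-theory ML. Returns estimates, asymptotic covariance,
# chi-square, df, implied and observed moments.
sem_fit_ml <- function(model, data) {
  data <- as.matrix(data)
  keep <- complete.cases(data)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  p <- ncol(data)
  n_free <- length(model$free)
  if (n <= n_free)
    stop("more free parameters than observations", call. = FALSE)
  mbar <- colMeans(data)
  S <- cov(data) * (n - 1) / n
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("observed covariance matrix is not positive definite",
         call. = FALSE)
  logdetS <- 2 * sum(log(diag(ch)))

  obj <- function(par) {
    names(par) <- names(model$free)
    sem_discrepancy(par, model, S, mbar, logdetS)
  }
  opt <- nlminb(model$free, obj,
                control = list(iter.max = 2000, eval.max = 4000))
  # one polish pass guards against premature nlminb stops
  opt2 <- nlminb(opt$par, obj,
                 control = list(iter.max = 2000, eval.max = 4000))
  if (opt2$objective < opt$objective) opt <- opt2
  est <- setNames(opt$par, names(model$free))
  converged <- opt$convergence == 0 && opt$objective < 1e9

  H <- tryCatch(optimHess(est, obj), error = function(e) NULL)
  acov <- NULL
  if (!is.null(H)) {
    acov <- tryCatch(solve(H) * 2 / n, error = function(e) NULL)
    if (!is.null(acov) && any(diag(acov) < 0)) acov[] <- NA_real_
    if (!is.null(acov)) dimnames(acov) <- list(names(est), names(est))
  }

  mats <- sem_fill(model, est)
  imp <- sem_implied(mats)
  chi2 <- max(n * opt$objective, 0)
  df <- p * (p + 3) / 2 - n_free

  # independence baseline (free variances and means, zero covariances)
  f_base <- sum(log(diag(S))) - logdetS
  baseline_chi2 <- n * f_base
  baseline_df <- p * (p - 1) / 2

  # standardized residuals over unique covariance and mean elements
  sdv <- sqrt(diag(S))
  res_cov <- (S - imp$sigma) / tcrossprod(sdv)
  res_mean <- (mbar - imp$mu) / sdv
  srmr <- sqrt(mean(c(res_cov[upper.tri(res_cov, diag = TRUE)],
                      res_mean)^2))

  list(estimates = est, acov = acov, matrices = mats, implied = imp,
       chi2 = chi2, df = df, n = n, p = p,
       baseline_chi2 = baseline_chi2, baseline_df = baseline_df,
       srmr = srmr, S = S, mbar = mbar, converged = converged,
       objective = opt$objective, model = model)
}

# Wald inference for one free parameter
sem_param_test <- function(fit, label) {
  est <- fit$estimates[[label]]
  se <- if (is.null(fit$acov)) NA_real_ else sqrt(fit$acov[label, label])
  z <- est / se
  c(est = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

# Latent correlation between factors a and b from labelled Psi entries,
# with a delta-method standard error.
sem_latent_correlation <- function(fit, lab_ab, lab_aa, lab_bb) {
  est <- fit$estimates
  v_ab <- est[[lab_ab]]; v_aa <- est[[lab_aa]]; v_bb <- est[[lab_bb]]
  rho <- v_ab / sqrt(v_aa * v_bb)
  se <- NA_real_
  if (!is.null(fit$acov) && !anyNA(fit$acov[c(lab_ab, lab_aa, lab_bb),
                                            c(lab_ab, lab_aa, lab_bb)])) {
    g <- c(1 / sqrt(v_aa * v_bb),
           -rho / (2 * v_aa),
           -rho / (2 * v_bb))
    V <- fit$acov[c(lab_ab, lab_aa, lab_bb), c(lab_ab, lab_aa, lab_bb)]
    se <- sqrt(as.numeric(t(g) %*% V %*% g))
  }
  z <- rho / se
  c(est = rho, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

#' Structural equation model fit indices
#'
#' Standard absolute and incremental fit indices from the model and
#' independence-baseline chi-squares: RMSEA
#' `sqrt(max(chi2 - df, 0) / (df n))` with a confidence interval from
#' inverting the noncentral chi-square distribution, CFI, and TLI. For a
#' saturated model (`df = 0`) RMSEA is defined as 0 and CFI as 1.
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param n sample size (used as-is in the RMSEA denominator).
#' @param baseline_chi2,baseline_df independence-model chi-square and df.
#' @param level confidence level of the RMSEA interval.
#' @return Named list: `rmsea`, `rmsea_ci` (length 2), `cfi`, `tli`.
#' @examples
#' fit_indices(41.32, 28, 101, 500, 36)
#' @export
fit_indices <- function(chi2, df, n, baseline_chi2, baseline_df,
                        level = 0.95) {
  if (df <= 0) {
    return(list(rmsea = 0, rmsea_ci = c(0, 0), cfi = 1, tli = 1))
  }
  rmsea <- sqrt(max(chi2 - df, 0) / (df * n))
  ncp_bound <- function(target_p) {
    # largest ncp with pchisq(chi2, df, ncp) >= target_p
    if (pchisq(chi2, df, ncp = 0) < target_p) return(0)
    upper <- max(chi2 * 2, 10)
    while (pchisq(chi2, df, ncp = upper) > target_p) upper <- upper * 2
    uniroot(function(l) pchisq(chi2, df, ncp = l) - target_p,
            c(0, upper), tol = 1e-8)$root
  }
  lo <- ncp_bound((1 + level) / 2)
  hi <- ncp_bound((1 - level) / 2)
  ci <- sqrt(c(lo, hi) / (df * n))

  d_m <- max(chi2 - df, 0)
  d_b <- max(baseline_chi2 - baseline_df, 0)
  cfi <- if (max(d_m, d_b) == 0) 1 else 1 - d_m / max(d_b, d_m)
  tli <- if (baseline_df > 0 && baseline_chi2 / baseline_df > 1) {
    (baseline_chi2 / baseline_df - chi2 / df) /
      (baseline_chi2 / baseline_df - 1)
  } else 1
  # TLI is not bounded above by 1 (well-fitting models can exceed it)
  list(rmsea = rmsea, rmsea_ci = ci, cfi = cfi, tli = tli)
}
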