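#' Latent difference score model specification
#'
#' Builds the 9-indicator latent-difference-score model relating a
#' diffusion parameter (or observed score) to working memory capacity.
#' Per block there is a pair of indicators: the baseline condition
#' (congruent task-repeat trials) and the changed condition (congruent
#' task-switch trials for `contrast = "switch"`, incongruent task-repeat
#' trials for `contrast = "incongruency"`; the incongruency contrast
#' never uses task-switch cells). The changed indicator loads on both the
#' baseline factor B and the change factor Delta with the same loading,
#' and strict measurement invariance is imposed within block: equal
#' loading, equal intercept and equal residual variance across the two
#' conditions of a block, with the paired residuals of a block allowed to
#' covary. WMC is measured by three parallel parcels.
#'
#' Identification: the block-1 loading is fixed to 1 and the block-1
#' intercept to 0, so the latent means of B and Delta are in the
#' indicator's units; the WMC factor mean is fixed to 0 with free parcel
#' intercepts. With 9 indicators, 54 observed moments and 26 free
#' parameters the model has 28 degrees of freedom.
#'
#' @param parameter which quantity the indicators carry: `"t0"`, `"v"`,
#'   or `"score"` (an observed performance score).
#' @param contrast `"switch"` or `"incongruency"`.
#' @return An object of class `lds_spec`: the indicator column names, the
#'   SEM pattern matrices and labels, and the model degrees of freedom.
#' @examples
#' spec <- lds_spec("t0", "switch")
#' spec$df
#' @export
lds_spec <- function(parameter = c("t0", "v", "score"),
                     contrast = c("switch", "incongruency")) {
  parameter <- match.arg(parameter)
  contrast <- match.arg(contrast)
  ind <- c(paste0("base_b", 1:3), paste0("chg_b", 1:3),
           paste0("wmc_p", 1:3))
  p <- 9L; m <- 3L  # latents: B, Delta, WMC

  lam_v <- matrix(0, p, m, dimnames = list(ind, c("B", "Delta", "WMC")))
  lam_l <- matrix("", p, m, dimnames = dimnames(lam_v))
  for (b in 1:3) {
    lam_v[b, "B"] <- 1
    lam_v[b + 3, "B"] <- 1
    lam_v[b + 3, "Delta"] <- 1
    if (b > 1) {
      lam_l[b, "B"] <- paste0("lambda", b)
      lam_l[b + 3, "B"] <- paste0("lambda", b)
      lam_l[b + 3, "Delta"] <- paste0("lambda", b)
    }
  }
  lam_v[7:9, "WMC"] <- c(1, 1, 1)
  lam_l[8:9, "WMC"] <- c("lw2", "lw3")

  th_v <- diag(0.05, p); dimnames(th_v) <- list(ind, ind)
  th_l <- matrix("", p, p, dimnames = dimnames(th_v))
  for (b in 1:3) {
    th_l[b, b] <- paste0("theta", b)
    th_l[b + 3, b + 3] <- paste0("theta", b)
    th_l[b, b + 3] <- paste0("thcov", b)  # paired residual covariance
    th_v[b, b + 3] <- 0.005
  }
  for (k in 7:9) th_l[k, k] <- paste0("thw", k - 6)
  th_v[7:9, 7:9] <- diag(2, 3)

  psi_v <- diag(c(0.05, 0.02, 4))
  dimnames(psi_v) <- list(c("B", "Delta", "WMC"), c("B", "Delta", "WMC"))
  psi_l <- matrix("", m, m, dimnames = dimnames(psi_v))
  diag(psi_l) <- c("psiB", "psiD", "psiW")
  psi_l[1, 2] <- "psiBD"; psi_l[1, 3] <- "psiBW"; psi_l[2, 3] <- "psiDW"

  nu_v <- matrix(0, p, 1, dimnames = list(ind, NULL))
  nu_l <- matrix("", p, 1, dimnames = list(ind, NULL))
  for (b in 2:3) {
    nu_l[b, 1] <- paste0("tau", b)
    nu_l[b + 3, 1] <- paste0("tau", b)
  }
  nu_l[7:9, 1] <- paste0("nuw", 1:3)
  nu_v[7:9, 1] <- 15

  al_v <- matrix(c(0.3, 0.1, 0), m, 1,
                 dimnames = list(c("B", "Delta", "WMC"), NULL))
  al_l <- matrix(c("iB", "iD", ""), m, 1)

  model <- sem_model(sem_matrix(lam_v, lam_l), sem_matrix(th_v, th_l),
                     sem_matrix(psi_v, psi_l), sem_matrix(nu_v, nu_l),
                     sem_matrix(al_v, al_l))
  df <- p * (p + 3) / 2 - length(model$free)
  structure(list(parameter = parameter, contrast = contrast,
                 indicators = ind, model = model, df = df),
            class = "lds_spec")
}

#' @export
print.lds_spec <- function(x, ...) {
  cat(sprintf(
    "LDS model spec: %s effect in %s; 9 indicators, %d free parameters, df = %d\n",
    x$contrast, x$parameter, length(x$model$free), x$df))
  invisible(x)
}

#' Assemble LDS indicator data
#'
#' Builds the subject-level wide table the LDS model is fit to, from
#' either a [subject_estimates()] table (diffusion parameters) or a
#' [score_cells()] table with a `measure` column name (observed scores),
#' merged with the WMC parcels of [score_rnb()].
#'
#' Baseline indicators are the congruent task-repeat cells per block; the
#' changed indicators are congruent task-switch cells (switch contrast)
#' or incongruent task-repeat cells (incongruency contrast). For
#' non-decision time under the parsimonious model the congruency
#' dimension is collapsed by the fit itself, so the pairs are the
#' task-repeat and task-switch cells.
#'
#' @param x a [subject_estimates()] data.frame or a [score_cells()]
#'   data.frame (the latter requires `measure`).
#' @param wmc a [score_rnb()] data.frame (subject, parcels).
#' @param parameter `"t0"` or `"v"` when `x` holds diffusion estimates;
#'   ignored when `measure` is given.
#' @param contrast `"switch"` or `"incongruency"`.
#' @param measure for observed scores: the column of `x` to use
#'   (e.g. `"speed"` or `"probit_error"`).
#' @return A data.frame with columns `subject`, `base_b1..3`,
#'   `chg_b1..3`, `wmc_p1..3`.
#' @export
lds_indicators <- function(x, wmc, parameter = c("t0", "v"),
                           contrast = c("switch", "incongruency"),
                           measure = NULL) {
  contrast <- match.arg(contrast)
  if (is.null(measure)) {
    parameter <- match.arg(parameter)
    est <- x[x$family == parameter, ]
    val <- est$mean
    s <- est$s; i <- est$i; blk <- est$block; subj <- est$subject
    if (parameter == "t0" && all(is.na(i))) i <- ifelse(is.na(i), 0L, i)
    if (all(is.na(s)))
      stop("estimates do not distinguish the switch dimension",
           call. = FALSE)
  } else {
    if (!measure %in% names(x))
      stop(sprintf("column '%s' not found", measure), call. = FALSE)
    val <- x[[measure]]
    s <- x$s; i <- x$i; blk <- x$block; subj <- x$subject
  }
  pick <- function(sv, iv, b) {
    sel <- s == sv & i == iv & blk == b
    out <- rep(NA_real_, length(unique(subj)))
    out[match(subj[sel], sort(unique(subj)))] <- val[sel]
    out
  }
  chg <- if (contrast == "switch") c(1L, 0L) else c(0L, 1L)
  subjects <- sort(unique(subj))
  out <- data.frame(subject = subjects)
  for (b in 1:3) out[[paste0("base_b", b)]] <- pick(0L, 0L, b)
  for (b in 1:3) out[[paste0("chg_b", b)]] <- pick(chg[1], chg[2], b)
  if (anyNA(out))
    stop("missing indicator cells for some subjects", call. = FALSE)
  idx <- match(out$subject, wmc$subject)
  if (anyNA(idx))
    stop("WMC parcels missing for some subjects", call. = FALSE)
  out$wmc_p1 <- wmc$parcel_1[idx]
  out$wmc_p2 <- wmc$parcel_2[idx]
  out$wmc_p3 <- wmc$parcel_3[idx]
  out
}

#' Fit a latent difference score model
#'
#' Normal-theory maximum-likelihood fit of the [lds_spec()] model to
#' subject-level indicator data, with mean structure. Reports the latent
#' means of the baseline and change factors, the three latent
#' correlations (baseline-change, WMC-baseline, WMC-change), measurement
#' parameters, and standard fit indices.
#'
#' @param data a [lds_indicators()] table (columns `base_b1..3`,
#'   `chg_b1..3`, `wmc_p1..3`).
#' @param spec an [lds_spec()]; defaults to the switch contrast for
#'   non-decision time.
#' @param level confidence level for the RMSEA interval.
#' @return An object of class `lds_fit`.
#' @examples
#' set.seed(1)
#' dat <- simulate_lds_indicators(200, seed = 1)
#' fit <- fit_lds(dat, lds_spec("t0", "switch"))
#' fit
#' @export
fit_lds <- function(data, spec = lds_spec("t0", "switch"), level = 0.95) {
  stopifnot(inherits(spec, "lds_spec"))
  cols <- spec$indicators
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # fit on a rescaled metric (indicator groups brought to unit-order
  # variance) for optimizer stability; estimates are transformed back.
  # Uniform scaling within an indicator group preserves the model, its
  # constraints, chi-square, df and all correlations.
  sc_d <- sd(unlist(data[, cols[1:6]]))
  sc_w <- sd(unlist(data[, cols[7:9]]))
  scaled <- data[, cols]
  scaled[, 1:6] <- scaled[, 1:6] / sc_d
  scaled[, 7:9] <- scaled[, 7:9] / sc_w
  model <- lds_starts(spec$model, scaled)
  fit <- sem_fit_ml(model, scaled)
  back <- c(lambda2 = 1, lambda3 = 1, lw2 = 1, lw3 = 1,
            theta1 = sc_d^2, theta2 = sc_d^2, theta3 = sc_d^2,
            thcov1 = sc_d^2, thcov2 = sc_d^2, thcov3 = sc_d^2,
            thw1 = sc_w^2, thw2 = sc_w^2, thw3 = sc_w^2,
            psiB = sc_d^2, psiD = sc_d^2, psiBD = sc_d^2,
            psiW = sc_w^2, psiBW = sc_d * sc_w, psiDW = sc_d * sc_w,
            tau2 = sc_d, tau3 = sc_d, nuw1 = sc_w, nuw2 = sc_w,
            nuw3 = sc_w, iB = sc_d, iD = sc_d)
  back <- back[names(fit$estimates)]
  fit$estimates <- fit$estimates * back
  if (!is.null(fit$acov)) fit$acov <- fit$acov * tcrossprod(back)

  means <- rbind(i_B = sem_param_test(fit, "iB"),
                 i_Delta = sem_param_test(fit, "iD"))
  rho <- rbind(
    rho1 = sem_latent_correlation(fit, "psiBD", "psiB", "psiD"),
    rho2 = sem_latent_correlation(fit, "psiBW", "psiB", "psiW"),
    rho3 = sem_latent_correlation(fit, "psiDW", "psiD", "psiW"))
  idx <- fit_indices(fit$chi2, fit$df, fit$n, fit$baseline_chi2,
                     fit$baseline_df, level)
  p_chi2 <- pchisq(fit$chi2, fit$df, lower.tail = FALSE)

  structure(list(spec = spec, sem = fit, means = means, rho = rho,
                 chi2 = fit$chi2, df = fit$df, p = p_chi2, n = fit$n,
                 rmsea = idx$rmsea, rmsea_ci = idx$rmsea_ci,
                 srmr = fit$srmr, cfi = idx$cfi, tli = idx$tli,
                 converged = fit$converged),
            class = "lds_fit")
}

# Data-driven starting values for the LDS pattern matrices.
lds_starts <- function(model, data) {
  base <- as.matrix(data[, 1:3])
  chg <- as.matrix(data[, 4:6])
  parc <- as.matrix(data[, 7:9])
  mb <- colMeans(base); mc <- colMeans(chg); mp <- colMeans(parc)
  model$alpha$value[1, 1] <- mb[1]
  model$alpha$value[2, 1] <- mc[1] - mb[1]
  start <- model$free
  set <- function(lab, val) if (lab %in% names(start)) start[lab] <<- val
  for (b in 2:3) set(paste0("tau", b), mb[b] - mb[1])
  vb <- mean(apply(base, 2, var))
  vd <- mean(apply(chg - base, 2, var))
  set("psiB", 0.75 * vb)
  set("psiD", max(0.5 * vd, 0.05 * vb))
  set("psiW", 0.75 * mean(apply(parc, 2, var)))
  set("psiBD", 0)
  set("psiBW", 0)
  set("psiDW", 0)
  for (b in 1:3) {
    set(paste0("theta", b), 0.25 * vb)
    set(paste0("thcov", b), 0)
  }
  for (k in 1:3) set(paste0("thw", k), 0.25 * var(parc[, k]))
  for (k in 1:3)
    if (paste0("nuw", k) %in% names(start)) start[paste0("nuw", k)] <- mp[k]
  set("iB", mb[1])
  set("iD", mc[1] - mb[1])
  model$nu$value[7:9, 1] <- mp
  model$free <- start
  model
}

#' @export
print.lds_fit <- function(x, ...) {
  cat(sprintf("Latent difference score model (%s effect, %s), n = %d\n",
              x$spec$contrast, x$spec$parameter, x$n))
  cat(sprintf("  chi2(%d) = %.2f, p = %.3f; RMSEA = %.3f [%.3f; %.3f]; SRMR = %.3f; CFI = %.3f; TLI = %.3f\n",
              x$df, x$chi2, x$p, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2],
              x$srmr, x$cfi, x$tli))
  cat(sprintf("  i_B = %.3f (p = %.3f), i_Delta = %.3f (p = %.3f)\n",
              x$means["i_B", "est"], x$means["i_B", "p"],
              x$means["i_Delta", "est"], x$means["i_Delta", "p"]))
  cat(sprintf("  rho1(B,Delta) = %.3f, rho2(WMC,B) = %.3f, rho3(WMC,Delta) = %.3f\n",
              x$rho["rho1", "est"], x$rho["rho2", "est"],
              x$rho["rho3", "est"]))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.lds_fit <- function(object, ...) object$sem$estimates

#' @export
summary.lds_fit <- function(object, ...) {
  print(object)
  cat("\nFree parameters:\n")
  print(round(object$sem$estimates, 4))
  invisible(object)
}

#' Latent response-caution factor model
#'
#' Models response caution as a latent factor over its three block-level
#' estimates, correlated with a WMC factor measured by the three parcels.
#' Means are saturated (free intercepts, latent means 0); the block-1 and
#' parcel-1 loadings are fixed to 1. The model has 8 degrees of freedom.
#'
#' @param a_est data.frame with columns `subject`, `block`, `mean`
#'   (caution estimates, e.g. `subject_estimates()` filtered to family
#'   `"a"`), or a wide data.frame with columns `a_b1..3`.
#' @param wmc a [score_rnb()] table.
#' @return A list of class `caution_fit`: latent correlation (with SE and
#'   p), standardized loadings, fit indices, chi-square and df.
#' @export
fit_caution_factor <- function(a_est, wmc) {
  if (all(c("block", "mean") %in% names(a_est))) {
    a_est <- a_est[if ("family" %in% names(a_est))
      a_est$family == "a" else TRUE, ]
    subjects <- sort(unique(a_est$subject))
    wide <- data.frame(subject = subjects)
    for (b in 1:3)
      wide[[paste0("a_b", b)]] <-
        a_est$mean[a_est$block == b][match(subjects,
                                           a_est$subject[a_est$block == b])]
  } else wide <- a_est
  idx <- match(wide$subject, wmc$subject)
  wide$wmc_p1 <- wmc$parcel_1[idx]
  wide$wmc_p2 <- wmc$parcel_2[idx]
  wide$wmc_p3 <- wmc$parcel_3[idx]
  ind <- c(paste0("a_b", 1:3), paste0("wmc_p", 1:3))
  # unit-order rescaling per indicator group; everything reported
  # (correlation, fit indices, standardized loadings) is scale invariant
  wide[, ind[1:3]] <- wide[, ind[1:3]] / sd(unlist(wide[, ind[1:3]]))
  wide[, ind[4:6]] <- wide[, ind[4:6]] / sd(unlist(wide[, ind[4:6]]))

  p <- 6L; m <- 2L
  lam_v <- matrix(0, p, m, dimnames = list(ind, c("A", "WMC")))
  lam_l <- matrix("", p, m, dimnames = dimnames(lam_v))
  lam_v[1, 1] <- 1; lam_l[2:3, 1] <- c("la2", "la3"); lam_v[2:3, 1] <- 1
  lam_v[4, 2] <- 1; lam_l[5:6, 2] <- c("lw2", "lw3"); lam_v[5:6, 2] <- 1
  th_v <- diag(c(rep(0.02, 3), rep(2, 3))); dimnames(th_v) <- list(ind, ind)
  th_l <- matrix("", p, p, dimnames = dimnames(th_v))
  diag(th_l) <- paste0("th", 1:6)
  psi_v <- matrix(c(0.05, 0, 0, 4), 2, 2)
  psi_l <- matrix(c("psiA", "psiAW", "psiAW", "psiW"), 2, 2)
  psi_l[2, 1] <- ""
  nu_v <- matrix(colMeans(wide[, ind]), p, 1)
  nu_l <- matrix(paste0("nu", 1:6), p, 1)
  al_v <- matrix(0, m, 1); al_l <- matrix("", m, 1)
  model <- sem_model(sem_matrix(lam_v, lam_l), sem_matrix(th_v, th_l),
                     sem_matrix(psi_v, psi_l), sem_matrix(nu_v, nu_l),
                     sem_matrix(al_v, al_l))
  model$free["psiA"] <- 0.75 * var(wide$a_b1)
  model$free["psiW"] <- 0.75 * var(wide$wmc_p1)
  for (k in 1:3) model$free[paste0("th", k)] <- 0.25 * var(wide[[ind[k]]])
  for (k in 4:6) model$free[paste0("th", k)] <- 0.25 * var(wide[[ind[k]]])

  fit <- sem_fit_ml(model, wide[, ind])
  rho <- sem_latent_correlation(fit, "psiAW", "psiA", "psiW")
  idx_f <- fit_indices(fit$chi2, fit$df, fit$n, fit$baseline_chi2,
                       fit$baseline_df)
  # standardized loadings: lambda * sd(latent) / sd(indicator, implied)
  lam <- fit$matrices$lambda
  lat_sd <- sqrt(diag(fit$matrices$psi))
  ind_sd <- sqrt(diag(fit$implied$sigma))
  std_load <- sweep(sweep(lam, 2, lat_sd, "*"), 1, ind_sd, "/")

  structure(list(rho = rho, chi2 = fit$chi2, df = fit$df, n = fit$n,
                 p = pchisq(fit$chi2, fit$df, lower.tail = FALSE),
                 rmsea = idx_f$rmsea, rmsea_ci = idx_f$rmsea_ci,
                 srmr = fit$srmr, cfi = idx_f$cfi, tli = idx_f$tli,
                 std_loadings = std_load, sem = fit,
                 converged = fit$converged),
            class = "caution_fit")
}

#' @export
print.caution_fit <- function(x, ...) {
  cat(sprintf("Latent caution factor model, n = %d\n", x$n))
  cat(sprintf("  chi2(%d) = %.2f, p = %.3f; RMSEA = %.2f; SRMR = %.2f; CFI = %.2f; TLI = %.2f\n",
              x$df, x$chi2, x$p, x$rmsea, x$srmr, x$cfi, x$tli))
  cat(sprintf("  latent correlation WMC-caution: %.3f (p = %.3f)\n",
              x$rho["est"], x$rho["p"]))
  invisible(x)
}

#' Simulate indicator data from the LDS population model
#'
#' Draws subject-level indicator data directly from the latent difference
#' score measurement model: latents (B, Delta, WMC) are multivariate
#' normal with the given means, SDs and correlations; each block's pair
#' of indicators satisfies strict invariance with paired residual
#' covariance; WMC parcels are parallel count-like indicators. Defaults
#' correspond to the non-decision-time switch model (baseline 0.298 s,
#' change 0.088 s, WMC-change correlation -0.405).
#'
#' @param n number of subjects.
#' @param means,sds length-3 numeric: latent means and SDs of
#'   (B, Delta, WMC).
#' @param rho length-3 numeric: correlations (B-Delta, WMC-B, WMC-Delta).
#' @param lambda block loadings (length 3, block 1 should be 1).
#' @param tau block intercepts (length 3, block 1 should be 0).
#' @param resid_sd residual SD of the diffusion-parameter indicators.
#' @param resid_cov paired residual covariance within block.
#' @param parcel_int,parcel_loading,parcel_resid_sd parcel measurement
#'   parameters.
#' @param seed integer seed.
#' @return A data.frame in the [lds_indicators()] layout.
#' @export
simulate_lds_indicators <- function(n, means = c(0.298, 0.088, 0),
                                    sds = c(0.06, 0.05, 1),
                                    rho = c(0.151, -0.011, -0.405),
                                    lambda = c(1, 1, 1), tau = c(0, 0, 0),
                                    resid_sd = 0.02, resid_cov = 1e-4,
                                    parcel_int = c(19, 19, 19),
                                    parcel_loading = c(3, 3, 3),
                                    parcel_resid_sd = 2, seed = 1L) {
  set.seed(as.integer(seed))
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho[1]
  R[1, 3] <- R[3, 1] <- rho[2]
  R[2, 3] <- R[3, 2] <- rho[3]
  if (min(eigen(R, only.values = TRUE)$values) < -1e-8)
    stop("latent correlations are not positive semi-definite",
         call. = FALSE)
  Sigma <- diag(sds) %*% R %*% diag(sds)
  lat <- MASS::mvrnorm(n, means, Sigma)
  out <- data.frame(subject = seq_len(n))
  for (b in 1:3) {
    e <- MASS::mvrnorm(n, c(0, 0),
                       matrix(c(resid_sd^2, resid_cov, resid_cov,
                                resid_sd^2), 2, 2))
    out[[paste0("base_b", b)]] <- tau[b] + lambda[b] * lat[, 1] + e[, 1]
    out[[paste0("chg_b", b)]] <-
      tau[b] + lambda[b] * (lat[, 1] + lat[, 2]) + e[, 2]
  }
  for (k in 1:3)
    out[[paste0("wmc_p", k)]] <- parcel_int[k] +
      parcel_loading[k] * lat[, 3] + rnorm(n, 0, parcel_resid_sd)
  attr(out, "truth") <- list(means = means, sds = sds, rho = rho)
  out
}
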