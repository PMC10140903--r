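#' Constrained diffusion-model lattice
#'
#' Defines which design cells each parameter family may vary over. The
#' lattice spans models of increasing flexibility in response caution `a`
#' (per block, or per block x switch) and non-decision time `t0` (per
#' block, or per block x switch), with drift `v` per block x switch,
#' or per block x switch x incongruency. `M2` is the parsimonious
#' reference model: caution equal across all trial types of a block,
#' non-decision time varying only between task-switch and repeat trials,
#' and drift varying over the full switch x incongruency crossing. `M1`
#' and `M3` force non-decision time to be identical across switch and
#' repeat trials.
#'
#' @param model one of `"M1"` .. `"M6"`.
#' @return A list of class `ddm_model_spec` with components `id`, `a_by`,
#'   `t0_by`, `v_by`.
#' @examples
#' ddm_model_spec("M2")
#' @export
ddm_model_spec <- function(model = c("M2", "M1", "M3", "M4", "M5", "M6")) {
  model <- match.arg(model)
  lattice <- list(
    M1 = list(a_by = "block",   t0_by = "block",   v_by = "block_s"),
    M2 = list(a_by = "block",   t0_by = "block_s", v_by = "block_s_i"),
    M3 = list(a_by = "block",   t0_by = "block",   v_by = "block_s_i"),
    M4 = list(a_by = "block_s", t0_by = "block",   v_by = "block_s_i"),
    M5 = list(a_by = "block_s", t0_by = "block_s", v_by = "block_s"),
    M6 = list(a_by = "block_s", t0_by = "block_s", v_by = "block_s_i")
  )
  structure(c(list(id = model), lattice[[model]]), class = "ddm_model_spec")
}

#' @rdname ddm_model_spec
#' @param a_by,t0_by cell structure of caution and non-decision time:
#'   `"block"` or `"block_s"`.
#' @param v_by cell structure of drift: `"block"`, `"block_s"`,
#'   `"block_i"` or `"block_s_i"`.
#' @export
ddm_model_custom <- function(a_by = "block", t0_by = "block",
                             v_by = "block") {
  stopifnot(a_by %in% c("block", "block_s"),
            t0_by %in% c("block", "block_s"),
            v_by %in% c("block", "block_s", "block_i", "block_s_i"))
  structure(list(id = "custom", a_by = a_by, t0_by = t0_by, v_by = v_by),
            class = "ddm_model_spec")
}

# Parameter slot table for one subject under a model spec: one row per
# estimated cell parameter, with the design cells it covers.
ddm_param_table <- function(spec, blocks = 1:3) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  fam <- function(family, by) {
    g <- switch(by,
      block = expand.grid(block = blocks, s = NA_integer_,
                          i = NA_integer_),
      stop("unknown cell structure: ", by),
      block_s = expand.grid(block = blocks, s = 0:1, i = NA_integer_),
      block_i = expand.grid(block = blocks, s = NA_integer_, i = 0:1),
      block_s_i = expand.grid(block = blocks, s = 0:1, i = 0:1))
    g$family <- family
    g
  }
  tab <- rbind(fam("a", spec$a_by), fam("t0", spec$t0_by),
               fam("v", spec$v_by))
  tab$type <- match(tab$family, c("a", "t0", "v")) - 1L
  tab$name <- paste0(tab$family, "_b", tab$block,
                     ifelse(is.na(tab$s), "", paste0("_s", tab$s)),
                     ifelse(is.na(tab$i), "", paste0("_i", tab$i)))
  tab$slot <- seq_len(nrow(tab)) - 1L
  tab[, c("slot", "family", "type", "block", "s", "i", "name")]
}

# Map design cells (block, s, i) to parameter slots of one family.
slot_lookup <- function(param_table, family, block, s, i) {
  pt <- param_table[param_table$family == family, ]
  if (is.na(pt$s[1])) s <- rep(NA_integer_, length(block))
  if (is.na(pt$i[1])) i <- rep(NA_integer_, length(block))
  pt_key <- paste(pt$block, pt$s, pt$i)
  idx <- match(paste(block, s, i), pt_key)
  pt$slot[idx]
}

#' Fit the hierarchical Bayesian diffusion model
#'
#' Estimates subject-level diffusion parameters per design cell under the
#' chosen lattice model, with a normal population distribution over
#' subjects on transformed scales (log for caution and non-decision time,
#' identity for drift). The likelihood is the Wiener first-passage
#' contamination mixture ([mixture_loglik()]) with a fixed 5%
#' contaminant proportion, uniform over each subject's observed RT range.
#' Sampling is adaptive Metropolis-within-Gibbs: random-walk updates of
#' the subject parameters, conjugate draws of the group means and
#' variances. With a single subject (or `hierarchical = FALSE`), subject
#' parameters get fixed weakly-informative priors instead of the
#' population model.
#'
#' Only scored test trials (phase `"test"`, not warm-up) enter the fit;
#' correct and error trials are both used and no post-error exclusion is
#' applied.
#'
#' @param trials trial-record data.frame with columns `subject`, `block`,
#'   `s`, `i`, `accuracy`, `rt` (seconds), optionally `phase`/`warmup`.
#' @param model lattice model id, see [ddm_model_spec()].
#' @param draws posterior draws kept per chain.
#' @param burnin burn-in iterations discarded per chain (adaptation
#'   happens here).
#' @param chains number of chains (>= 2 recommended; required by
#'   [gelman_rubin()]).
#' @param thin thinning interval.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param pi_cont contaminant proportion of the likelihood mixture.
#' @param hierarchical population model on/off; defaults to on when more
#'   than one subject is present.
#' @param err series truncation tolerance used inside the sampler.
#' @return An object of class `ddm_hfit`.
#' @examples
#' \donttest{
#' pop <- sample_population(population_spec(n_subjects = 8), seed = 1)
#' trials <- simulate_switch_task(pop, make_trial_list(1), seed = 2)
#' fit <- fit_ddm(trials, "M2", draws = 200, burnin = 100, seed = 3)
#' summary(fit)
#' }
#' @export
fit_ddm <- function(trials, model = "M2", draws = 1000L, burnin = 500L,
                    chains = 2L, thin = 1L, seed = 1L, pi_cont = 0.05,
                    hierarchical = NULL, err = 1e-7) {
  spec <- if (inherits(model, "ddm_model_spec")) model else
    ddm_model_spec(model)
  trials <- scored_trials(trials)
  if (nrow(trials) == 0L) stop("no scored trials", call. = FALSE)
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("response times must be positive and finite", call. = FALSE)

  subjects <- sort(unique(trials$subject))
  n_subj <- length(subjects)
  if (is.null(hierarchical)) hierarchical <- n_subj > 1L
  blocks <- sort(unique(trials$block))
  pt <- ddm_param_table(spec, blocks)
  P <- nrow(pt)

  jidx <- match(trials$subject, subjects) - 1L
  ia <- slot_lookup(pt, "a", trials$block, trials$s, trials$i)
  it0 <- slot_lookup(pt, "t0", trials$block, trials$s, trials$i)
  iv <- slot_lookup(pt, "v", trials$block, trials$s, trials$i)
  if (anyNA(ia) || anyNA(it0) || anyNA(iv))
    stop("trials reference design cells outside the model spec",
         call. = FALSE)

  # every subject must have trials in every distinguished cell
  cover <- table(factor(jidx, levels = 0:(n_subj - 1)),
                 factor(iv, levels = pt$slot[pt$family == "v"]))
  if (any(cover == 0L)) {
    bad <- which(cover == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("subject %s x %s", subjects[bad[, 1]],
                       pt$name[pt$family == "v"][bad[, 2]]),
               collapse = "; "), call. = FALSE)
  }

  # combo = unique (subject, a-slot, t0-slot, v-slot); CSR trial layout
  combo_key <- paste(jidx, ia, it0, iv)
  combo_levels <- unique(combo_key)
  cid <- match(combo_key, combo_levels)
  ord <- order(cid)
  first <- !duplicated(cid)
  cmeta <- data.frame(subj = jidx[first], ia = ia[first], it0 = it0[first],
                      iv = iv[first], id = cid[first])
  cmeta <- cmeta[order(cmeta$id), ]
  off <- c(0L, cumsum(tabulate(cid, nbins = length(combo_levels))))

  upper <- as.integer(trials$accuracy)
  rt_s <- trials$rt[ord]
  up_s <- upper[ord]

  cont_lo <- tapply(trials$rt, jidx, min)[as.character(0:(n_subj - 1))]
  cont_hi <- tapply(trials$rt, jidx, max)[as.character(0:(n_subj - 1))]

  # data-informed initial values on the transformed scale
  eta0 <- matrix(0, n_subj, P)
  for (jj in seq_len(n_subj)) {
    rows <- jidx == jj - 1L
    rtj <- trials$rt[rows]
    t0_init <- max(0.12, 0.85 * quantile(rtj, 0.02))
    for (p in seq_len(P)) {
      fam <- pt$family[p]
      slot <- pt$slot[p]
      if (fam == "a") eta0[jj, p] <- log(1.5)
      else if (fam == "t0") eta0[jj, p] <- log(t0_init)
      else {
        sel <- rows & iv == slot
        acc <- mean(upper[sel])
        acc <- min(max(acc, 0.52), 0.98)
        eta0[jj, p] <- log(acc / (1 - acc)) / 1.5
      }
    }
  }

  prior_m <- c(0.4, -1.2, 1.0)   # by type (log a, log t0, v): flat-mode mean
  prior_s <- c(3, 3, 5)
  m0 <- c(0.4, -1.2, 1.0)        # group-mean hyperprior
  s0 <- c(1.5, 1.5, 3)

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    eta_ch <- eta0 + matrix(rnorm(length(eta0), 0, 0.08), n_subj, P)
    res <- cpp_hddm_chain(rt_s, up_s, as.integer(off),
                          as.integer(cmeta$subj), as.integer(cmeta$ia),
                          as.integer(cmeta$it0), as.integer(cmeta$iv),
                          n_subj, P, as.integer(pt$type),
                          as.numeric(cont_lo), as.numeric(cont_hi),
                          pi_cont, eta_ch,
                          as.integer(draws), as.integer(burnin),
                          as.integer(thin), hierarchical,
                          prior_m, prior_s, m0, s0, 2.0, 0.2, err)
    d <- res$draws
    subj_names <- as.vector(t(outer(subjects, pt$name,
                                    function(s, n) paste0(n, "[", s, "]"))))
    colnames(d) <- c(if (hierarchical) c(paste0("mu_", pt$name),
                                         paste0("sigma_", pt$name)),
                     subj_names)
    chain_draws[[ch]] <- d
  }

  structure(list(draws = chain_draws, param_table = pt, model = spec,
                 subjects = subjects, trials = trials,
                 hierarchical = hierarchical,
                 cont_window = cbind(lo = as.numeric(cont_lo),
                                     hi = as.numeric(cont_hi)),
                 settings = list(draws = draws, burnin = burnin,
                                 chains = chains, thin = thin, seed = seed,
                                 pi_cont = pi_cont, err = err)),
            class = "ddm_hfit")
}

# scored test trials: phase == "test" and not warm-up, when flagged
scored_trials <- function(trials) {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "test", ]
  if ("warmup" %in% names(trials)) trials <- trials[!trials$warmup, ]
  trials
}

#' @export
print.ddm_hfit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical diffusion-model fit (%s): %d subjects, %d trials\n",
    x$model$id, length(x$subjects), nrow(x$trials)))
  cat(sprintf("  %d chains x %d draws (burn-in %d)%s\n",
              x$settings$chains, x$settings$draws, x$settings$burnin,
              if (x$hierarchical) "" else ", non-hierarchical"))
  invisible(x)
}

#' Pooled posterior draws of one parameter
#'
#' @param fit a [fit_ddm()] result.
#' @param par parameter name: group-level (`"mu_t0_b1_s0"`,
#'   `"sigma_v_b1_s0_i0"`) or subject-level (`"t0_b1_s0[3]"`).
#' @return Numeric vector of pooled post-burn-in draws over chains.
#' @export
extract_draws <- function(fit, par) {
  stopifnot(inherits(fit, "ddm_hfit"))
  if (!par %in% colnames(fit$draws[[1]]))
    stop(sprintf("parameter '%s' not found in the posterior draws", par),
         call. = FALSE)
  unlist(lapply(fit$draws, function(d) d[, par]), use.names = FALSE)
}

#' Posterior means of group-average parameters
#'
#' The group average on the natural scale: for each draw, the mean of the
#' subject-level parameter values (a, t0 in their natural units; drift as
#' is), summarized by its posterior mean.
#'
#' @param object a [fit_ddm()] result.
#' @param ... unused.
#' @return Named numeric vector, one entry per estimated cell parameter.
#' @export
coef.ddm_hfit <- function(object, ...) {
  pt <- object$param_table
  out <- numeric(nrow(pt))
  names(out) <- pt$name
  for (k in seq_len(nrow(pt))) {
    cols <- paste0(pt$name[k], "[", object$subjects, "]")
    vals <- lapply(object$draws, function(d)
      rowMeans(d[, cols, drop = FALSE]))
    out[k] <- mean(unlist(vals))
  }
  out
}

#' @export
summary.ddm_hfit <- function(object, ...) {
  est <- subject_estimates(object)
  gr <- tryCatch(gelman_rubin(object), error = function(e) NULL)
  group <- coef(object)
  out <- list(model = object$model$id, n_subjects = length(object$subjects),
              n_trials = nrow(object$trials), group_means = group,
              convergence = gr)
  class(out) <- "summary.ddm_hfit"
  out
}

#' @export
print.summary.ddm_hfit <- function(x, ...) {
  cat(sprintf("Model %s: %d subjects, %d trials\n", x$model, x$n_subjects,
              x$n_trials))
  cat("Group-average parameters (posterior means):\n")
  print(round(x$group_means, 3))
  if (!is.null(x$convergence))
    cat(sprintf("R-hat: mean %.4f, max %.4f\n",
                x$convergence$summary["mean"],
                x$convergence$summary["max"]))
  invisible(x)
}

#' Subject-level posterior estimates
#'
#' Posterior mean and SD of every subject x cell parameter, one row per
#' subject and distinguished design cell. This is the table the latent
#' difference score stage consumes.
#'
#' @param fit a [fit_ddm()] result.
#' @return A data.frame with columns `subject`, `family`, `block`, `s`,
#'   `i`, `name`, `mean`, `sd`.
#' @export
subject_estimates <- function(fit) {
  stopifnot(inherits(fit, "ddm_hfit"))
  pt <- fit$param_table
  grid <- expand.grid(k = seq_len(nrow(pt)), subject = fit$subjects)
  cols <- paste0(pt$name[grid$k], "[", grid$subject, "]")
  all_draws <- do.call(rbind, fit$draws)
  m <- colMeans(all_draws[, cols, drop = FALSE])
  s <- apply(all_draws[, cols, drop = FALSE], 2, sd)
  data.frame(subject = grid$subject, family = pt$family[grid$k],
             block = pt$block[grid$k], s = pt$s[grid$k], i = pt$i[grid$k],
             name = pt$name[grid$k], mean = unname(m), sd = unname(s))
}

#' Boxplots of subject-level parameter estimates
#'
#' Draws one panel per parameter family: subject posterior means split by
#' design cell (caution by block; non-decision time by block and switch;
#' drift by block, switch and congruency).
#'
#' @param x a [fit_ddm()] result.
#' @param ... passed to [graphics::boxplot()].
#' @return The estimates table, invisibly.
#' @export
plot.ddm_hfit <- function(x, ...) {
  est <- subject_estimates(x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  for (fam in c("a", "t0", "v")) {
    e <- est[est$family == fam, ]
    graphics::boxplot(mean ~ name, data = e, las = 2, xlab = "",
                      ylab = switch(fam, a = "caution",
                                    t0 = "non-decision time (s)",
                                    v = "drift rate"), ...)
  }
  invisible(est)
}

#' Write and read subject-estimate tables
#'
#' CSV serialization of [subject_estimates()] tables at full double
#' precision (17 significant digits), so that a write/read cycle
#' reproduces the numeric values bit-identically.
#'
#' @param estimates a [subject_estimates()] data.frame.
#' @param path file path.
#' @return `read_estimates()` returns the data.frame; `write_estimates()`
#'   returns `path` invisibly.
#' @export
write_estimates <- function(estimates, path) {
  out <- estimates
  for (cl in c("mean", "sd"))
    out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  est <- read.csv(path, stringsAsFactors = FALSE)
  est$mean <- as.numeric(est$mean)
  est$sd <- as.numeric(est$sd)
  est
}

#' Gelman-Rubin convergence diagnostic
#'
#' The classic multi-chain potential scale reduction factor: the ratio of
#' the pooled between/within-chain variance estimate to the within-chain
#' variance, `R-hat = sqrt(1 + (1 + 1/m) B / ((n - 1) W))` for `m` chains
#' of length `n` (identical chains give exactly 1). Optionally computed on
#' split half-chains and/or rank-normalized draws.
#'
#' @param x a [fit_ddm()] result, or a list of chain matrices
#'   (iterations x parameters).
#' @param split split each chain into halves before computing R-hat.
#' @param rank_normalize compute on rank-normalized draws.
#' @return A list of class `convergence_report`: `psrf` (per parameter)
#'   and `summary` (mean, sd, min, max).
#' @export
gelman_rubin <- function(x, split = FALSE, rank_normalize = FALSE) {
  chains <- if (inherits(x, "ddm_hfit")) x$draws else x
  if (!is.list(chains) || length(chains) < 2L)
    stop("at least two chains are required", call. = FALSE)
  n <- nrow(chains[[1]])
  if (n < 50L) stop("need >= 50 post-burn-in iterations", call. = FALSE)
  if (split) {
    half <- n %/% 2L
    chains <- c(lapply(chains, function(d) d[seq_len(half), , drop = FALSE]),
                lapply(chains, function(d)
                  d[(n - half + 1L):n, , drop = FALSE]))
  }
  mat <- lapply(chains, function(d) as.matrix(d))
  if (rank_normalize) {
    pooled <- do.call(rbind, mat)
    N <- nrow(pooled)
    for (j in seq_len(ncol(pooled))) {
      z <- qnorm((rank(pooled[, j]) - 3 / 8) / (N + 1 / 4))
      splits <- rep(seq_along(mat), each = nrow(mat[[1]]))
      for (c_i in seq_along(mat)) mat[[c_i]][, j] <- z[splits == c_i]
    }
  }
  m <- length(mat)
  nn <- nrow(mat[[1]])
  means <- sapply(mat, colMeans)
  vars <- sapply(mat, function(d) apply(d, 2, var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)  # var of chain means = B/n
  psrf <- sqrt(1 + (1 + 1 / m) * B_over_n * nn / ((nn - 1) * W))
  psrf[W < .Machine$double.eps] <- 1  # constant parameters
  names(psrf) <- colnames(mat[[1]])
  structure(list(psrf = psrf,
                 summary = c(mean = mean(psrf), sd = sd(psrf),
                             min = min(psrf), max = max(psrf))),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("R-hat over %d parameters: mean %.5f (sd %.5f), range %.5f-%.5f\n",
              length(x$psrf), x$summary["mean"], x$summary["sd"],
              x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' Bayesian probability of a parameter difference
#'
#' Folded exceedance probability `2 |Pr(a > b) - 0.5|` over pooled
#' posterior draws: 0 means the two posteriors are indistinguishable, 1
#' means fully separated. With `folded = FALSE` the one-sided mass
#' `Pr(a > b)` is returned instead.
#'
#' @param a,b numeric vectors of pooled posterior draws (e.g. from
#'   [extract_draws()]), equal length or independently drawn.
#' @param folded return the folded form (default) or the one-sided mass.
#' @return A probability in `[0, 1]`.
#' @export
posterior_diff_prob <- function(a, b, folded = TRUE) {
  if (length(a) == 0L || length(b) == 0L)
    stop("empty draws", call. = FALSE)
  if (length(a) != length(b)) {
    k <- max(length(a), length(b))
    a <- rep_len(a, k); b <- rep_len(b, k)
  }
  p <- mean(a > b)
  if (folded) 2 * abs(p - 0.5) else p
}
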