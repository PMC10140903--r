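#' Pipeline configuration
#'
#' A fully serializable description of an end-to-end run: seeds, cohort
#' size, population ground truth overrides, lattice model, MCMC
#' settings, scoring options. A run is reproducible from the
#' configuration alone; [write_config()]/[read_config()] round-trip it
#' through YAML.
#'
#' The default MCMC settings mirror the reference analysis (10,000 kept
#' draws, 1,000 burn-in, 2 chains); recovery studies and tests use
#' scaled-down settings passed explicitly.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @param n_subjects cohort size.
#' @param model lattice model id for the diffusion stage.
#' @param draws,burnin,chains MCMC settings.
#' @param population named list of [population_spec()] overrides
#'   (`means`, `sds`, `corr`, `block_effects`).
#' @param speed speed-score convention, see [score_cells()].
#' @param ppc_reps posterior predictive replicates.
#' @param exclude_subjects optional subject ids to drop before fitting
#'   (robustness re-analyses).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 101L, model = "M2",
                            draws = 10000L, burnin = 1000L, chains = 2L,
                            population = list(), speed = "per_trial",
                            ppc_reps = 500L, exclude_subjects = NULL) {
  structure(list(seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), model = model,
                 draws = as.integer(draws), burnin = as.integer(burnin),
                 chains = as.integer(chains), population = population,
                 speed = speed, ppc_reps = as.integer(ppc_reps),
                 exclude_subjects = exclude_subjects),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[names(cfg) %in%
                                 names(formals(pipeline_config))])
}

# deterministic stage seeds derived from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2000000011L
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a cohort from the population model, then runs every
#' analysis stage: conventional performance scoring (cell means, effect
#' scores, repeated-measures ANOVAs of speed and probit error),
#' hierarchical diffusion-model estimation with convergence diagnostics,
#' Recall-N-Back scoring and parceling, the three latent difference
#' score models (switch effect in t0, switch and incongruency effects in
#' drift) and the latent caution factor model.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `switchddm_report` collecting all stage
#'   outputs.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 1, n_subjects = 40, draws = 300,
#'                        burnin = 150)
#' rep <- run_pipeline(cfg)
#' print(rep)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pspec <- do.call(population_spec,
                   c(list(n_subjects = config$n_subjects),
                     config$population))
  pop <- sample_population(pspec, seed = stage_seed(config$seed, 1L))
  trial_list <- make_trial_list(stage_seed(config$seed, 2L))
  trials <- simulate_switch_task(pop, trial_list,
                                 seed = stage_seed(config$seed, 3L))
  rnb <- simulate_rnb(pop, rnb_design(stage_seed(config$seed, 4L)),
                      seed = stage_seed(config$seed, 5L))
  if (!is.null(config$exclude_subjects)) {
    trials <- trials[!trials$subject %in% config$exclude_subjects, ]
    rnb <- rnb[!rnb$subject %in% config$exclude_subjects, ]
  }

  cells <- score_cells(trials, speed = config$speed)
  effects <- effect_scores(cells)
  anova_speed <- rm_anova(cells, "speed", "subject",
                          c("block", "s", "i"))
  anova_probit <- rm_anova(cells, "probit_error", "subject",
                           c("block", "s", "i"))
  wmc <- score_rnb(rnb)

  fit <- fit_ddm(trials, config$model, draws = config$draws,
                 burnin = config$burnin, chains = config$chains,
                 seed = stage_seed(config$seed, 6L))
  convergence <- gelman_rubin(fit)
  est <- subject_estimates(fit)

  par_summary <- do.call(rbind, lapply(split(est, est$name), function(e)
    data.frame(name = e$name[1],
               q10 = quantile(e$mean, .1), q25 = quantile(e$mean, .25),
               median = median(e$mean), q75 = quantile(e$mean, .75),
               q90 = quantile(e$mean, .9))))

  lds <- list(
    switch_t0 = fit_lds(lds_indicators(est, wmc, "t0", "switch"),
                        lds_spec("t0", "switch")),
    switch_v = fit_lds(lds_indicators(est, wmc, "v", "switch"),
                       lds_spec("v", "switch")),
    incon_v = fit_lds(lds_indicators(est, wmc, "v", "incongruency"),
                      lds_spec("v", "incongruency")))
  caution <- fit_caution_factor(est[est$family == "a", ], wmc)

  structure(list(config = config, cells = cells, effects = effects,
                 anova_speed = anova_speed, anova_probit = anova_probit,
                 wmc = wmc, fit = fit, convergence = convergence,
                 estimates = est, parameter_summary = par_summary,
                 lds = lds, caution = caution),
            class = "switchddm_report")
}

#' @export
print.switchddm_report <- function(x, ...) {
  cat("== Task-switching diffusion/LDS pipeline report ==\n")
  cat(sprintf("Cohort: %d subjects (seed %d), model %s\n",
              x$config$n_subjects, x$config$seed, x$config$model))
  cat("\n-- Mean RT (ms) and error rate by block x s x i --\n")
  agg <- aggregate(cbind(rt_ms = mean_rt * 1000, error = error_rate) ~
                     block + s + i, x$cells, mean)
  print(round(agg[order(agg$s, agg$i, agg$block), ], 3), row.names = FALSE)
  cat("\n-- Speed-score ANOVA --\n")
  print(transform(x$anova_speed[, c("term", "df1", "df2", "F", "p", "pes")],
                  F = round(F, 2), p = round(p, 4), pes = round(pes, 2)),
        row.names = FALSE)
  cat("\n-- Convergence --\n")
  print(x$convergence)
  cat("\n-- Latent difference score models --\n")
  tab <- do.call(rbind, lapply(names(x$lds), function(nm) {
    f <- x$lds[[nm]]
    data.frame(model = nm, chi2 = round(f$chi2, 2), df = f$df,
               rmsea = round(f$rmsea, 3),
               i_B = round(f$means["i_B", "est"], 3),
               i_Delta = round(f$means["i_Delta", "est"], 3),
               rho3 = round(f$rho["rho3", "est"], 3))
  }))
  print(tab, row.names = FALSE)
  cat("\n-- Latent caution factor --\n")
  print(x$caution)
  invisible(x)
}

#' Parameter-recovery study
#'
#' Repeats the simulate-and-fit cycle over independent synthetic cohorts
#' with known ground truth and reports recovery metrics: bias and RMSE
#' of the group-level non-decision-time switch increment, the rank
#' correlation between true and estimated subject-level increments, and
#' the fraction of replications in which posterior-predictive MSE
#' selects the generating model over the alternatives.
#'
#' @param config a [pipeline_config()]; its population defaults define
#'   the generating truth (t0 switch increment 88 ms under the package
#'   defaults).
#' @param reps number of replications (>= 2).
#' @param models lattice models compared by PPC (first one is treated as
#'   the generating model).
#' @param ppc_reps posterior predictive replicates per fitted model.
#' @return An object of class `recovery_study`: per-replication table
#'   and summary metrics.
#' @export
recovery_study <- function(config, reps = 10L,
                           models = c("M2", "M1", "M3"),
                           ppc_reps = 30L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (reps < 2L) stop("'reps' must be at least 2", call. = FALSE)
  pspec <- do.call(population_spec,
                   c(list(n_subjects = config$n_subjects),
                     config$population))
  truth_incr <- pspec$means["t0_delta"]
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    sr <- stage_seed(config$seed, 100L + 7L * r)
    pop <- sample_population(pspec, seed = sr)
    trials <- simulate_switch_task(pop, make_trial_list(sr + 1L),
                                   seed = sr + 2L)
    mse <- setNames(numeric(length(models)), models)
    est_incr <- NA_real_
    rank_cor <- NA_real_
    for (m in models) {
      fit <- fit_ddm(trials, m, draws = config$draws,
                     burnin = config$burnin, chains = config$chains,
                     seed = sr + 3L)
      mse[m] <- ppc_mse(fit, n_rep = ppc_reps, seed = sr + 4L)$mse
      if (m == models[1]) {
        est <- subject_estimates(fit)
        t0e <- est[est$family == "t0", ]
        if (all(is.na(t0e$s)))
          stop("generating model must distinguish t0 by switch",
               call. = FALSE)
        per_subj <- sapply(split(t0e, t0e$subject), function(e)
          mean(e$mean[e$s == 1]) - mean(e$mean[e$s == 0]))
        est_incr <- mean(per_subj)
        truth_subj <- pop$subjects$t0_delta[
          match(as.numeric(names(per_subj)), pop$subjects$subject)]
        rank_cor <- suppressWarnings(
          cor(truth_subj, per_subj, method = "spearman"))
      }
    }
    rows[[r]] <- data.frame(rep = r, est_increment = est_incr,
                            rank_cor = rank_cor,
                            selected = models[which.min(mse)],
                            t(mse))
  }
  tab <- do.call(rbind, rows)
  summary <- list(
    truth_increment = unname(truth_incr),
    mean_increment = mean(tab$est_increment),
    bias = mean(tab$est_increment) - unname(truth_incr),
    rmse = sqrt(mean((tab$est_increment - truth_incr)^2)),
    mean_rank_cor = mean(tab$rank_cor),
    selection_rate = mean(tab$selected == models[1]))
  structure(list(table = tab, summary = summary, models = models,
                 config = config),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery study: %d replications, models %s\n",
              nrow(x$table), paste(x$models, collapse = "/")))
  cat(sprintf("  t0 switch increment: truth %.1f ms, mean estimate %.1f ms (bias %+.1f ms, RMSE %.1f ms)\n",
              1000 * s$truth_increment, 1000 * s$mean_increment,
              1000 * s$bias, 1000 * s$rmse))
  cat(sprintf("  mean rank correlation of subject increments: %.2f\n",
              s$mean_rank_cor))
  cat(sprintf("  generating model selected by PPC MSE in %.0f%% of replications\n",
              100 * s$selection_rate))
  invisible(x)
}
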