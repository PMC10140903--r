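#' Conventional cell scores for the switching task
#'
#' Aggregates scored test trials (phase `"test"`, warm-up excluded) per
#' subject x block x switch x incongruency cell: mean correct-trial RT,
#' mean speed (the per-trial reciprocal 1/RT averaged over correct
#' trials, i.e. responses per second), error rate, and the
#' probit-transformed error rate. Because raw latencies and accuracies
#' are heavily skewed, the speed and probit transforms are the scores
#' used for the conventional analyses.
#'
#' Probit edge correction: error rates are corrected as
#' `(errors + 0.5) / (n + 1)` before applying the standard-normal
#' quantile, keeping cells with 0 or 100% errors finite.
#'
#' @param trials trial-record data.frame (see [simulate_switch_task()]).
#' @param speed `"per_trial"` (mean of 1/RT, default) or `"of_mean"`
#'   (reciprocal of the mean RT).
#' @param exclude_post_error drop trials immediately following an error
#'   (within subject and block, by `trial_index`) before scoring. Off by
#'   default: all scored trials enter the cell means.
#' @return A data.frame with one row per subject x block x s x i:
#'   `n_trials`, `n_correct`, `mean_rt` (s), `speed` (1/s),
#'   `error_rate`, `probit_error`, `flagged` (cell without correct
#'   trials: `mean_rt`/`speed` are `NA`).
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 2), seed = 1)
#' trials <- simulate_switch_task(pop, make_trial_list(1), seed = 2)
#' head(score_cells(trials))
#' @export
score_cells <- function(trials, speed = c("per_trial", "of_mean"),
                        exclude_post_error = FALSE) {
  speed <- match.arg(speed)
  trials <- scored_trials(trials)
  if (nrow(trials) == 0L) stop("no scored trials", call. = FALSE)
  if (exclude_post_error && "trial_index" %in% names(trials)) {
    trials <- trials[order(trials$subject, trials$block,
                           trials$trial_index), ]
    prev_err <- c(FALSE, trials$accuracy[-nrow(trials)] == 0L)
    same_run <- c(FALSE, trials$subject[-1] == trials$subject[-nrow(trials)] &
                    trials$block[-1] == trials$block[-nrow(trials)])
    trials <- trials[!(prev_err & same_run), ]
  }
  f <- list(subject = trials$subject, block = trials$block, s = trials$s,
            i = trials$i)
  n <- aggregate(trials$rt, f, length)
  names(n)[5] <- "n_trials"
  nc <- aggregate(trials$accuracy, f, sum)$x
  corr <- trials[trials$accuracy == 1L, ]
  key <- function(d) paste(d$subject, d$block, d$s, d$i)
  out <- n
  out$n_correct <- nc
  if (nrow(corr) > 0L) {
    fc <- list(subject = corr$subject, block = corr$block, s = corr$s,
               i = corr$i)
    mrt <- aggregate(corr$rt, fc, mean)
    spd <- if (speed == "per_trial") aggregate(1 / corr$rt, fc, mean)
           else transform(mrt, x = 1 / mrt$x)
    out$mean_rt <- mrt$x[match(key(out), key(mrt))]
    out$speed <- spd$x[match(key(out), key(spd))]
  } else {
    out$mean_rt <- NA_real_
    out$speed <- NA_real_
  }
  out$error_rate <- 1 - out$n_correct / out$n_trials
  out$probit_error <- qnorm(
    (out$n_trials - out$n_correct + 0.5) / (out$n_trials + 1))
  out$flagged <- out$n_correct == 0L
  out <- out[order(out$subject, out$block, out$s, out$i), ]
  rownames(out) <- NULL
  out
}

#' Global and specific switch/incongruency effect scores
#'
#' Per-subject and block effect scores on the cell means: the global
#' switch effect averages over congruency (`mean(s=1) - mean(s=0)`),
#' while the specific switch effect uses only congruent trials
#' (`(s1,i0) - (s0,i0)`); analogously the global incongruency effect
#' averages over switch and the specific effect uses only task-repeat
#' trials (`(s0,i1) - (s0,i0)`). Effects are computed for mean RT (in
#' milliseconds) and error rate.
#'
#' @param cells a [score_cells()] table (all four cells required per
#'   subject x block).
#' @return A data.frame with one row per subject x block x measure
#'   (`rt_ms`, `error_rate`): `global_switch`, `specific_switch`,
#'   `global_incon`, `specific_incon`.
#' @export
effect_scores <- function(cells) {
  key <- paste(cells$subject, cells$block)
  out <- list()
  for (k in unique(key)) {
    cc <- cells[key == k, ]
    if (nrow(cc) != 4L)
      stop("missing design cell(s) for subject x block ", k, call. = FALSE)
    cell <- function(s, i, col) cc[cc$s == s & cc$i == i, col]
    for (measure in c("rt_ms", "error_rate")) {
      col <- if (measure == "rt_ms") "mean_rt" else "error_rate"
      scale <- if (measure == "rt_ms") 1000 else 1
      m <- sapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                  function(z) cell(z[1], z[2], col)) * scale
      out[[length(out) + 1L]] <- data.frame(
        subject = cc$subject[1], block = cc$block[1], measure = measure,
        global_switch = mean(m[3:4]) - mean(m[1:2]),
        specific_switch = m[3] - m[1],
        global_incon = mean(m[c(2, 4)]) - mean(m[c(1, 3)]),
        specific_incon = m[2] - m[1])
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$measure, res$subject, res$block), ]
  rownames(res) <- NULL
  res
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Fully within-subject ANOVA of a balanced design, fit through
#' [stats::aov()] with `Error(subject/(...))` strata so that every
#' within-subject term is tested against its own subject-by-term error
#' stratum. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#' Degrees of freedom are unadjusted (no sphericity correction).
#'
#' @param data long-format data.frame with one row per subject x cell.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param factors character vector of within-subject factor columns.
#' @return A data.frame with one row per term: `term`, `df1`, `df2`,
#'   `F`, `p`, `pes` (partial eta squared), `ss_effect`, `ss_error`.
#' @examples
#' d <- expand.grid(subject = 1:8, b = 1:3, s = 0:1)
#' d$y <- rnorm(nrow(d)) + d$s
#' rm_anova(d, "y", "subject", c("b", "s"))
#' @export
rm_anova <- function(data, dv, subject, factors) {
  d <- data
  d$.subj <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  cell_counts <- table(d[, c(".subj", factors)])
  if (any(cell_counts != 1L))
    stop("design must be complete and balanced with one observation per subject x cell (aggregate first)",
         call. = FALSE)
  rhs <- paste(factors, collapse = " * ")
  form <- as.formula(sprintf("%s ~ %s + Error(.subj/(%s))", dv, rhs, rhs))
  fit <- aov(form, data = d)
  out <- list()
  for (stratum in names(fit)) {
    s <- summary(fit[[stratum]])[[1]]
    terms_here <- trimws(rownames(s))
    resid_row <- terms_here == "Residuals"
    if (!any(resid_row)) next
    ss_err <- s[resid_row, "Sum Sq"]
    df_err <- s[resid_row, "Df"]
    for (r in which(!resid_row)) {
      ss_eff <- s[r, "Sum Sq"]
      Fv <- s[r, "F value"]; pv <- s[r, "Pr(>F)"]
      pes <- ss_eff / (ss_eff + ss_err)
      if (ss_eff < .Machine$double.eps) {  # degenerate 0/0: no effect
        Fv <- 0; pv <- 1; pes <- 0
      }
      out[[length(out) + 1L]] <- data.frame(
        term = gsub(":", " x ", terms_here[r]),
        df1 = s[r, "Df"], df2 = df_err, F = Fv, p = pv, pes = pes,
        ss_effect = ss_eff, ss_error = ss_err)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partial-credit scoring of the Recall-N-Back task
#'
#' Counts correct individual recall responses over the scored test
#' blocks. Load-one blocks are excluded (they do not require working
#' memory), leaving nine scored blocks (loads 2-4 crossed with 6/9/12
#' updates) and a maximum score of 81. Three parallel parcels are built
#' from the block scores via [build_parcels()].
#'
#' @param records a [simulate_rnb()] table (or real data with the same
#'   columns).
#' @return A data.frame per subject: `total` (partial-credit score),
#'   `parcel_1`, `parcel_2`, `parcel_3`.
#' @export
score_rnb <- function(records) {
  rec <- records[records$phase == "test" & records$load >= 2L, ]
  if (nrow(rec) == 0L) stop("no scored test records", call. = FALSE)
  blocks <- aggregate(rec$correct,
                      list(subject = rec$subject, load = rec$load,
                           n_updates = rec$n_updates), sum)
  names(blocks)[4] <- "n_correct"
  out <- list()
  for (j in unique(blocks$subject)) {
    bj <- blocks[blocks$subject == j, ]
    parcels <- build_parcels(bj)
    out[[length(out) + 1L]] <- data.frame(
      subject = j, total = sum(bj$n_correct),
      parcel_1 = parcels[1], parcel_2 = parcels[2], parcel_3 = parcels[3])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parallel parcels of Recall-N-Back block scores
#'
#' Assigns the nine scored blocks (loads 2-4 x updates 6/9/12) to three
#' parcels by a fixed Latin square, so that every parcel contains exactly
#' one block of each load and one of each update count -- making the
#' parcels parallel in difficulty and length (maximum 27 each). The
#' assignment is `parcel = ((load - 2) + u) mod 3 + 1` with `u` the 0-based
#' index of the update count in (6, 9, 12).
#'
#' @param block_scores data.frame with columns `load`, `n_updates`,
#'   `n_correct` covering the nine scored blocks of one subject.
#' @return Numeric length-3 vector of parcel sums.
#' @export
build_parcels <- function(block_scores) {
  need <- expand.grid(load = 2:4, n_updates = c(6L, 9L, 12L))
  key <- paste(block_scores$load, block_scores$n_updates)
  idx <- match(paste(need$load, need$n_updates), key)
  if (anyNA(idx))
    stop("missing scored block(s): ",
         paste(paste0("load ", need$load, "/", need$n_updates,
                      " updates")[is.na(idx)], collapse = ", "),
         call. = FALSE)
  bs <- block_scores[idx, ]
  parcel <- ((bs$load - 2L) + match(bs$n_updates, c(6L, 9L, 12L)) - 1L) %% 3L + 1L
  as.numeric(tapply(bs$n_correct, parcel, sum))
}
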