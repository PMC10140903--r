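#' Posterior predictive model check by summary-statistic MSE
#'
#' Simulates replicate datasets from the fitted posterior and compares
#' them to the observed data through per-subject, per-design-cell summary
#' statistics: response accuracy and the .1/.3/.5/.7/.9 RT quantiles of
#' correct and of error responses. For each replicate one posterior
#' iteration is drawn at random, the full design (same trial counts per
#' subject and cell) is simulated from that iteration's subject-level
#' parameters, and the summaries recomputed. The report's `mse` is the
#' mean squared deviation between the observed summaries and the
#' replicate-mean summaries, over all summary elements that are defined
#' in the observed data. Quantiles enter the comparison only when the
#' relevant response type has at least `min_n` trials in a cell: order
#' statistics of sparser sets (for example the handful of errors in a
#' mostly-correct cell) are dominated by sampling noise, which would
#' dilute the model comparison rather than inform it. The default of 16
#' is half a typical design cell.
#'
#' @param fit a [fit_ddm()] result (the data it was fit to are stored in
#'   the object).
#' @param n_rep number of posterior predictive replicates (>= 2).
#' @param seed integer seed.
#' @param probs RT quantile probabilities summarizing each distribution.
#' @param min_n minimum trials of a response type in a cell for its
#'   quantiles to enter the comparison.
#' @return An object of class `ddm_ppc`: `mse`, `n_rep`, `stats`
#'   (description of the summary set), `n_elements`.
#' @export
ppc_mse <- function(fit, n_rep = 500L, seed = 1L,
                    probs = c(.1, .3, .5, .7, .9), min_n = 16L) {
  stopifnot(inherits(fit, "ddm_hfit"))
  if (n_rep < 2L) stop("'n_rep' must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  trials <- fit$trials
  pt <- fit$param_table
  subjects <- fit$subjects

  # finest design cells present in the data
  cells <- unique(trials[, c("subject", "block", "s", "i")])
  cells <- cells[order(cells$subject, cells$block, cells$s, cells$i), ]
  cell_key <- paste(cells$subject, cells$block, cells$s, cells$i)
  trial_cell <- match(paste(trials$subject, trials$block, trials$s,
                            trials$i), cell_key)
  n_per_cell <- tabulate(trial_cell, nbins = nrow(cells))

  summarize <- function(rt, acc, cell_idx) {
    nq <- length(probs)
    out <- matrix(NA_real_, nrow(cells), 1 + 2 * nq)
    for (c_i in seq_len(nrow(cells))) {
      sel <- cell_idx == c_i
      if (!any(sel)) next
      a <- acc[sel]; r <- rt[sel]
      out[c_i, 1] <- mean(a)
      if (sum(a == 1L) >= min_n)
        out[c_i, 1 + seq_len(nq)] <- quantile(r[a == 1L], probs,
                                              names = FALSE)
      if (sum(a == 0L) >= min_n)
        out[c_i, 1 + nq + seq_len(nq)] <- quantile(r[a == 0L], probs,
                                                   names = FALSE)
    }
    out
  }
  obs <- summarize(trials$rt, as.integer(trials$accuracy), trial_cell)

  # slot of each family parameter for every cell
  sidx <- match(cells$subject, subjects)
  ia <- slot_lookup(pt, "a", cells$block, cells$s, cells$i)
  it0 <- slot_lookup(pt, "t0", cells$block, cells$s, cells$i)
  iv <- slot_lookup(pt, "v", cells$block, cells$s, cells$i)
  col_of <- function(slot) paste0(pt$name[slot + 1L], "[",
                                  subjects[sidx], "]")
  a_cols <- col_of(ia); t0_cols <- col_of(it0); v_cols <- col_of(iv)

  all_draws <- do.call(rbind, fit$draws)
  n_draws <- nrow(all_draws)
  lo <- fit$cont_window[sidx, "lo"]
  hi <- fit$cont_window[sidx, "hi"]
  picont <- fit$settings$pi_cont

  acc_sum <- matrix(0, nrow(cells), ncol(obs))
  acc_n <- matrix(0L, nrow(cells), ncol(obs))
  draw_ids <- sample.int(n_draws, n_rep, replace = n_rep > n_draws)
  for (r in seq_len(n_rep)) {
    d <- all_draws[draw_ids[r], ]
    par <- cbind(d[a_cols], d[v_cols], d[t0_cols])
    sim <- cpp_sim_cells(par, as.integer(n_per_cell), 0.5, picont,
                         lo, hi, 512L)
    rep_sum <- summarize(sim$rt, sim$upper, sim$cell)
    ok <- !is.na(rep_sum)
    acc_sum[ok] <- acc_sum[ok] + rep_sum[ok]
    acc_n[ok] <- acc_n[ok] + 1L
  }
  rep_mean <- acc_sum / acc_n
  use <- !is.na(obs) & acc_n > 0L
  mse <- mean((obs[use] - rep_mean[use])^2)

  structure(list(mse = mse, n_rep = as.integer(n_rep),
                 stats = sprintf(
                   "accuracy + correct/error RT quantiles (%s) per subject x block x s x i",
                   paste(probs, collapse = "/")),
                 n_elements = sum(use)),
            class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check: MSE = %.6f (%d replicates, %d summary elements)\n",
              x$mse, x$n_rep, x$n_elements))
  invisible(x)
}
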