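#' Generate a task-switching trial list
#'
#' Builds the design skeleton of the color/size switching paradigm: two
#' task-pure blocks of 44 trials (size, then color), a mixed practice block
#' of 24 trials, and three mixed test blocks of 128 scored trials preceded
#' by 8 warm-up trials each. Within every test block the four
#' switch-by-congruency cells are exactly balanced (32 trials each) and
#' runs of the same task are capped at four trials (at most three
#' consecutive task repetitions). The switch flag of the first scored trial
#' is defined relative to the last warm-up trial.
#'
#' The list is a design skeleton only: `response`, `accuracy` and `rt` are
#' filled in by [simulate_switch_task()] (or by real data).
#'
#' @param seed integer seed; the same seed always yields the identical list.
#' @param n_test_blocks number of mixed test blocks.
#' @param trials_per_block scored trials per test block (a multiple of 4).
#' @param n_warmup warm-up trials per test block.
#' @return A data.frame with columns `phase` (`pure`/`practice`/`test`),
#'   `block` (1..n for test blocks, `NA` otherwise), `trial_index`, `task`,
#'   `s` (switch flag), `i` (incongruency flag), `shape`,
#'   `correct_response`, `warmup`.
#' @examples
#' tl <- make_trial_list(seed = 1)
#' table(tl$phase)
#' @export
make_trial_list <- function(seed = 1L, n_test_blocks = 3L,
                            trials_per_block = 128L, n_warmup = 8L) {
  if (trials_per_block %% 4L != 0L)
    stop("'trials_per_block' must be a multiple of 4", call. = FALSE)
  set.seed(as.integer(seed))
  shapes <- c("triangle", "square", "circle")

  mk <- function(phase, block, n, task, s, i, warmup) {
    data.frame(phase = phase, block = block, trial_index = seq_len(n),
               task = task, s = s, i = i,
               shape = sample(rep_len(shapes, n)),
               correct_response = sample(rep_len(c("left", "right"), n)),
               warmup = warmup, stringsAsFactors = FALSE)
  }

  balanced_flags <- function(n) sample(rep_len(c(0L, 1L), n))

  out <- list(
    mk("pure", NA_integer_, 44L, "size", 0L, balanced_flags(44L), FALSE),
    mk("pure", NA_integer_, 44L, "color", 0L, balanced_flags(44L), FALSE)
  )

  # mixed practice: random task order, flags derived from the sequence
  pr_task <- sample(rep_len(c("size", "color"), 24L))
  pr_s <- c(0L, as.integer(pr_task[-1L] != pr_task[-24L]))
  out[[3L]] <- mk("practice", NA_integer_, 24L, pr_task, pr_s,
                  balanced_flags(24L), FALSE)

  for (b in seq_len(n_test_blocks)) {
    wu_task <- sample(c("size", "color"), n_warmup, replace = TRUE)
    wu_s <- c(0L, as.integer(wu_task[-1L] != wu_task[-n_warmup]))
    wu <- mk("test", b, n_warmup, wu_task, wu_s,
             sample(rep_len(c(0L, 1L), n_warmup)), TRUE)

    s_seq <- balanced_switch_sequence(trials_per_block, max_repeat_run = 3L)
    task <- character(trials_per_block)
    prev <- wu_task[n_warmup]
    for (k in seq_len(trials_per_block)) {
      task[k] <- if (s_seq[k] == 1L) setdiff(c("size", "color"), prev) else prev
      prev <- task[k]
    }
    i_seq <- integer(trials_per_block)
    i_seq[sample(which(s_seq == 1L), trials_per_block / 4L)] <- 1L
    i_seq[sample(which(s_seq == 0L), trials_per_block / 4L)] <- 1L

    sc <- mk("test", b, trials_per_block, task, s_seq, i_seq, FALSE)
    sc$trial_index <- sc$trial_index + n_warmup
    out[[length(out) + 1L]] <- rbind(wu, sc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Balanced 0/1 switch sequence: n/2 switches, n/2 repeats, with at most
# `max_repeat_run` consecutive repeats (so identical-task runs are capped at
# max_repeat_run + 1). Zeros are distributed over the gaps between the
# switches and resampled until the cap holds.
balanced_switch_sequence <- function(n, max_repeat_run = 3L) {
  n_one <- n %/% 2L
  n_zero <- n - n_one
  repeat {
    gaps <- tabulate(sample.int(n_one + 1L, n_zero, replace = TRUE),
                     nbins = n_one + 1L)
    if (max(gaps) <= max_repeat_run) break
  }
  s <- integer(0)
  for (k in seq_len(n_one))
    s <- c(s, rep(0L, gaps[k]), 1L)
  c(s, rep(0L, gaps[n_one + 1L]))
}

#' Recall-N-Back block design
#'
#' The figural updating task design: 3 practice blocks followed by 12 test
#' blocks crossing memory load (1-4 stimulus-location bindings) with the
#' number of updating steps (6, 9 or 12) exactly once. Each update step is
#' one scored recall response. Load-one test blocks are excluded from
#' scoring downstream, leaving 9 scored blocks with a partial-credit
#' maximum of 3 x (6 + 9 + 12) = 81.
#'
#' @param seed integer seed for the pseudo-random block order.
#' @return A data.frame with columns `block`, `phase`, `load`, `n_updates`.
#' @export
rnb_design <- function(seed = 1L) {
  set.seed(as.integer(seed))
  test <- expand.grid(load = 1:4, n_updates = c(6L, 9L, 12L))
  test <- test[sample.int(nrow(test)), , drop = FALSE]
  data.frame(block = seq_len(3L + nrow(test)),
             phase = rep(c("practice", "test"), c(3L, nrow(test))),
             load = c(1L, 2L, 3L, test$load),
             n_updates = c(6L, 6L, 6L, test$n_updates))
}
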