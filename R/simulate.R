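#' Simulate switching-task data for a synthetic cohort
#'
#' Fills a trial-list skeleton with responses, accuracies and response
#' times drawn from each subject's cell-specific diffusion parameters
#' (accuracy coding: the upper boundary is the correct response). Trials
#' outside the test phase (pure and practice blocks) are simulated from
#' the subject's block-1 parameters of the matching switch/congruency
#' cell; they are excluded from all scoring and fitting anyway.
#'
#' A fixed proportion of trials (the population spec's `pi_cont`) are
#' contaminants: uniform RT over `cont_window`, response at chance.
#'
#' @param pop a [sample_population()] result.
#' @param trial_list a [make_trial_list()] skeleton, shared by all
#'   subjects (the paradigm uses identical pseudo-random lists to
#'   standardize measurement).
#' @param seed integer seed.
#' @param cont_window contaminant RT window in seconds.
#' @return A data.frame of trial records: `subject`, `phase`, `block`,
#'   `trial_index`, `task`, `s`, `i`, `shape`, `correct_response`,
#'   `response`, `accuracy`, `rt` (seconds), `warmup`, `contaminant`.
#' @examples
#' pop <- sample_population(population_spec(n_subjects = 2), seed = 1)
#' trials <- simulate_switch_task(pop, make_trial_list(1), seed = 2)
#' @export
simulate_switch_task <- function(pop, trial_list = make_trial_list(),
                                 seed = 1L, cont_window = c(0.25, 5)) {
  stopifnot(inherits(pop, "ddm_population"))
  set.seed(as.integer(seed))
  cp <- pop$cell_params
  subjects <- sort(unique(cp$subject))

  # effective design cell of every trial (non-test phases use block 1)
  block_eff <- ifelse(trial_list$phase == "test", trial_list$block, 1L)
  out <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    j <- subjects[k]
    cpj <- cp[cp$subject == j, ]
    key <- paste(cpj$block, cpj$s, cpj$i)
    trial_key <- paste(block_eff, trial_list$s, trial_list$i)
    cell_idx <- match(trial_key, key)
    if (anyNA(cell_idx)) {
      miss <- unique(trial_key[is.na(cell_idx)])
      stop(sprintf("subject %s lacks parameters for cell(s) %s",
                   j, paste(miss, collapse = ", ")), call. = FALSE)
    }
    n_per_cell <- tabulate(cell_idx, nbins = nrow(cpj))
    sim <- cpp_sim_cells(as.matrix(cpj[, c("a", "v", "t0")]),
                         as.integer(n_per_cell), 0.5, pop$spec$pi_cont,
                         rep(cont_window[1], nrow(cpj)),
                         rep(cont_window[2], nrow(cpj)), 2048L)
    # scatter the cell-grouped draws back into trial order
    ord <- order(cell_idx)
    tl <- trial_list
    tl$subject <- j
    tl$rt <- NA_real_
    tl$accuracy <- NA_integer_
    tl$contaminant <- NA
    tl$rt[ord] <- sim$rt
    tl$accuracy[ord] <- sim$upper
    tl$contaminant[ord] <- sim$contaminant == 1L
    tl$response <- ifelse(tl$accuracy == 1L, tl$correct_response,
                          ifelse(tl$correct_response == "left", "right",
                                 "left"))
    out[[k]] <- tl
  }
  res <- do.call(rbind, out)
  cols <- c("subject", "phase", "block", "trial_index", "task", "s", "i",
            "shape", "correct_response", "response", "accuracy", "rt",
            "warmup", "contaminant")
  res <- res[, cols]
  rownames(res) <- NULL
  res
}

#' Logistic accuracy model for the Recall-N-Back simulator
#'
#' Maps working-memory capacity, memory load and within-block position to
#' a correctness probability:
#' `P(correct) = plogis(intercept + b_wmc * wmc + b_load * (load - 1) +
#' b_pos * (position - 1))`. The reference study fits no such model; it
#' exists purely to endow synthetic recall data with a WMC-graded,
#' load-sensitive structure.
#'
#' @param intercept baseline log-odds of a correct response at load 1.
#' @param b_wmc slope on the standardized WMC latent.
#' @param b_load additive log-odds shift per unit of memory load above 1
#'   (negative: higher load is harder).
#' @param b_pos log-odds shift per update position within a block.
#' @return A list of class `rnb_link`.
#' @export
rnb_link <- function(intercept = 2.2, b_wmc = 0.9, b_load = -0.55,
                     b_pos = -0.01) {
  structure(list(intercept = intercept, b_wmc = b_wmc, b_load = b_load,
                 b_pos = b_pos), class = "rnb_link")
}

#' Simulate Recall-N-Back data
#'
#' Draws Bernoulli correctness per update trial from the logistic link:
#' higher WMC yields stochastically more correct responses, higher load
#' fewer.
#'
#' @param pop a [sample_population()] result (uses the `wmc` latent).
#' @param design a [rnb_design()] table.
#' @param link an [rnb_link()].
#' @param seed integer seed.
#' @return A data.frame of records: `subject`, `block`, `phase`, `load`,
#'   `n_updates`, `trial_index`, `correct`.
#' @export
simulate_rnb <- function(pop, design = rnb_design(), link = rnb_link(),
                         seed = 1L) {
  stopifnot(inherits(pop, "ddm_population"), inherits(link, "rnb_link"))
  set.seed(as.integer(seed))
  subj <- pop$subjects
  blocks <- design[rep(seq_len(nrow(design)), design$n_updates), ]
  blocks$trial_index <- unlist(lapply(design$n_updates, seq_len))
  n_b <- nrow(blocks)
  out <- vector("list", nrow(subj))
  for (k in seq_len(nrow(subj))) {
    eta <- link$intercept + link$b_wmc * subj$wmc[k] +
      link$b_load * (blocks$load - 1) + link$b_pos * (blocks$trial_index - 1)
    p <- 1 / (1 + exp(-eta))
    if (any(is.nan(p)) || any(p < 0) || any(p > 1))
      stop("link produced probabilities outside [0, 1]", call. = FALSE)
    rec <- blocks
    rec$subject <- subj$subject[k]
    rec$correct <- rbinom(n_b, 1L, p)
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  res <- res[, c("subject", "block", "phase", "load", "n_updates",
                 "trial_index", "correct")]
  rownames(res) <- NULL
  res
}

#' Read and write trial-level CSV tables
#'
#' Plain-CSV serialization of trial records in the package's column
#' schema. `read_trials()` optionally converts response times given in
#' milliseconds to seconds via `unit = "ms"`.
#'
#' @param trials a trial record data.frame.
#' @param path file path.
#' @param unit unit of the `rt` column on disk: `"s"` (default) or
#'   `"ms"`.
#' @return `read_trials()` returns the data.frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, unit = c("s", "ms")) {
  unit <- match.arg(unit)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "block", "s", "i", "accuracy", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (unit == "ms") trials$rt <- trials$rt / 1000
  trials
}
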