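# Brute-force oracles used to verify the scoring arithmetic, independent of
# the implementation paths they check.

# Within-subject ANOVA by explicit inclusion-exclusion sums of squares.
# data: long data.frame, one observation per subject x cell; factors fully
# crossed and balanced. Returns per-term F, dfs, partial eta squared.
anova_oracle <- function(data, dv, subject, factors) {
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  y <- d[[dv]]
  all_facs <- c(factors, subject)

  # marginal mean of y at the level combination of factor subset U
  marg <- function(U) {
    if (length(U) == 0L) return(rep(mean(y), length(y)))
    key <- interaction(d[U], drop = FALSE)
    ave(y, key)
  }
  # inclusion-exclusion effect sum of squares for factor subset T
  ss_of <- function(T_set) {
    e <- rep(0, length(y))
    for (k in 0:length(T_set)) {
      for (U in combn_list(T_set, k)) {
        e <- e + (-1)^(length(T_set) - length(U)) * marg(U)
      }
    }
    sum(e^2)
  }
  lev <- function(f) nlevels(d[[f]])
  n_subj <- lev(subject)

  out <- list()
  for (k in 1:length(factors)) {
    for (T_set in combn_list(factors, k)) {
      ss_t <- ss_of(T_set)
      ss_e <- ss_of(c(T_set, subject))
      df_t <- prod(sapply(T_set, lev) - 1)
      df_e <- df_t * (n_subj - 1)
      Fv <- (ss_t / df_t) / (ss_e / df_e)
      out[[length(out) + 1L]] <- data.frame(
        term = paste(T_set, collapse = " x "),
        df1 = df_t, df2 = df_e, F = Fv,
        p = pf(Fv, df_t, df_e, lower.tail = FALSE),
        pes = ss_t / (ss_t + ss_e), ss_effect = ss_t, ss_error = ss_e)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

combn_list <- function(x, k) {
  if (k == 0L) return(list(character(0)))
  cmb <- combn(x, k, simplify = FALSE)
  cmb
}

# Effect scores by direct arithmetic on the four cell values
# (named s0i0, s0i1, s1i0, s1i1).
effect_oracle <- function(m) {
  m <- unname(m[c("s0i0", "s0i1", "s1i0", "s1i1")])
  c(global_switch = (m[3] + m[4]) / 2 - (m[1] + m[2]) / 2,
    specific_switch = m[3] - m[1],
    global_incon = (m[2] + m[4]) / 2 - (m[1] + m[3]) / 2,
    specific_incon = m[2] - m[1])
}

# quick synthetic cohort for fit-based tests
tiny_cohort <- function(n_subjects = 4, seed = 1) {
  pop <- sample_population(population_spec(n_subjects = n_subjects),
                           seed = seed)
  trials <- simulate_switch_task(pop, make_trial_list(seed), seed = seed + 1)
  list(pop = pop, trials = trials)
}
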