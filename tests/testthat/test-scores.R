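# Conventional performance scoring: transforms, effect scores, ANOVA,
# Recall-N-Back partial credit and parcels.

make_cell_trials <- function(rts, accs, subject = 1, block = 1, s = 0,
                             i = 0) {
  data.frame(subject = subject, phase = "test", block = block,
             trial_index = seq_along(rts), s = s, i = i,
             accuracy = accs, rt = rts, warmup = FALSE)
}

test_that("speed is the mean of per-trial reciprocals", {
  tr <- make_cell_trials(c(0.5, 1.0), c(1, 1))
  cs <- score_cells(tr)
  expect_equal(cs$speed, 1.5)
  expect_equal(cs$mean_rt, 0.75)
  cs2 <- score_cells(tr, speed = "of_mean")
  expect_equal(cs2$speed, 1 / 0.75)
})

test_that("probit transform applies the documented edge correction", {
  # half errors: corrected rate is exactly 1/2 -> probit 0
  tr <- make_cell_trials(rep(0.6, 32), rep(c(1, 0), 16))
  expect_equal(score_cells(tr)$probit_error, 0)
  # zero errors in 32 trials: probit of 0.5/33
  tr0 <- make_cell_trials(rep(0.6, 32), rep(1, 32))
  expect_equal(score_cells(tr0)$probit_error, qnorm(0.5 / 33),
               tolerance = 1e-12)
  # all errors: finite
  tr1 <- make_cell_trials(rep(0.6, 8), rep(0, 8))
  expect_true(is.finite(score_cells(tr1)$probit_error))
  expect_true(score_cells(tr1)$flagged)
  expect_true(is.na(score_cells(tr1)$speed))
})

test_that("speed transform reduces the skew of simulated latencies", {
  pop <- sample_population(population_spec(n_subjects = 1), seed = 3)
  tr <- simulate_switch_task(pop, make_trial_list(4), seed = 5)
  tr <- tr[tr$phase == "test" & !tr$warmup & tr$accuracy == 1, ]
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  cell <- tr[tr$s == 0 & tr$i == 0, ]
  expect_lt(abs(skew(1 / cell$rt)), abs(skew(cell$rt)))
})

test_that("effect scores follow their definitions", {
  cells <- expand.grid(subject = 1, block = 1, s = 0:1, i = 0:1)
  cells$mean_rt <- c(0.700, 0.825, 0.720, 0.886)[
    match(paste(cells$s, cells$i), c("0 0", "1 0", "0 1", "1 1"))]
  cells$error_rate <- 0.1
  eff <- effect_scores(cells)
  rt <- eff[eff$measure == "rt_ms", ]
  expect_equal(rt$specific_switch, 125)
  expect_equal(rt$global_switch, 145.5)
  expect_equal(rt$specific_incon, 20)
  expect_equal(rt$global_incon, (720 + 886) / 2 - (700 + 825) / 2)

  # invariance to adding a constant
  cells2 <- cells
  cells2$mean_rt <- cells2$mean_rt + 0.25
  eff2 <- effect_scores(cells2)
  expect_equal(eff2[eff2$measure == "rt_ms", c(4:7)], rt[, 4:7])

  # all-equal cells give zero effects
  cells3 <- cells
  cells3$mean_rt <- 0.7
  eff3 <- effect_scores(cells3)
  expect_true(all(abs(as.matrix(eff3[, 4:7])[eff3$measure == "rt_ms", ])
                  < 1e-12))
})

test_that("effect scores match the brute-force oracle on random cells", {
  set.seed(99)
  for (rep in 1:5) {
    m <- setNames(runif(4, 0.5, 1.2), c("s0i0", "s0i1", "s1i0", "s1i1"))
    cells <- expand.grid(subject = 1, block = 1, s = 0:1, i = 0:1)
    cells$mean_rt <- m[paste0("s", cells$s, "i", cells$i)]
    cells$error_rate <- runif(4)
    eff <- effect_scores(cells)
    rt <- eff[eff$measure == "rt_ms", ]
    o <- effect_oracle(m * 1000)
    expect_equal(rt$global_switch, unname(o["global_switch"]),
                 tolerance = 1e-10)
    expect_equal(rt$specific_switch, o["specific_switch"],
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(rt$global_incon, unname(o["global_incon"]),
                 tolerance = 1e-10)
    expect_equal(rt$specific_incon, o["specific_incon"],
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("global and specific effects coincide without an s x i interaction", {
  cells <- expand.grid(subject = 1, block = 1, s = 0:1, i = 0:1)
  cells$mean_rt <- 0.7 + 0.1 * cells$s + 0.03 * cells$i  # purely additive
  cells$error_rate <- 0
  eff <- effect_scores(cells)
  rt <- eff[eff$measure == "rt_ms", ]
  expect_equal(rt$global_switch, rt$specific_switch, tolerance = 1e-10)
  expect_equal(rt$global_incon, rt$specific_incon, tolerance = 1e-10)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(123)
  for (rep in 1:3) {
    d <- expand.grid(subject = 1:9, b = 1:3, s = 0:1, i = 0:1)
    d$y <- rnorm(nrow(d)) + 0.4 * d$s + 0.2 * d$i * d$s
    got <- rm_anova(d, "y", "subject", c("b", "s", "i"))
    want <- anova_oracle(d, "y", "subject", c("b", "s", "i"))
    want <- want[match(got$term, want$term), ]
    expect_equal(got$ss_effect, want$ss_effect, tolerance = 1e-8)
    expect_equal(got$ss_error, want$ss_error, tolerance = 1e-8)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$pes, want$pes, tolerance = 1e-8)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
  }
})

test_that("ANOVA degrees of freedom match the design size", {
  d <- expand.grid(subject = 1:101, b = 1:3, s = 0:1, i = 0:1)
  set.seed(1)
  d$y <- rnorm(nrow(d))
  out <- rm_anova(d, "y", "subject", c("b", "s", "i"))
  blk <- out[out$term == "b", ]
  expect_equal(c(blk$df1, blk$df2), c(2, 200))
  sw <- out[out$term == "s", ]
  expect_equal(c(sw$df1, sw$df2), c(1, 100))
})

test_that("constant responses give zero F throughout", {
  d <- expand.grid(subject = 1:6, b = 1:3, s = 0:1)
  d$y <- 1
  out <- rm_anova(d, "y", "subject", c("b", "s"))
  expect_true(all(out$F == 0))
  expect_true(all(out$p == 1))
})

test_that("an injected switch effect is detected selectively", {
  set.seed(7)
  d <- expand.grid(subject = 1:100, b = 1:3, s = 0:1, i = 0:1)
  subj_int <- rnorm(100, 0, 0.5)
  d$y <- subj_int[d$subject] + 0.5 * d$s + rnorm(nrow(d), 0, 0.4)
  out <- rm_anova(d, "y", "subject", c("b", "s", "i"))
  expect_lt(out$p[out$term == "s"], 1e-10)
  expect_gt(min(out$p[out$term != "s"]), 0.01)
})

test_that("unbalanced designs are rejected", {
  d <- expand.grid(subject = 1:6, b = 1:3, s = 0:1)
  d$y <- rnorm(nrow(d))
  expect_error(rm_anova(d[-1, ], "y", "subject", c("b", "s")), "balanced")
})

test_that("partial-credit scoring excludes load-one and practice blocks", {
  pop <- sample_population(population_spec(n_subjects = 3), seed = 2)
  rnb <- simulate_rnb(pop, seed = 3)
  base <- score_rnb(rnb)

  flip <- rnb
  flip$correct[flip$load == 1] <- 1L - flip$correct[flip$load == 1]
  expect_equal(score_rnb(flip)$total, base$total)

  flip2 <- rnb
  flip2$correct[flip2$phase == "practice"] <-
    1L - flip2$correct[flip2$phase == "practice"]
  expect_equal(score_rnb(flip2)$total, base$total)

  expect_equal(base$parcel_1 + base$parcel_2 + base$parcel_3, base$total)
  expect_true(all(base$total <= 81))
})

test_that("parcels form a Latin square over load and updates", {
  bs <- expand.grid(load = 2:4, n_updates = c(6L, 9L, 12L))
  bs$n_correct <- bs$n_updates  # all correct
  parcels <- build_parcels(bs)
  expect_equal(parcels, c(27, 27, 27))
  # assignment covers each load and update count once per parcel
  parcel <- ((bs$load - 2L) + match(bs$n_updates, c(6L, 9L, 12L)) - 1L) %% 3L + 1L
  for (p in 1:3) {
    expect_setequal(bs$load[parcel == p], 2:4)
    expect_setequal(bs$n_updates[parcel == p], c(6, 9, 12))
  }
  expect_error(build_parcels(bs[-1, ]), "missing scored block")
})
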