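# Hierarchical diffusion-model estimation: lattice, sampler, diagnostics.

test_that("the lattice fixes M2 and the equal-t0 alternatives", {
  m2 <- ddm_model_spec("M2")
  expect_equal(m2$a_by, "block")
  expect_equal(m2$t0_by, "block_s")
  expect_equal(m2$v_by, "block_s_i")
  expect_equal(ddm_model_spec("M1")$t0_by, "block")
  expect_equal(ddm_model_spec("M3")$t0_by, "block")
  pt <- switchddm:::ddm_param_table(m2)
  expect_equal(sum(pt$family == "a"), 3)
  expect_equal(sum(pt$family == "t0"), 6)
  expect_equal(sum(pt$family == "v"), 12)
})

test_that("fits are reproducible under identical seeds", {
  co <- tiny_cohort(3, seed = 11)
  f1 <- fit_ddm(co$trials, "M2", draws = 60, burnin = 40, seed = 5)
  f2 <- fit_ddm(co$trials, "M2", draws = 60, burnin = 40, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ddm(co$trials, "M2", draws = 60, burnin = 40, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("equality constraints of the model spec are honored structurally", {
  co <- tiny_cohort(3, seed = 13)
  fit <- fit_ddm(co$trials, "M2", draws = 60, burnin = 40, seed = 2)
  est <- subject_estimates(fit)
  counts <- table(est$family) / length(fit$subjects)
  expect_equal(unname(counts["a"]), 3)    # one caution value per block
  expect_equal(unname(counts["t0"]), 6)   # block x switch
  expect_equal(unname(counts["v"]), 12)   # block x switch x congruency
  # caution carries no s/i distinction, t0 no congruency distinction
  expect_true(all(is.na(est$s[est$family == "a"])))
  expect_true(all(is.na(est$i[est$family == "t0"])))
})

test_that("empty design cells are reported with subject and cell", {
  co <- tiny_cohort(2, seed = 17)
  tr <- co$trials
  drop <- which(tr$subject == 2 & tr$block == 1 & tr$s == 1 & tr$i == 1)
  tr <- tr[-drop, ]
  expect_error(fit_ddm(tr, "M2", draws = 20, burnin = 10),
               "subject 2 x v_b1_s1_i1")
})

test_that("subject estimate tables round-trip through CSV bit-identically", {
  co <- tiny_cohort(2, seed = 19)
  fit <- fit_ddm(co$trials, "M2", draws = 50, burnin = 30, seed = 3)
  est <- subject_estimates(fit)
  path <- tempfile(fileext = ".csv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_identical(back$mean, est$mean)
  expect_identical(back$sd, est$sd)
  unlink(path)
})

test_that("a degenerate single-draw posterior returns that draw", {
  co <- tiny_cohort(2, seed = 23)
  fit <- fit_ddm(co$trials, "M2", draws = 50, burnin = 30, seed = 3)
  one <- fit
  one$draws <- lapply(fit$draws, function(d) d[1, , drop = FALSE])
  est <- subject_estimates(one)
  v <- one$draws[[1]][1, "t0_b1_s0[1]"]
  # with two chains of one draw each, the mean is over both chains
  v2 <- one$draws[[2]][1, "t0_b1_s0[1]"]
  got <- est$mean[est$name == "t0_b1_s0" & est$subject == 1]
  expect_equal(got, mean(c(v, v2)), tolerance = 1e-12)
})

test_that("the Gelman-Rubin statistic flags non-mixing and passes clones", {
  set.seed(31)
  base <- matrix(rnorm(600), 200, 3,
                 dimnames = list(NULL, c("p1", "p2", "p3")))
  gr <- gelman_rubin(list(base, base, base))
  expect_true(all(abs(gr$psrf - 1) < 1e-6))

  far <- base + 5
  gr2 <- gelman_rubin(list(base, far))
  expect_true(all(gr2$psrf > 1.1))

  expect_error(gelman_rubin(list(base)), "two chains")
  expect_error(gelman_rubin(list(base[1:10, ], base[1:10, ])), ">= 50")
  # split and rank-normalized variants stay near 1 for stationary chains
  gr3 <- gelman_rubin(list(base, base + 0), split = TRUE,
                      rank_normalize = TRUE)
  expect_true(all(gr3$psrf < 1.05))
})

test_that("a well-mixed fit converges by R-hat", {
  co <- tiny_cohort(6, seed = 37)
  fit <- fit_ddm(co$trials, "M2", draws = 400, burnin = 300, seed = 4)
  gr <- gelman_rubin(fit)
  expect_lt(gr$summary["max"], 1.2)
  expect_lt(gr$summary["mean"], 1.05)
})

test_that("posterior difference probabilities behave like folded exceedance", {
  set.seed(41)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(posterior_diff_prob(a, b), 0.05)          # same distribution
  expect_equal(posterior_diff_prob(a + 100, b), 1)    # full separation
  # N(0,1) vs N(1,1): folded exceedance 2|Phi(1/sqrt(2)) - .5| ~ .5205
  a2 <- rnorm(2e5); b2 <- rnorm(2e5, 1)
  expect_lt(abs(posterior_diff_prob(a2, b2) - 0.5204999), 0.01)
  expect_lt(abs(posterior_diff_prob(a2, b2, folded = FALSE) -
                  pnorm(-1 / sqrt(2))), 0.01)
  expect_error(posterior_diff_prob(numeric(0), a), "empty")
})

test_that("posterior predictive MSE is invariant to trial order", {
  co <- tiny_cohort(3, seed = 43)
  fit <- fit_ddm(co$trials, "M2", draws = 60, burnin = 40, seed = 5)
  m1 <- ppc_mse(fit, n_rep = 10, seed = 9)$mse
  set.seed(43)
  fit$trials <- fit$trials[sample.int(nrow(fit$trials)), ]
  m2 <- ppc_mse(fit, n_rep = 10, seed = 9)$mse
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_error(ppc_mse(fit, n_rep = 1), "at least 2")
})

test_that("self-simulated data yield a small posterior predictive MSE", {
  co <- tiny_cohort(4, seed = 47)
  fit <- fit_ddm(co$trials, "M2", draws = 150, burnin = 100, seed = 6)
  m_small <- ppc_mse(fit, n_rep = 60, seed = 1)$mse
  m_tiny <- ppc_mse(fit, n_rep = 8, seed = 1)$mse
  expect_lt(m_small, 0.05)     # near the Monte-Carlo floor
  expect_lte(m_small, m_tiny * 1.5)  # does not grow with replicates
})

test_that("draw extraction finds parameters and rejects unknowns", {
  co <- tiny_cohort(2, seed = 53)
  fit <- fit_ddm(co$trials, "M2", draws = 50, burnin = 30, seed = 3)
  d <- extract_draws(fit, "mu_t0_b1_s1")
  expect_length(d, 100)  # pooled over 2 chains
  expect_error(extract_draws(fit, "nonexistent"), "not found")
})
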