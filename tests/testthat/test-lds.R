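# Latent difference score models and the SEM engine.

test_that("the 9-indicator LDS model has 28 degrees of freedom", {
  for (par in c("t0", "v", "score")) {
    for (con in c("switch", "incongruency")) {
      spec <- lds_spec(par, con)
      expect_equal(spec$df, 28)
      expect_equal(length(spec$model$free), 26)
    }
  }
})

test_that("the spec is reconstructible from its defining fields", {
  spec <- lds_spec("v", "incongruency")
  again <- lds_spec(spec$parameter, spec$contrast)
  expect_identical(spec$model, again$model)
  expect_identical(spec$indicators, again$indicators)
})

test_that("indicator assembly picks the right cells per contrast", {
  est <- expand.grid(subject = 1:2, block = 1:3, s = 0:1, i = 0:1)
  est$family <- "v"
  # encode the cell into the value so the selection is verifiable
  est$mean <- est$block + 10 * est$s + 100 * est$i
  est$name <- "v"
  wmc <- data.frame(subject = 1:2, total = 50, parcel_1 = 17,
                    parcel_2 = 16, parcel_3 = 17)
  sw <- lds_indicators(est, wmc, "v", "switch")
  expect_equal(sw$base_b2[1], 2)        # s0 i0 block 2
  expect_equal(sw$chg_b2[1], 12)        # s1 i0: switch cells, congruent
  inc <- lds_indicators(est, wmc, "v", "incongruency")
  expect_equal(inc$chg_b2[1], 102)      # s0 i1: never a switch cell
  expect_true(all(inc$chg_b1 < 110))    # no s=1 contribution anywhere
})

test_that("latent means and correlations are recovered from generated data", {
  dat <- simulate_lds_indicators(600, seed = 5)
  fit <- fit_lds(dat, lds_spec("t0", "switch"))
  expect_true(fit$converged)
  expect_equal(fit$df, 28)
  expect_lt(abs(fit$means["i_B", "est"] - 0.298),
            3 * fit$means["i_B", "se"] + 0.005)
  expect_lt(abs(fit$means["i_Delta", "est"] - 0.088),
            3 * fit$means["i_Delta", "se"] + 0.005)
  expect_lt(abs(fit$rho["rho3", "est"] - (-0.405)), 0.15)
})

test_that("a zero change mean is recovered without bias", {
  dat <- simulate_lds_indicators(500, means = c(0.3, 0, 0), seed = 7)
  fit <- fit_lds(dat, lds_spec("t0", "switch"))
  expect_lt(abs(fit$means["i_Delta", "est"]),
            2 * fit$means["i_Delta", "se"])
})

test_that("strict invariance ties the implied mean difference to the change factor", {
  dat <- simulate_lds_indicators(400, lambda = c(1, 0.9, 1.1),
                                 tau = c(0, 0.02, -0.01), seed = 9)
  fit <- fit_lds(dat, lds_spec("t0", "switch"))
  mats <- fit$sem$matrices
  imp <- fit$sem$implied
  iD <- mats$alpha[2]
  for (b in 1:3) {
    lam_b <- mats$lambda[b, "B"]
    expect_equal(imp$mu[b + 3] - imp$mu[b], lam_b * iD, tolerance = 1e-8)
  }
})

test_that("fit indices follow their formulas and conventions", {
  idx <- fit_indices(41.32, 28, 101, 500, 36)
  expect_equal(idx$rmsea, sqrt((41.32 - 28) / (28 * 101)), tolerance = 1e-10)
  expect_equal(round(idx$rmsea, 2), 0.07)
  # chi2 = df sits at the RMSEA boundary
  expect_equal(fit_indices(28, 28, 101, 500, 36)$rmsea, 0)
  # saturated convention
  sat <- fit_indices(0, 0, 101, 500, 36)
  expect_equal(sat$rmsea, 0)
  expect_equal(sat$cfi, 1)
  # RMSEA confidence bounds bracket the point estimate
  expect_lte(idx$rmsea_ci[1], idx$rmsea)
  expect_gte(idx$rmsea_ci[2], idx$rmsea)
})

test_that("a saturated model fits perfectly with zero df", {
  set.seed(11)
  y <- MASS::mvrnorm(80, c(0, 1), matrix(c(1, .3, .3, 1), 2))
  lam <- switchddm:::sem_matrix(diag(2), matrix("", 2, 2))
  th <- switchddm:::sem_matrix(diag(0, 2),
                               matrix(c("t1", "t12", "", "t2"), 2, 2,
                                      byrow = TRUE))
  psi <- switchddm:::sem_matrix(diag(0, 2), matrix("", 2, 2))
  nu <- switchddm:::sem_matrix(matrix(0, 2, 1), matrix(c("n1", "n2"), 2, 1))
  al <- switchddm:::sem_matrix(matrix(0, 2, 1), matrix("", 2, 1))
  model <- switchddm:::sem_model(lam, th, psi, nu, al)
  model$free[c("t1", "t2")] <- 1
  fit <- switchddm:::sem_fit_ml(model, y)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-4)
  expect_lt(fit$srmr, 1e-4)
})

test_that("the caution factor model recovers the latent correlation", {
  gen <- function(n, r, seed) {
    set.seed(seed)
    lat <- MASS::mvrnorm(n, c(1.6, 0),
                         matrix(c(0.09, r * 0.3 * 2, r * 0.3 * 2, 4), 2))
    a <- sapply(1:3, function(b) lat[, 1] + rnorm(n, 0, 0.12))
    parc <- sapply(1:3, function(k) 18 + 1.5 * lat[, 2] + rnorm(n, 0, 2))
    list(a_est = data.frame(subject = rep(1:n, 3),
                            block = rep(1:3, each = n),
                            mean = as.vector(a)),
         wmc = data.frame(subject = 1:n, parcel_1 = parc[, 1],
                          parcel_2 = parc[, 2], parcel_3 = parc[, 3]))
  }
  d <- gen(500, -0.3, 13)
  fit <- fit_caution_factor(d$a_est, d$wmc)
  expect_equal(fit$df, 8)
  expect_lt(abs(fit$rho["est"] - (-0.3)), 0.08)
  # positively intercorrelated indicators load positively
  expect_true(all(fit$std_loadings[1:3, 1] > 0))
  expect_true(all(fit$std_loadings[4:6, 2] > 0))

  d0 <- gen(500, 0, 17)
  fit0 <- fit_caution_factor(d0$a_est, d0$wmc)
  expect_lt(abs(fit0$rho["est"]), 0.1)
})

test_that("missing indicators raise errors", {
  dat <- simulate_lds_indicators(100, seed = 1)
  expect_error(fit_lds(dat[, -2], lds_spec("t0", "switch")), "missing")
  est <- expand.grid(subject = 1:2, block = 1:2, s = 0:1, i = 0:1)
  est$family <- "v"; est$mean <- 1
  wmc <- data.frame(subject = 1:2, parcel_1 = 1, parcel_2 = 1,
                    parcel_3 = 1)
  expect_error(lds_indicators(est, wmc, "v", "switch"), "missing")
})
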