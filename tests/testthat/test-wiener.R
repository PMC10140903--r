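# Wiener first-passage core: densities, closed forms, simulation,
# contamination-mixture likelihood.

test_that("zero drift gives symmetric boundary densities", {
  p <- ddm_params(a = 2, v = 0, t0 = 0)
  tt <- c(0.05, 0.2, 0.5, 1, 2, 5)
  expect_equal(wfpt_density(tt, p, "upper"), wfpt_density(tt, p, "lower"),
               tolerance = 1e-12)
})

test_that("defective densities integrate to the absorption probabilities", {
  for (par in list(c(1.5, 1.2), c(2, 1), c(1, -0.8), c(2.5, 0))) {
    p <- ddm_params(a = par[1], v = par[2], t0 = 0)
    up <- integrate(function(t) wfpt_density(t, p, "upper"), 0, Inf,
                    rel.tol = 1e-9)$value
    lo <- integrate(function(t) wfpt_density(t, p, "lower"), 0, Inf,
                    rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, choice_probability(p, "upper"), tolerance = 1e-4)
    expect_equal(lo, choice_probability(p, "lower"), tolerance = 1e-4)
  }
})

test_that("choice probabilities match the gambler's-ruin closed form", {
  expect_equal(choice_probability(ddm_params(2, 0, 0), "upper"), 0.5)
  expect_equal(choice_probability(ddm_params(2, 0, 0), "lower"), 0.5)
  # a = 2, v = 1, s = 1: 1 / (1 + exp(-a v))
  expect_equal(choice_probability(ddm_params(2, 1, 0), "upper"),
               1 / (1 + exp(-2)), tolerance = 1e-10)
  # strictly increasing in drift
  pv <- sapply(seq(-1, 1, by = 0.25), function(v)
    choice_probability(ddm_params(2, v, 0), "upper"))
  expect_true(all(diff(pv) > 0))
})

test_that("mean decision times match the closed forms", {
  expect_equal(mean_decision_time(ddm_params(2, 0, 0)), 1.0)
  expect_equal(mean_decision_time(ddm_params(2, 1, 0)), tanh(1),
               tolerance = 1e-12)
  # decreasing in |v| at fixed a
  mdt <- sapply(c(0, 0.5, 1, 1.5, 2), function(v)
    mean_decision_time(ddm_params(2, v, 0)))
  expect_true(all(diff(mdt) < 0))
})

test_that("density evaluation is accurate and continuous across the series switch", {
  tt <- seq(0.01, 4, by = 0.002)
  for (par in list(c(1.5, 1.2), c(2, -1), c(0.8, 2))) {
    p <- ddm_params(par[1], par[2], 0)
    coarse <- wfpt_density(tt, p, "upper", err = 1e-11)
    fine <- wfpt_density(tt, p, "upper", err = 1e-15)
    expect_lt(max(abs(coarse - fine)), 1e-9)
  }
})

test_that("simulation is reproducible and matches closed-form moments", {
  p0 <- ddm_params(2, 0, 0.3, pi_cont = 0)
  s1 <- simulate_trials(2e4, p0, seed = 11)
  s2 <- simulate_trials(2e4, p0, seed = 11)
  expect_identical(s1, s2)

  n <- 1e5
  frac_up <- mean(simulate_trials(n, p0, seed = 12)$boundary == "upper")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac_up - 0.5), 3 * se)

  p1 <- ddm_params(2, 1, 0.3, pi_cont = 0)
  s <- simulate_trials(n, p1, seed = 13)
  se_rt <- sd(s$rt) / sqrt(n)
  expect_lt(abs(mean(s$rt) - (0.3 + tanh(1))), 3 * se_rt)
})

test_that("Euler path simulation agrees with inverse-CDF sampling", {
  p <- ddm_params(1.6, 1.2, 0.25, pi_cont = 0)
  a <- simulate_trials(8000, p, seed = 21)
  b <- simulate_trials(8000, p, seed = 22, method = "euler", dt = 5e-5)
  expect_lt(abs(mean(a$boundary == "upper") - mean(b$boundary == "upper")),
            0.02)
  ks <- suppressWarnings(ks.test(a$rt, b$rt))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate mixture produces uniform contaminants", {
  expect_error(ddm_params(2, 1, 0.3, pi_cont = 1), "pi_cont")
  p <- ddm_params(2, 1, 0.3, pi_cont = 0.999)
  s <- simulate_trials(5000, p, seed = 31, cont_window = c(0.25, 5))
  cont <- s[s$contaminant, ]
  expect_gt(nrow(cont), 4900)
  ks <- suppressWarnings(ks.test(cont$rt, "punif", 0.25, 5))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(cont$boundary == "upper") - 0.5), 0.03)
})

test_that("mixture log-likelihood follows its contract", {
  p <- ddm_params(1.8, 1.1, 0.3, pi_cont = 0)
  d <- wfpt_density(0.4, p, "upper")
  expect_equal(mixture_loglik(0.7, "upper", p, cont_window = c(0.2, 3)),
               log(d), tolerance = 1e-10)

  # an RT below t0: -Inf without contamination, finite with it
  p5 <- ddm_params(1.8, 1.1, 0.3, pi_cont = 0.05)
  rts <- c(0.25, 0.6, 0.8)
  bnd <- c("upper", "upper", "lower")
  expect_identical(mixture_loglik(rts, bnd, p, cont_window = c(0.2, 3)),
                   -Inf)
  expect_true(is.finite(mixture_loglik(rts, bnd, p5,
                                       cont_window = c(0.2, 3))))

  # invariant to trial order
  set.seed(41)
  s <- simulate_trials(500, p5, seed = 41)
  ord <- sample.int(500)
  expect_equal(mixture_loglik(s$rt, s$boundary, p5),
               mixture_loglik(s$rt[ord], s$boundary[ord], p5),
               tolerance = 1e-10)

  expect_error(mixture_loglik(numeric(0), character(0), p5), "no trials")
  expect_error(mixture_loglik(c(-1, 0.5), c("upper", "upper"), p5),
               "positive")
  expect_error(wfpt_density(c(0, 0.5), p5), "positive")
})

test_that("the likelihood peaks near the generating parameters", {
  truth <- ddm_params(1.6, 1.2, 0.3, pi_cont = 0.05)
  s <- simulate_trials(1e4, truth, seed = 51, cont_window = c(0.25, 5))
  ll <- function(a, v, t0)
    mixture_loglik(s$rt, s$boundary,
                   ddm_params(a, v, t0, pi_cont = 0.05),
                   cont_window = c(0.25, 5))
  grid <- expand.grid(a = seq(1.0, 2.2, 0.15), v = seq(0.4, 2.0, 0.2),
                      t0 = seq(0.15, 0.45, 0.05))
  vals <- mapply(ll, grid$a, grid$v, grid$t0)
  best <- grid[which.max(vals), ]
  expect_lt(abs(best$a - 1.6), 0.16)
  expect_lt(abs(best$v - 1.2), 0.21)
  expect_lt(abs(best$t0 - 0.3), 0.051)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(ddm_params(-1, 1, 0.3), "'a'")
  expect_error(ddm_params(2, NA, 0.3), "'v'")
  expect_error(ddm_params(2, 1, -0.1), "'t0'")
  expect_error(ddm_params(2, 1, 0.3, z_rel = 0.4), "start point")
  expect_error(ddm_params(2, 1, 0.3, s_diff = 0.1), "diffusion")
})
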