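# Cohort simulators: switching task and Recall-N-Back.

test_that("an injected non-decision-time increment appears in mean RT", {
  # deterministic population: only a 100 ms t0 switch increment, no drift
  # effects, so the correct-RT switch cost equals the increment
  spec <- population_spec(
    n_subjects = 25,
    means = c(t0_delta = 0.1, dv_switch = 0, dv_incon = 0),
    sds = c(t0_base = 0, t0_delta = 0, v_base = 0, dv_switch = 0,
            dv_incon = 0, a = 0, wmc = 0),
    block_effects = list(a = c(0, 0, 0), t0 = c(0, 0, 0), v = c(0, 0, 0)),
    pi_cont = 0)
  pop <- sample_population(spec, seed = 2)
  tr <- simulate_switch_task(pop, make_trial_list(3), seed = 4)
  tr <- tr[tr$phase == "test" & !tr$warmup & tr$accuracy == 1, ]
  d <- mean(tr$rt[tr$s == 1]) - mean(tr$rt[tr$s == 0])
  se <- sqrt(var(tr$rt[tr$s == 1]) / sum(tr$s == 1) +
             var(tr$rt[tr$s == 0]) / sum(tr$s == 0))
  expect_lt(abs(d - 0.1), 3 * se)
})

test_that("zero drift yields chance accuracy", {
  spec <- population_spec(
    n_subjects = 10,
    means = c(v_base = 0, dv_switch = 0, dv_incon = 0),
    sds = c(t0_base = 0, t0_delta = 0, v_base = 0, dv_switch = 0,
            dv_incon = 0, a = 0, wmc = 0),
    block_effects = list(a = c(0, 0, 0), t0 = c(0, 0, 0), v = c(0, 0, 0)),
    pi_cont = 0)
  pop <- sample_population(spec, seed = 5)
  tr <- simulate_switch_task(pop, make_trial_list(6), seed = 7)
  tr <- tr[tr$phase == "test" & !tr$warmup, ]
  expect_lt(abs(mean(tr$accuracy) - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("simulation is deterministic given seeds", {
  pop <- sample_population(population_spec(n_subjects = 3), seed = 1)
  tl <- make_trial_list(2)
  expect_identical(simulate_switch_task(pop, tl, seed = 9),
                   simulate_switch_task(pop, tl, seed = 9))
  expect_identical(simulate_rnb(pop, seed = 9), simulate_rnb(pop, seed = 9))
})

test_that("missing cell parameters are reported by cell", {
  pop <- sample_population(population_spec(n_subjects = 2), seed = 1)
  pop$cell_params <- pop$cell_params[
    !(pop$cell_params$subject == 2 & pop$cell_params$block == 3 &
        pop$cell_params$s == 1 & pop$cell_params$i == 1), ]
  expect_error(simulate_switch_task(pop, make_trial_list(1), seed = 1),
               "subject 2 lacks parameters.*3 1 1")
})

test_that("very high WMC saturates the Recall-N-Back score at 81", {
  spec <- population_spec(n_subjects = 4, means = c(wmc = 100),
                          sds = c(t0_base = 0, t0_delta = 0, v_base = 0,
                                  dv_switch = 0, dv_incon = 0, a = 0,
                                  wmc = 0))
  pop <- sample_population(spec, seed = 1)
  rnb <- simulate_rnb(pop, seed = 2)
  sc <- score_rnb(rnb)
  expect_true(all(sc$total == 81))
  expect_true(all(sc$parcel_1 == 27 & sc$parcel_2 == 27 &
                    sc$parcel_3 == 27))
})

test_that("a zero WMC slope removes the WMC-accuracy relation", {
  pop <- sample_population(population_spec(n_subjects = 300), seed = 3)
  rnb <- simulate_rnb(pop, link = rnb_link(b_wmc = 0), seed = 4)
  sc <- score_rnb(rnb)
  r <- cor(pop$subjects$wmc[match(sc$subject, pop$subjects$subject)],
           sc$total)
  expect_lt(abs(r), 0.15)
})

test_that("accuracy decreases with memory load", {
  pop <- sample_population(population_spec(n_subjects = 120), seed = 5)
  rnb <- simulate_rnb(pop, seed = 6)
  acc <- tapply(rnb$correct[rnb$phase == "test"],
                rnb$load[rnb$phase == "test"], mean)
  expect_true(all(diff(acc) < 0))
})

test_that("trial tables round-trip through CSV with unit conversion", {
  pop <- sample_population(population_spec(n_subjects = 2), seed = 1)
  tr <- simulate_switch_task(pop, make_trial_list(1), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  expect_equal(back$accuracy, tr$accuracy)
  tr_ms <- tr
  tr_ms$rt <- tr_ms$rt * 1000
  write_trials(tr_ms, path)
  back_ms <- read_trials(path, unit = "ms")
  expect_equal(back_ms$rt, tr$rt, tolerance = 1e-9)
  unlink(path)
})
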