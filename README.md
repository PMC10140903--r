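# switchddm

Diffusion-model decomposition of task-switching costs, and latent
difference score (LDS) models relating the component processes to
visuospatial working memory capacity (WMC).

## What it does, and for whom

Task-switching paradigms measure cognitive flexibility: responses are
slower and more error-prone when the classification rule changes from
one trial to the next (switch cost), and when the task-irrelevant
stimulus attribute maps onto the competing response (incongruency
cost). Mean RT confounds at least three processes. `switchddm` separates
them with the Wiener diffusion model — response caution *a* (boundary
separation), drift rate *ν* (evidence-accumulation efficiency), and
non-decision time *t₀* (encoding, motor output, and task-set
preparation) — and then asks, at the level of reliable latent factors,
how each component cost relates to WMC. It is written for researchers in
computational cognitive modeling and individual-differences psychology
who want a tested, reproducible pipeline from trial-level data (or a
fully specified synthetic cohort) to latent-variable conclusions.

The core quantities:

- **Wiener first-passage likelihood.** RT densities at the correct and
  error boundary under accuracy coding (start point fixed at *a*/2,
  diffusion coefficient 1), evaluated by the standard small-time /
  large-time series; a 5% uniform contaminant mixture keeps the
  likelihood finite for fast outliers.
- **Hierarchical Bayesian estimation** of a constrained model lattice
  M1–M6. The reference model M2 holds *a* constant within block, lets
  *t₀* vary by switch, and *ν* by switch × congruency. Convergence is
  checked by Gelman–Rubin R̂, model adequacy by posterior predictive
  MSE on accuracy and RT quantiles.
- **LDS models.** Per block, the changed condition's indicator loads on
  a baseline factor B and a change factor Δ with equal loading, under
  strict measurement invariance; Δ's mean and variance are the reliable
  task-switch (or incongruency) effect, correlated with a WMC factor
  measured by three parallel Recall-N-Back parcels. The 9-indicator
  models have 28 degrees of freedom.

## Worked example

```r
library(switchddm)

# a synthetic cohort with known latent structure (the defaults encode a
# 298 ms baseline t0, an 88 ms switch increment, and a -0.405 latent
# correlation between WMC and that increment)
pop    <- sample_population(population_spec(n_subjects = 40), seed = 1)
trials <- simulate_switch_task(pop, make_trial_list(1), seed = 2)
rnb    <- simulate_rnb(pop, seed = 3)

fit <- fit_ddm(trials, "M2", draws = 500, burnin = 300, seed = 4)
round(coef(fit)[c("t0_b1_s0", "t0_b1_s1", "v_b1_s0_i0", "v_b1_s1_i1")], 3)
#>   t0_b1_s0   t0_b1_s1 v_b1_s0_i0 v_b1_s1_i1
#>      0.296      0.375      1.853      1.041

est <- subject_estimates(fit)
wmc <- score_rnb(rnb)
lds <- fit_lds(lds_indicators(est, wmc, "t0", "switch"),
               lds_spec("t0", "switch"))
lds
#> Latent difference score model (switch effect, t0), n = 40
#>   chi2(28) = 41.26, p = 0.051; RMSEA = 0.109 [0.000; 0.187]; SRMR = 0.039; CFI = 0.974; TLI = 0.966
#>   i_B = 0.295 (p = 0.000), i_Delta = 0.080 (p = 0.000)
#>   rho1(B,Delta) = 0.209, rho2(WMC,B) = 0.031, rho3(WMC,Delta) = -0.473
```

Read: the model reproduces the generated structure — a 295 ms baseline
non-decision time against a generating 298 ms, an 80 ms reliable switch
increment (`i_Delta`) against a generating 88 ms, and a negative latent
correlation between WMC and the increment (`rho3`, generated at
−0.405; at n = 40 the estimate is noisy — the packaged recovery studies
quantify this over many cohorts at larger n). The cell
means, effect scores, repeated-measures ANOVAs and the latent caution
model are available through `run_pipeline()`:

```r
rep <- run_pipeline(pipeline_config(seed = 1, n_subjects = 40,
                                    draws = 500, burnin = 300))
print(rep)
```

`recovery_study()` repeats simulate-and-fit over independent cohorts and
reports bias/RMSE of the group t₀ switch increment, rank correlations of
subject-level increments, and how often posterior predictive MSE selects
the generating model against the equal-t₀ alternatives M1/M3.

## Data in and out

Trial-level CSVs use the documented column schema (`subject`, `block`,
`s`, `i`, `accuracy`, `rt` in seconds; `read_trials(..., unit = "ms")`
converts milliseconds). Subject-estimate tables round-trip through
`write_estimates()`/`read_estimates()` at full precision. Configurations
serialize to YAML via `write_config()`/`read_config()`.
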