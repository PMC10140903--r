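---
title: "Decomposing task-switching costs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing task-switching costs: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchddm)
```

## The scientific problem

Switching between two classification tasks carries a measurable cost:
responses on task-switch trials are slower and more error-prone than on
task-repeat trials, and responses are further slowed when the stimulus
attribute that is irrelevant to the current task maps onto the competing
response (response incongruency). Mean response times conflate several
processes — preparation before evidence accumulation starts, the
efficiency of accumulation itself, and the speed–accuracy trade-off. This
package decomposes the costs with a diffusion model and then asks, at the
level of reliable latent variables, how the component costs relate to
visuospatial working memory capacity (WMC) measured by a Recall-N-Back
task.

## The diffusion model

A two-choice decision is modeled as a Wiener process with drift $\nu$
between absorbing boundaries $0$ and $a$, starting at $a/2$ (accuracy
coding: the upper boundary is the correct response, so an unbiased start
point is the natural fixed choice — the paradigm gives no reason to favor
one *response* a priori, and no bias parameter is estimated). The
within-trial diffusion coefficient is fixed at $s = 1$, which defines the
scale of $a$ and $\nu$; inter-trial variabilities are fixed at zero.
Observed response time is the first-passage time plus a non-decision time
$t_0$ capturing encoding, motor output and — critically for task
switching — task-set preparation.

The first-passage density is evaluated with the standard pair of
alternating series (a small-time and a large-time representation), with
the number of terms chosen per evaluation so the absolute truncation
error stays below the requested tolerance ($10^{-11}$ by default; the
two branches consequently agree to well below $10^{-9}$ at the automatic
switch point). Choice probabilities and mean decision times have closed
forms — $P(\text{upper}) = 1/(1+e^{-a\nu})$ and
$\mathbb{E}[T_d] = (a/2\nu)\tanh(a\nu/2)$ for the unbiased start — which
the test suite uses as independent oracles for both the density and the
simulator.

A fixed 5% of trials are treated as contaminants: uniform in time over a
window with responses at chance. In the likelihood the window defaults to
each subject's observed RT range; in simulation it is a configurable
window (default 0.25–5 s). The mixture keeps the likelihood finite for
responses faster than $t_0$, which otherwise would have zero density.

Trial simulation draws decision times by numerical inversion of the
first-passage distribution (trapezoid-integrated on a 2048-point grid; a
512-point grid is used inside posterior predictive replicates where the
interpolation bias is common to all compared models). An independent
Euler–Maruyama path simulator is included and cross-checked against the
inverse-CDF sampler in the tests, so the two routes validate each other.

## The model lattice and hierarchical estimation

Design cells are block (1–3) × switch (repeat/switch) × congruency.
The lattice of estimable models varies which cells each parameter family
distinguishes:

| model | caution $a$ | non-decision $t_0$ | drift $\nu$ |
|-------|-------------|--------------------|-------------|
| M1 | block | block | block × s |
| M2 | block | block × s | block × s × i |
| M3 | block | block | block × s × i |
| M4 | block × s | block | block × s × i |
| M5 | block × s | block × s | block × s |
| M6 | block × s | block × s | block × s × i |

M2 is the parsimonious reference model: caution equal across the trial
types of a block (the upcoming trial type is unpredictable, so no
cell-wise criterion adjustment is possible), non-decision time varying
only with switch (preparation is confined to switches), and drift free
over the full crossing. M1 and M3 force equal non-decision times across
switch and repeat trials and serve as the critical misfit contrasts. The
composition of the remaining lattice members is a documented
reconstruction spanning the allowed parameter families up to the full
crossing (M6); only M2's composition and the equal-$t_0$ property of
M1/M3 are substantively constrained.

Estimation is hierarchical Bayes: subject-level cell parameters on
transformed scales (log for $a$ and $t_0$, identity for $\nu$) are drawn
around normal population distributions per cell. The sampler is adaptive
Metropolis-within-Gibbs — scalar random-walk updates of subject
parameters tuned to a ~40% acceptance rate during burn-in, and conjugate
normal/inverse-gamma draws of the population means and variances
(mean hyperprior: normal with SD 1.5 on the log scales and 3 for drift;
variance prior: inverse-gamma(2, 0.2)). With a single subject the
population model is replaced by fixed weakly-informative priors. Any
correct sampler is acceptable for this model class; the implementation
is validated by (i) agreement with a grid/ML oracle on a single subject
with $10^4$ trials, (ii) ground-truth recovery of the group-level
non-decision-time increment across synthetic cohorts, and (iii) the
Gelman–Rubin statistic. The reported $\widehat R$ is the classic
multi-chain form $\sqrt{1 + (1+1/m)\,B/((n-1)W)}$, which equals exactly 1
for identical chains; split-chain and rank-normalized variants are
available as options.

Posterior predictive checking simulates the full design from randomly
drawn posterior iterations and compares observed and replicate-mean
summaries per subject and design cell: accuracy and the .1/.3/.5/.7/.9
RT quantiles of correct and of error responses. Quantiles enter only for
response types with at least 16 trials in a cell (half a typical cell):
order statistics of a handful of errors are dominated by sampling noise
and would dilute the mean-squared-error comparison between models rather
than inform it. The same observed-element set is used for every compared
model, so the MSEs are directly comparable.

The probability that two parameters differ is reported as the folded
exceedance $2\,|\Pr(\theta_a > \theta_b) - 0.5|$ over pooled draws (0 =
indistinguishable, 1 = fully separated); the one-sided mass is available
via `folded = FALSE`.

## Conventional scores

Latencies of correct trials are scored as speed $1/\mathrm{RT}$
(responses per second, the per-trial reciprocal averaged within cell —
the literal reading of the transform; the reciprocal of the mean is
available as an option), and error rates are probit-transformed with the
edge correction $(e + 0.5)/(n + 1)$ so empty and full cells stay finite.
Effect scores come in global (averaged over the other factor) and
specific (only the baseline level of the other factor) forms. The
repeated-measures ANOVAs use subject-by-term error strata with
unadjusted degrees of freedom, and partial eta squared
$SS_e/(SS_e+SS_{err})$; the implementation delegates to `aov()` and is
verified against an explicit inclusion-exclusion sums-of-squares oracle.
All scored trials enter the cell means by default — whether trials after
an error should be excluded is a genuinely open convention, so it is an
explicit flag (`exclude_post_error`) rather than a silent default.

The Recall-N-Back is scored by partial credit — every correct recall
response counts — over the nine test blocks with load ≥ 2 (load-one
blocks require no memory updating), for a maximum of
$3 \times (6+9+12) = 81$. Three parallel parcels are built by a fixed
Latin square over load × update count, so each parcel contains one block
of every load and one of every update count (maximum 27 each).

## Latent difference score models

For each diffusion parameter (and, identically, for observed scores) the
baseline condition is the congruent task-repeat cell per block, and the
changed condition is the congruent task-switch cell (switch contrast) or
the incongruent task-repeat cell (incongruency contrast). The changed
indicator loads on both the baseline factor B and the change factor Δ
with the same block loading; within a block the pair shares loading,
intercept and residual variance (strict measurement invariance), and the
paired residuals may covary because both indicators come from the same
block. WMC is measured by the three parcels. Identification fixes the
block-1 loading to 1 and the block-1 intercept to 0, so the latent means
of B and Δ are in the indicator's own units (seconds of non-decision
time, drift units); the WMC factor mean is fixed at 0 with free parcel
intercepts. Nine indicators give 54 observed moments; with 26 free
parameters the model has 28 degrees of freedom. Parcel residuals are
uncorrelated (no covariances are freed).

Estimation is normal-theory maximum likelihood with mean structure,
written directly on the implied moments
$\Sigma = \Lambda\Psi\Lambda' + \Theta$, $\mu = \nu + \Lambda\alpha$
with equality constraints through shared parameter labels. The
discrepancy uses the ML ($n$-divisor) covariance, so $\chi^2 = nF$;
standard errors come from the numerical Hessian, and latent correlations
carry delta-method standard errors. Internally the indicator groups are
rescaled to unit-order variance before optimization — a pure
reparameterization that leaves $\chi^2$, df, correlations and all fit
indices unchanged and removes the 1000-fold variance gap between
non-decision-time indicators and count-valued parcels. RMSEA uses $n$
(not $n-1$) in the denominator and a 95% confidence interval from
inverting the noncentral chi-square; SRMR averages squared standardized
residuals over the unique covariance and mean elements; CFI/TLI use the
free-variance independence baseline. For a saturated model RMSEA is
defined as 0 and CFI as 1. TLI is not capped at 1.

The latent caution model treats the three block-level caution estimates
as indicators of one factor, correlated with the WMC parcel factor;
means are saturated and the model has 8 degrees of freedom.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested. One subject is seven latents — baseline $t_0$, its switch
increment, baseline drift, drift decrements for switch and incongruency,
caution, and WMC — drawn multivariate-normal with user-specified
correlations. Defaults reproduce the reference mean structure: baseline
$t_0$ 298 ms with an 88 ms switch increment; baseline drift 1.938 with
decrements −0.293 (switch) and −0.619 (incongruency); WMC correlations
−0.405 with the $t_0$ increment, −0.011 with baseline $t_0$, 0.301 and
−0.269 with the drift change factors, −0.28 with caution. Caution
defaults to 1.70: together with the default drift this implies a
congruent-repeat accuracy of ~0.96 and a mean RT of ~0.70 s, matching
the empirically typical first-block cell. Latent SDs (60/50 ms for the
$t_0$ latents, 0.45/0.25/0.30 drift units, 0.35 caution) are chosen so
that simulated between-subject spreads of cell means and effect scores
land in the plausible range for young-adult cohorts. Block effects are
additive practice shifts (caution 0/−0.12/−0.18; $t_0$ 0/−15/−30 ms;
drift 0/+0.05/+0.15) applied to the baselines only, so the generating
switch increment is constant across blocks. Cell parameters are
truncated at $a \ge 0.3$ and $t_0 \ge 30$ ms; under the defaults fewer
than 1% of values are touched.

Trial lists mirror the paradigm: two task-pure blocks of 44 trials, a
24-trial mixed practice block, and three test blocks of 128 scored
trials preceded by 8 warm-up trials, with exactly 32 trials per switch ×
congruency cell per block and the switch flag of the first scored trial
defined against the last warm-up trial. The original pseudo-random
lists' constraints are not fully reported; we balance cells exactly and
cap identical-task runs at four trials to avoid degenerate sequences —
a documented choice, not an inferred one. The same list is used for all
subjects, as in the standardized paradigm. Error feedback and forced
corrections affect only the procedure, not the first response; the
generator simulates first-response RT and accuracy only.

Recall-N-Back data are generated from a logistic accuracy model —
intercept 2.2, slope 0.9 per WMC SD, −0.55 per load step, −0.01 per
update position — yielding mean accuracies of roughly .84/.71/.57 at
loads 2–4 and a WMC-graded score distribution. The reference analysis
fits no such model; it exists purely so the synthetic scores carry the
latent structure the LDS stage is supposed to find. What passing tests
show is therefore that the pipeline recovers structure *of the kind the
generator builds in* (normal latents, additive cell effects, logistic
link); real data can depart from all of these (skewed latents,
load-specific strategies, non-stationary practice effects), and the
tests make no claim about those departures.

## Numerical and design choices

- **RT unit.** Seconds everywhere; the CSV reader converts milliseconds
  on request (`unit = "ms"`).
- **Density tolerance.** $10^{-11}$ for direct evaluation and
  simulation tables; $10^{-7}$ inside the MCMC sampler, where the
  likelihood-difference noise floor is far above it.
- **Sampler sizes.** The reference configuration is 10,000 kept draws
  with 1,000 burn-in and 2 chains. The packaged recovery studies and
  tests use scaled-down chains (hundreds of draws) with the cohort sizes
  stated alongside each result; recovery quality at those sizes is
  itself what the tests certify.
- **Ties and degenerate inputs.** Cells without correct trials get
  missing speed/mean-RT and a flag; all-equal ANOVA responses define
  $F = 0$, $p = 1$ (the 0/0 case); identical MCMC chains give
  $\widehat R = 1$ exactly; a saturated SEM reports $\chi^2 = 0$,
  df = 0, RMSEA 0, CFI 1.
- **Estimates serialization.** Full 17-digit precision, so CSV
  round-trips are bit-identical.
- **Interface.** The package is organized as a classic modelling
  package: two fitting functions returning classed objects
  (`fit_ddm()`, `fit_lds()`) with `print`/`summary`/`coef` methods,
  plus `run_pipeline()`/`recovery_study()` as the orchestration layer.
  Users drive it from R; no shell entry point is provided.

## Known limitations

- Inter-trial parameter variabilities, start-point bias and contaminant
  proportion are fixed, not estimated; data generated with substantial
  bias or variability will be absorbed into the core parameters.
- The ML SEM engine handles complete cases only (no FIML), assumes
  multivariate normality, and offers no robust corrections — adequate
  for the generated indicator distributions, optimistic for heavily
  skewed real scores.
- The scalar-update sampler mixes more slowly than gradient-based
  samplers for strongly correlated posteriors; the convergence
  diagnostics are there to be looked at, not assumed.
- Posterior-mean indicators entering the LDS stage carry hierarchical
  shrinkage; with few trials per cell this attenuates between-subject
  variance and can bias latent correlations toward zero relative to
  fitting everything jointly.
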