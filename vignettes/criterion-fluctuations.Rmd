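---
title: "Modelling trial-to-trial criterion fluctuations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-to-trial criterion fluctuations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the generative
model and its assumptions, the inference algorithm, the parameters that
matter and their defaults, the design decisions that were genuinely open,
and what the simulation-based validation does and does not establish.

## The generative model

A binary response on trial $t$ of subject $i$ follows

$$y_{it} \sim \mathrm{Bern}\!\left(f(w_i^\top u_{it} + x_{it})\right),
\qquad f(z) = \frac{1}{1+e^{-z}},$$

where $u_{it} \in \mathbb{R}^p$ are observed covariates and
$x_{it}$ is the latent decision criterion. Adding a drifting value to the
log-odds is mathematically identical to comparing a decision variable to a
drifting criterion, which is why a signal-detection reader can interpret
$x_t$ directly as (minus) the criterion. The criterion follows an AR(1)
process

$$x_{it} = b_i + a_i x_{i,t-1} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma_i^2),$$

with persistence $a_i \in [0,1]$ and innovation variance $\sigma_i^2$.
Two reparametrizations keep the model well-behaved:

* the intercept is never free: $b_i = \mu_{x,i}(1-a_i)$, so
  $\mu_{x,i}$ — the mean of the criterion trajectory, i.e. the subject's
  overall bias — is the estimated quantity;
* the inverse-gamma population distribution of the $\sigma_i^2$ is
  parametrized by its mean $\mu_{\sigma^2}$ and scale $\beta_{\sigma^2}$,
  with shape $\alpha_{\sigma^2} = \beta_{\sigma^2}/\mu_{\sigma^2} + 1$
  derived, which decorrelates the otherwise strongly coupled shape and
  scale estimates.

The hierarchy pools strength across subjects:
$w_i \sim N(\mu_w, \mathrm{diag}(\sigma_w^2))$,
$a_i \sim \mathrm{TruncNorm}(\mu_a, \sigma_a^2, [0,1])$,
$\sigma_i^2 \sim \mathrm{IGa}(\alpha_{\sigma^2}, \beta_{\sigma^2})$,
$\mu_{x,i} \sim N(0, \sigma_{\mu x}^2)$. Negative persistence is excluded
because it would produce trial-to-trial criterion jumps rather than the
slow drift being modelled; values above 1 are non-stationary.

### The initial state

The AR(1) law determines every state given the previous one, but not the
first. Three conventions are implemented (`init` in the simulator, the
filter, and `sampler_config()`):

* **`"innovation"`** (default): $x_1 \sim N(\mu_{x,i}, \sigma_i^2)$.
* **`"stationary"`**: $x_1 \sim N(\mu_{x,i}, \sigma_i^2/(1-a_i^2))$.
* **`"fixed"`**: $x_1$ set to a supplied value.

The stationary start is the textbook choice and makes $\mu_{x,i}$ the
marginal mean at every trial, but its variance diverges as $a_i \to 1$.
Under the reference population ($\mu_a = 0.98$, $\mathrm{sd}_a = 0.03$,
truncated at 1) roughly one subject in fifty draws $a_i > 0.999$, where
the stationary standard deviation exceeds 3 logits even at
$\sigma_i^2 = 0.1$: such simulated observers start saturated and emit
hundreds of identical responses, carrying no information about their
weights. The innovation start keeps $\mu_{x,i}$ the marginal mean at
every trial and $\sigma_i^2$ the fluctuation scale at every horizon while
remaining well-defined at $a_i = 1$, so it is the default for both
simulation and inference. Simulation and inference always share one
convention — the filter's first-trial prior is exactly the simulator's
first-state law.

## Posterior inference

The sampler is an augmented, blocked Gibbs sweep. Per subject:

1. **Pólya-gamma auxiliaries.** $\omega_t \sim \mathrm{PG}(1, \psi_t)$
   with $\psi_t = w^\top u_t + x_t$. Conditional on $\omega$, the
   Bernoulli likelihood is Gaussian in $\psi$ with pseudo-observation
   $\kappa_t/\omega_t$ ($\kappa_t = y_t - \tfrac12$) and noise variance
   $1/\omega_t$. The sampler is the exact Devroye alternating-series
   method for the $b=1$ case (implemented in C++ on R's RNG stream); a
   truncated sum-of-gammas representation (≥ 200 terms) is kept as an
   approximate fallback and as an independent cross-check.
2. **Trajectory.** Forward filtering / backward sampling on the
   conditionally linear-Gaussian chain draws $x_{1:T}$ exactly from its
   joint conditional. The Kalman update is computed in a form using
   $h_t = \kappa_t - \omega_t w^\top u_t$ that stays finite as
   $\omega_t \to 0$; note that at $\omega_t = 0$ the *linear* tilt
   $e^{\kappa_t x_t}$ of the augmented likelihood remains, so only the
   filtering variances (not the means) revert to the AR(1) prior
   marginals.
3. **Weights.** Exact multivariate-normal conditional with precision
   $\mathrm{diag}(1/\sigma_w^2) + \sum_t \omega_t u_t u_t^\top$.
4. **Persistence $a_i$.** The truncated-normal prior is conjugate with
   the AR(1) regression of centered states. Under the innovation or fixed
   start this conditional is exact; under the stationary start the first
   state's $\sqrt{1-a^2}$ factor breaks conjugacy, and the conjugate draw
   is used as an independence-Metropolis proposal accepted against that
   factor (acceptance is near 1 at realistic $T$), so the chain still
   targets the exact joint.
5. **Variance $\sigma_i^2$.** Exact inverse-gamma conditional; the first
   state contributes $\tfrac12$ to the shape and
   $(x_1-\mu_x)^2/2$ (innovation) or $(1-a^2)(x_1-\mu_x)^2/2$
   (stationary) to the scale.
6. **Trajectory mean $\mu_{x,i}$.** Exact Gaussian conditional; the mean
   enters every transition through $b = \mu_x(1-a)$ and the first-state
   law.

Globally, $\mu_w$, $\sigma_w^2$ and $\sigma_{\mu x}^2$ have closed-form
conjugate updates, while $(\mu_a, \sigma_a^2, \mu_{\sigma^2},
\beta_{\sigma^2})$ are updated by scalar random-walk Metropolis–Hastings
with symmetric Gaussian proposals; proposals violating positivity or the
$[0,1]$ domain are rejected, and acceptances are logged per iteration.
The update order within a sweep is fixed (auxiliaries → trajectory →
weights → $a$ → $\sigma^2$ → $\mu_x$ → globals); blocked-Gibbs validity
does not depend on the order, but bit-reproducibility under a seed does.

The whole transition kernel is validated by a joint-distribution
(Geweke-style) test in the test suite: alternating forward simulation of
responses with Gibbs sweeps on a 2-subject, 50-trial configuration leaves
every parameter's marginal indistinguishable from its prior. This test is
sensitive to essentially any error in any conditional, which is why the
exactness of the initial-state treatment above matters.

### Variants

Two switches reproduce reduced models used in the confound analyses:
`estimate_fluctuations = FALSE` freezes $x_t \equiv \mu_{x,i}$, reducing
the model to hierarchical logistic regression with a random intercept
(the "fixed criterion" fit); `fixed_a` clamps every $a_i$ (e.g. at
0.9995, the near-random-walk assumed by earlier single-subject
approaches) and skips the corresponding updates.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `iterations`, `burn_in` | 1000, 250 | enough for stable posterior means at the reference design; all chains single-run |
| `mh_steps` | (0.01, 0.005, 0.05, 0.1) | starting proposal SDs for $(\mu_a, \sigma_a^2, \mu_{\sigma^2}, \beta_{\sigma^2})$ |
| `adapt` | TRUE | Robbins-Monro-style step rescaling every 25 burn-in sweeps toward ~0.3 acceptance, frozen at burn-in end so detailed balance holds for all retained samples |
| `init` | "innovation" | see above |
| `traj_max_draws` | 200 | thinned trajectory draws kept for credible bands; the posterior mean uses every post-burn-in sweep |

### Hyperpriors

The group-level parameters need proper priors for every conditional to be
well-defined; the constants live in `hyperprior_config()` and can be
replaced wholesale. The defaults are broad: $N(0, 25)$ on each weight
mean, IG(2, 1) on weight variances, IG(2, 0.5) on $\mu_{\sigma^2}$,
$\beta_{\sigma^2}$ and $\sigma_{\mu x}^2$. Two choices deserve note:

* **$\mu_a$ is given a normal prior truncated to $[0,1]$** (location 0.5,
  scale 1 — nearly flat on the unit interval). When the $a_i$ pile up
  near 1, the truncated-normal likelihood has a ridge trading location
  against scale, and an unbounded location wanders far above 1 while the
  implied distribution on $[0,1]$ barely changes; truncating keeps the
  location interpretable as a persistence level and the chain
  well-behaved.
* **$\sigma_a^2$ gets IG(1, 0.01)** — heavy-tailed with mode near 0.003.
  Population spreads of persistence are small on the $a$ scale (a
  standard deviation of 0.03 means $\sigma_a^2 \approx 10^{-3}$); an
  inverse-gamma with mean far above that scale is accidentally
  informative upward, so the prior is chosen to span
  $\sigma_a \in [0.005, 0.3]$ without favoring the top.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the reference study design: per-subject
parameters drawn from the hierarchy above, i.i.d. standard-normal
covariates, and Bernoulli responses through the logistic link. A master
seed expands into per-subject L'Ecuyer-CMRG substreams, so growing the
dataset does not perturb earlier subjects' draws.

Real data differ in ways the generator deliberately ignores: covariates
are not i.i.d. Gaussian (stimulus designs are blocked and discrete,
previous-response covariates are autocorrelated by construction), there
are session breaks across which the criterion need not evolve smoothly,
lapses and finger errors contaminate the link, and the true criterion
dynamics need not be AR(1). Passing recovery tests on simulated data
therefore establishes *computational* correctness — the sampler inverts
the model that generated the data — not that the AR(1) form is right for
any particular dataset. The history-bias experiment partially probes
robustness to non-Gaussian covariates, since its previous-response
covariate is generated sequentially from the realized responses.

## Validation design and problem sizes

The test suite validates in layers, from exact to statistical:

1. closed-form values (logistic, reparametrizations, d′, correlations);
2. dense-Gaussian oracles for the filter and the FFBS joint law at tiny
   $T$, to 10 decimals;
3. 1-D grid oracles for every per-subject conditional and for the
   stationary law of the Metropolis kernels (KS < 0.05 on 5000 draws at
   $T = 200$);
4. the joint-distribution (Geweke-style) test of the full kernel;
5. recovery studies at the reference design — two replicate 50 × 500
   datasets for weight (r ≥ .98), AR-parameter (r ≈ .70/.68/.63 bands)
   and trajectory (mean r ≥ .83) recovery, a 20 × 5000 dataset for the
   high-trial persistence level, and ten 15 × 300 datasets for
   credible-interval coverage tested as binomial consistency with 92%;
6. the confound experiments at 10 subjects × 400–500 trials: monotone
   inflation/deflation under the fixed-criterion fit, interval coverage
   of the generative weights under the full fit, and the paired
   superiority of free over clamped persistence.

These sizes are the package's own validation choices: large enough that
the documented patterns are stable across seeds, small enough that the
full suite runs on a laptop in minutes. `scripts/acceptance.R` re-runs
the pipeline at the 50-subject reference design from a caller-supplied
seed.

## Numerical choices

* Filtering variances are floored at $10^{-12}$; degenerate transitions
  ($a = 0$ or $\sigma^2 = 0$) take exact branches in the backward kernel.
* Truncated-normal draws use the inverse-CDF method, which does not stall
  when the location sits near or beyond a boundary; draws of $a$ are
  capped at $1 - 10^{-9}$ so downstream stationary-variance expressions
  stay finite.
* The truncated-normal log-normalizer is computed in the better Gaussian
  tail, so Metropolis targets stay finite for locations far outside
  $[0,1]$.
* Metropolis acceptance treats non-finite proposal log-densities as
  rejections (and escapes a non-finite current state), and always
  consumes one uniform so the RNG call sequence is configuration-stable.
* Point estimates are posterior means over post-burn-in samples;
  credible intervals are equal-tailed (percentile) rather than HPD —
  simplest well-defined choice, configurable via `credible_interval()`.
* Initialization: per-subject logistic fits for $w_i$ (clipped to ±5),
  $a_i = 0.9$, $\sigma_i^2 = 0.1$, $\mu_{x,i}$ at the clipped logit of
  the response mean, flat trajectories. Cheap; overdispersion is handled
  by burn-in.

## Application defaults

* The previous-response covariate is coded $\{-1, +1\}$ (first trial 0),
  so a positive weight means repetition — the standard convention in the
  choice-history literature.
* The fluctuation-condition grid spans none → strong drift:
  $(a, \sigma^2) \in \{(0,0), (0.9,0.1), (0.97,0.15), (0.99,0.2),
  (0.995,0.3)\}$; configurable, as is the single signed evidence level of
  the d′ demonstration (default magnitude 0.7, which puts the
  no-fluctuation d′ near 1.1 at the generative slope 1.25).
* The free-vs-clamped persistence experiment draws
  $a_i \sim U[0.81, 0.96]$ and $\sigma_i^2 \sim U[0.05, 0.35]$ — the
  ranges typical of empirical fits — and clamps at 0.9995.

## Known limitations

* Only the intercept drifts; covariate weights are static. Fluctuating
  sensitivities would need a multivariate latent state.
* Reaction times are not modelled; only choices inform the trajectory.
* Single-chain design: convergence is assessed by within-chain
  autocorrelation and the Geweke validation, not cross-chain R-hat.
* Sessions are assumed gapless; missing trials are not handled.
* At 500 trials the dynamics parameters $(a_i, \sigma_i^2, \mu_{x,i})$
  are recovered far less precisely than the trajectory itself; users
  interpreting those parameters should consult the recovery levels above
  and prefer more subjects over more trials for group-level inference.
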