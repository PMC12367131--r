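# hmfc — hierarchical estimation of criterion fluctuations

Binary-choice observers are usually modelled as comparing a decision
variable against a *fixed* decision criterion. A growing body of evidence
says the criterion drifts slowly from trial to trial instead — and
ignoring that drift has real consequences: it manufactures *apparent*
choice-history bias (a spurious tendency to repeat the previous response),
and it deflates both the psychometric slope and d′, the standard
signal-detection measure of sensitivity.

`hmfc` implements a hierarchical Bayesian state-space model (a Bernoulli
linear dynamical system) that estimates the latent criterion trajectory of
every subject along with the parameters governing its dynamics, pooling
strength across subjects so that ~500 trials per subject suffice. It is
aimed at psychophysicists and cognitive neuroscientists who need either to
*control for* criterion drift (unbiased history and sensitivity estimates)
or to *study* it (trial-resolved criterion states for neural analyses).

## The model

On trial *t*, subject *i* responds

y_it ~ Bernoulli( f( wᵢᵀ u_it + x_it ) ),     f(z) = 1 / (1 + e^−z),

where `u_it` are observed covariates (stimulus evidence, previous
response, ...), `wᵢ` their weights, and `x_it` the latent criterion,
which follows an AR(1) process

x_it = bᵢ + aᵢ x_i,t−1 + ε_it,     ε_it ~ N(0, σᵢ²),

with persistence `aᵢ ∈ [0, 1]`, fluctuation variance `σᵢ²`, and intercept
derived from the trajectory mean, bᵢ = μ_x,i (1 − aᵢ). Per-subject
parameters share hierarchical priors:

- wᵢ ~ N(μ_w, diag(σ_w²))
- aᵢ ~ TruncNorm(μ_a, σ_a², [0, 1])
- σᵢ² ~ InvGamma(α_σ², β_σ²), with α_σ² = β_σ²/μ_σ² + 1 derived
- μ_x,i ~ N(0, σ_μx²)

Inference is an augmented, blocked Gibbs sampler: Pólya-gamma auxiliaries
make the Bernoulli likelihood conditionally Gaussian, the trajectory is
drawn exactly by forward filtering / backward sampling, the per-subject
parameters have conjugate conditionals, and the group-level parameters are
updated in closed form or by random-walk Metropolis–Hastings. The exact
Devroye Pólya-gamma sampler and the Kalman recursions are implemented in
C++ (Rcpp); a 50-subject × 500-trial fit of 1000 iterations takes well
under a minute on one CPU.

## Worked example

```r
library(hmfc)

sim <- simulate_dataset(default_hyper_params(), n_subjects = 20,
                        n_trials = 500, seed = 1)
fit <- fit_hmfc(sim, sampler_config(iterations = 600, burn_in = 200),
                seed = 2)
fit
#> Hierarchical criterion-fluctuation fit
#>   subjects:    20
#>   iterations: 600 (burn-in 200)
#>   posterior mean group-level parameters:
#>      mu_w_1      mu_w_2      mu_w_3  sigma2_w_1  sigma2_w_2  sigma2_w_3
#>     0.36500     0.00171    -0.48200     1.41000     1.11000     1.15000
#>        mu_a    sigma2_a   mu_sigma2 beta_sigma2  sigma2_mux
#>     0.98700     0.00322     0.20400     0.61200     0.24900
#>   MH acceptance (post burn-in): mu_a 0.32, sigma2_a 0.29, mu_sigma2 0.53, beta_sigma2 0.33

recovery_report(fit, sim)
#> Recovery report
#>   parameter recovery correlations:
#>    w_1    w_2    w_3      a sigma2   mu_x
#>  0.989  0.992  0.988  0.899  0.496  0.556
#>   trajectory: mean correlation 0.842 , mean RMSE 0.81
#>   group-level 95% CI covers truth: 10 / 11 parameters
```

The report compares posterior means against the generator's ground truth:
covariate weights recover almost perfectly (r ≈ .99) even at 500 trials;
the AR(1) dynamics parameters are harder at this trial count but the
latent criterion *trajectory* itself — the quantity most analyses need —
is recovered at r ≈ .84 on average. `trajectory_summary(fit)` gives
per-trial posterior means with credible bands, and `plot_trajectory()` /
`plot_recovery()` draw the standard overlay and scatter figures.

The confound demonstrations live in `history_bias_experiment()` (apparent
repetition bias under unmodelled drift, and its correction),
`sensitivity_experiment()` (psychometric-slope and d′ shrinkage), and
`fixed_vs_free_a_experiment()` (why the persistence must be a free
parameter rather than clamped near a random walk).

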