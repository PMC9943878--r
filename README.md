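# odenoise

Parameter inference for ODE models of biological systems when the
measurement noise is **autocorrelated**.

## The problem

Fitting an ODE model `dx/dt = h(t, x, θ)` to a noisy time series
`y(t_i) = f(t_i; θ) + ε(t_i)` almost always assumes the errors are
independent Gaussian draws. But measurement processes — a patch-clamp
amplifier that responds sluggishly, an electrochemical sensor sampled at
kilohertz rates — leave *persistent* imprints: consecutive errors are
correlated. Pretending such errors are independent does not merely
misestimate the noise; it makes parameter uncertainties artificially
small, because each correlated observation carries less information than
an independent one would.

`odenoise` quantifies and repairs this. Its core quantity is the
**variance inflation ratio (VIR)**: the ratio of the true asymptotic
variance of a maximum-likelihood parameter estimate under the actual
(ARMA) noise process to the variance claimed under the false IID
assumption (with the false model's noise scale matched to the true
process variance). For the constant-mean model `x(t) = μ + ε(t)`:

| noise process | VIR for μ |
|---|---|
| AR(1), coefficient ρ | `(1 + ρ) / (1 − ρ)` |
| MA(1), coefficient ϕ | `1 + 2ϕ / (1 + ϕ²)` (maximum 2 at ϕ = 1) |
| ARMA(1,1) | AR(1) VIR × `(1 + 2ϕ(1 − ρ) / (1 + ϕ² + 2ϕρ))` |

For a nonlinear model with sensitivities `∂f/∂θ`, the AR(1) VIR
generalises to
`(1 − ρ²) Σ (∂f/∂θ)² / Σ (∂f/∂θ|_t − ρ ∂f/∂θ|_{t−1})²`,
and a numeric Fisher-information route (`fim_numeric()`,
`vir_numeric_fim()`) covers multi-parameter models with unknown σ, ρ and
initial state. At ρ = 0.95 — nothing unusual for high-frequency
recordings — an IID analysis overstates precision for a constant-mean fit
by a factor of 39.

The package provides:

- **Noise processes** (`noise_spec()`, `simulate_arma()`,
  `theoretical_acf()`, `stationary_variance()`, `koyck_ma_weights()`) —
  AR/MA/ARMA simulation and theory.
- **Likelihoods** (`loglik_iid()`, `loglik_ar1_conditional()`,
  `loglik_arma11_conditional()`, `loglik_arma_kalman()`) — conditional
  ARMA likelihoods (early innovations fixed at zero) and the exact
  Gaussian likelihood through a state-space (Kalman) recursion with
  stationary initialisation.
- **Diagnostics** (`diagnose()`, `fit_point_estimate()`,
  `model_residuals()`, `sample_acf()`, `arma_grid_aic()`) — the
  fit → residuals → sample ACF → ARMA/ARIMA model selection workflow.
- **Bayesian inference** (`run_mcmc()`, `rhat()`, `posterior_summary()`,
  `empirical_vir()`) — adaptive-covariance Metropolis sampling with
  rank-normalised split-R̂ convergence checks.
- **Models** — constant mean, logistic growth, and a Hodgkin–Huxley hERG
  ion-channel current model under piecewise-constant voltage protocols,
  with forward sensitivities.
- **A replication harness** (`study_design()`, `run_study()`) for the
  logistic-growth simulation study comparing IID and AR(1) fits.

Everything takes and returns tidy data frames and plays well with the
pipe; `tidy()`/`glance()` methods summarise fits and `autoplot()` draws
the standard diagnostics.

## Worked example

Simulate logistic-growth data with strongly autocorrelated measurement
noise, then let the diagnostic workflow discover that fact:

```r
library(odenoise)

design <- study_design(n_obs = 1000, seed = 1)   # r = 0.5, kappa = 50, x0 = 1
data   <- generate_dataset(design, rho = 0.9, replicate = 1)

dg <- diagnose(data, logistic_model(), p_max = 2, q_max = 2, seed = 1)
dg
#> <odn_diagnosis>
#>   lag-1 sample ACF: 0.889 (white-noise bound 0.062) -> autocorrelated
#>   recommended noise model: ARIMA(1,0,0)
```

The IID fit's residuals have lag-1 autocorrelation 0.889 — fourteen times
the white-noise bound — and the AIC grid prefers a model with an
autoregressive term. Refitting with the matched AR(1) likelihood:

```r
fit <- fit_point_estimate(data, logistic_model(), "ar1", seed = 1)
tidy(fit)
#> # A tibble: 5 × 4
#>   term  estimate  lower  upper
#>   <chr>    <dbl>  <dbl>  <dbl>
#> 1 r        0.532  0.481  0.589
#> 2 kappa   49.8   48.7   51.0
#> 3 x0       0.836  0.565  1.24
#> 4 sigma    1.07   1.02   1.12
#> 5 rho      0.890  0.858  0.915
```

All five parameters (including the noise coefficient ρ) are recovered
within their 95% intervals. The price of the *false* IID analysis is the
variance inflation ratio:

```r
vir_ar1(0.9)
#> [1] 19
```

an IID fit of this data would report standard errors for μ-like
parameters about √19 ≈ 4.4× too small.

## Command line

A thin launcher over the same functions lives at `inst/cli/odenoise`:

```sh
odenoise simulate --model logistic --noise '{"ar":[0.9],"ma":[],"sigma":1,"d":0}' --out data.csv
odenoise diagnose --data data.csv --config config.json --out diag
odenoise vir --rho 0.5            # prints 3
odenoise replicate --design default_4_1 --mode map_only --out study
```

Every artifact-writing command records a provenance JSON (package
version, arguments, seed, config hash) sufficient to rerun it.

## Caveats

Autocorrelation parameters are defined **per sampling interval**:
resampling a series changes the effective ρ. The likelihood machinery
assumes an equally spaced time grid. See the methods vignette
(`vignettes/autocorrelated-noise.Rmd`) for the model, conventions,
numerical choices and known limitations.
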