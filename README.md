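# lifmix

When a visual cortical neuron's receptive field contains several stimuli at
once, does it respond on each trial to just **one** of them (chosen with
some probability), or to a **weighted average** of all of them? The two
hypotheses — *probability-mixing* (PM) and *response-averaging* (RA) —
produce identical trial-averaged firing rates, so they can only be
separated by modelling spike trains at the single-trial level.

`lifmix` implements both hypotheses inside a leaky integrate-and-fire (LIF)
membrane model with post-spike currents,

```
dX = ( -γ(X − μ) + I(t) + H(t) ) dt + σ dW,   spike & reset at x_th,
```

where `I(t)` is the stimulus current — one stimulus `S_k(t)` per trial with
probability `α_k` under PM, the average `Σ β_k S_k(t)` under RA — and
`H(t) = Σ k_h(t − τ)` sums a double-exponential response kernel
`k_h(t) = η₁e^{−η₂t} − η₃e^{−η₄t}` over all past spikes (bursting,
adapting, or refractory dynamics depending on η).

The package provides:

* a seeded Euler–Maruyama **simulator** for spike trains under either
  hypothesis (sinusoidal, piecewise-constant, or stored Ornstein–Uhlenbeck
  stimuli; additive or square-root "Feller" noise);
* four interchangeable **first-passage-time solvers** for the ISI density
  `g(t)` and CDF `G(t)`: Fokker–Planck PDF and CDF equations
  (Crank–Nicolson + Thomas), and first-/second-kind Volterra integral
  equations (`solve_fpt()`, `isi_density()`);
* **maximum-likelihood estimation** of `(μ, σ, η, α or β)` — marginal MLE
  with log-sum-exp, and an EM algorithm for the PM mixture (`fit()`,
  `em_step()`);
* **model selection**: uniform spike-time residuals `z = G(t)` with KS
  tests, DIC differences, stage-1 vs stage-2 estimate drift, and a
  selection-accuracy sweep (`uniform_residuals()`, `ks_uniformity()`,
  `dic_difference()`, `selection_experiment()`);
* study drivers that replicate the simulation-study protocol at desk scale
  (`study_single_recovery()`, `study_mixture_recovery()`,
  `study_ks_rejection()`), and a CLI (`inst/cli/lifmix.R`) with verbs
  `simulate | fit | residuals | select | reproduce`.

## Worked example

Simulate ten 4-second probability-mixing trials at the default study
setting (bursting kernel, two sinusoidal stimuli, `α = (0.4, 0.6)`), fit
both hypotheses with the response kernel frozen, and ask which model the
data support:

```r
library(lifmix)
set <- study_defaults()
mix <- mixture_params("probability_mixing", set$alpha)
ds  <- simulate_dataset(set$lif, set$kernel, set$stimuli, mix,
                        sim_config(T = 4, n_trains = 10, seed = 1))
ds
#> LIF dataset: 10 trains, 62.6 spikes on average

lif0 <- set$lif; lif0$mu <- 0.6; lif0$sigma <- 1.5   # displaced start
fit_pm <- fit(ds, set$stimuli, model = "pm", estimator = "em",
              lif = lif0, kernel = set$kernel, method = "fp_cdf")
fit_pm
#> LIF fit (pm, mixture stage, em estimator, fp_cdf backend)
#>   mu = 0.4973  sigma = 1.0296
#>   eta = (50, 25, 40, 15)
#>   weights = (0.4, 0.6)
#>   log-likelihood = 1596.839  (converged: TRUE, 2 iterations)

fit_ra <- fit(ds, set$stimuli, model = "ra",
              lif = lif0, kernel = set$kernel, method = "fp_cdf")
fit_ra$theta[c("mu", "sigma")]
#> $mu     0.3087
#> $sigma  2.6195

dic_difference(fit_pm, fit_ra)
#> [1] -702.4
uniform_residuals(ds, fit_pm, set$stimuli, set$lif)
#> Uniform residuals: n = 626, KS D = 0.0202, p = 0.9602 (pm model)
```

Reading the output: the PM fit recovers the generating parameters
(`μ = 0.5`, `σ = 1`, `α₁ = 0.4`) almost exactly, while forcing the RA model
onto the same data drags `μ̂` down and inflates `σ̂` to 2.6 — the
characteristic misspecification signature. The DIC difference of −702
(negative favours the first argument; beyond ±10 is strong evidence)
selects PM decisively, and the PM fit's pooled residuals are
indistinguishable from uniform (KS p = 0.96).

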