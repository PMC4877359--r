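---
title: "Probability-mixing and response-averaging in LIF neurons: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-mixing and response-averaging in LIF neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifmix)
```

## The scientific question

When a cortical neuron's receptive field contains several distinct stimuli,
how does it respond? Two hypotheses with very different implications for
neural coding make the same prediction for trial-averaged firing rates and
can only be separated by trial-level modelling:

* **Probability-mixing (PM).** On each trial the neuron responds to exactly
  one of the $K$ stimuli, drawn with probabilities
  $\alpha = (\alpha_1, \ldots, \alpha_K)$, $\sum_k \alpha_k = 1$. The
  attended component is latent and held fixed within a trial.
* **Response-averaging (RA).** The neuron is driven on every trial by the
  weighted average $\sum_k \beta_k S_k(t)$ of all stimulus currents,
  $\sum_k \beta_k = 1$.

`lifmix` embeds both hypotheses in a leaky integrate-and-fire (LIF)
membrane model, provides maximum-likelihood estimation of all free
parameters from observed spike trains, and tests which hypothesis generated
the data.

## The model

The membrane potential follows

$$dX(t) = \bigl(-\gamma(X(t) - \mu) + I(t) + H(t)\bigr)\,dt + \sigma\,dW(t),$$

with a spike recorded and $X$ reset to $x_0$ whenever $X$ reaches the
threshold $x_{\mathrm{th}}$. The three drift terms are the leak (decay rate
$\gamma$, reversal potential $\mu$), the stimulus current $I(t)$ — a single
$S_k(t)$ under PM, the $\beta$-average under RA — and the post-spike
current $H(t) = \sum_{\tau < t} k_h(t - \tau)$ accumulated over all past
spikes of the trial through the response kernel

$$k_h(t) = \eta_1 e^{-\eta_2 t} - \eta_3 e^{-\eta_4 t}.$$

Depending on the $\eta$ inequalities the kernel produces bursting
($\eta_1 > \eta_3$, $\eta_2 > \eta_4$), firing-rate adaptation
($\eta_1 = 0$) or a refractory period ($\eta_1 < \eta_3$,
$\eta_2 < \eta_4$). Three stimulus families are supported: sinusoidal
$s_1 \sin(s_2 t + s_3) + s_4$, piecewise constant, and a stored
Ornstein–Uhlenbeck (OU) realization $dS = (s_1 - S)\,dt + s_2\,dW$. An
optional square-root (Feller) noise variant replaces $\sigma\,dW$ by
$\sigma\sqrt{X}\,dW$.

Only spike times are observed, so threshold, reset and the lower reflecting
boundary $x^-$ are numerical conveniences, and $\gamma$ is not
identifiable from spikes alone: it is treated as known everywhere (the
package never estimates it).

The parameter vector is $\theta = (\mu, \sigma, \eta, \alpha)$ under PM or
$(\mu, \sigma, \eta, \beta)$ under RA. The likelihood of a trial factorises
over interspike intervals (ISIs), each contributing the first-passage-time
(FPT) density $g(t)$ of the membrane diffusion to threshold given the
trial's spike history and stimulus. Under PM, the per-trial latent
component is marginalised:
$\ell(\theta) = \sum_i \log \sum_k \alpha_k \prod_j g_k(t^i_j;\theta)$,
evaluated with log-sum-exp; under RA the likelihood is the plain product
under the averaged stimulus.

## Four first-passage-time solvers

No closed form exists for $g(t)$ with time-varying drive, so the package
offers four numerical backends (`solve_fpt()`, dispatched per-ISI by the
likelihood code), all operating on the total current
$I_{\mathrm{total}}(t) = \gamma\mu + I(t) + H(t)$:

* **`fp_pdf`** — the Fokker–Planck equation for the membrane density
  $f(x,t)$, written in conservation (finite-volume) form and advanced by
  Crank–Nicolson with Thomas tridiagonal solves. Absorbing boundary at
  $x_{\mathrm{th}}$, zero-flux reflecting boundary at $x^-$, and a
  discretized Dirac initial mass ($1/\Delta x$ in the cell containing
  $x_0$). $g$ is minus the backward difference of the interior mass, so
  interior mass plus absorbed mass is conserved to round-off.
* **`fp_cdf`** — the corresponding PDE for the membrane CDF $F(x,t)$ with
  $\partial_x F(x_{\mathrm{th}},t) = 0$ (ghost node), $F(x^-,t) = 0$ and a
  Heaviside initial condition; the ISI survival function is
  $F(x_{\mathrm{th}},t)$.
* **`volterra1`** — the first-kind Volterra (Fortet) equation linking the
  threshold-free Gaussian transition density $f^*$ to $g$. The kernel is
  weakly singular on the diagonal; the package uses product-midpoint
  integration (unknowns at half-steps, with the $1/\sqrt{t-s}$ factor
  integrated exactly on every subinterval) and clips the density at zero
  during the forward recursion, since oscillating negatives in deep
  refractory troughs would otherwise corrupt the tail. This remains the
  least accurate backend on coarse grids — a property of the equation, not
  a defect of the others.
* **`volterra2`** — the second-kind Volterra equation with the
  singularity-removed kernel $\phi$. The printed form pairs an
  inhomogeneous term $-2\psi$ with the regular kernel $\phi$; using the
  Fortet identity, the equation is algebraically equivalent to the fully
  regular form $g(t) = -2\phi(x_{\mathrm{th}},t|x_0,0) +
  2\int_0^t \phi(x_{\mathrm{th}},t|x_{\mathrm{th}},s)\,g(s)\,ds$, which is
  what the package solves; $\phi$ vanishes on the diagonal like
  $\sqrt{t-s}$, and the final subinterval uses the exact integral of that
  vanishing law ($\tfrac{2}{3}\Delta t$) instead of the trapezoid weight.
  This is the most accurate backend on fine grids and serves as the
  reference solution.

The Gaussian transition moments behind both Volterra backends,
$M(t|v,s) = v e^{-\gamma(t-s)} + \int_s^t I_{\mathrm{total}}(u)
e^{-\gamma(t-u)}du$ and $V(t|s) = \sigma^2(1 - e^{-2\gamma(t-s)})/(2\gamma)$,
are accumulated incrementally on the grid, keeping each ISI solve at
$O(n^2)$; the PDE backends are $O(nm)$. The Feller variant is served by the
two Fokker–Planck backends only (its transition law is not Gaussian, so the
Volterra backends refuse it with an informative error).

Numerical hygiene: densities are clipped at zero and CDFs forced monotone
into $[0,1]$ after solving; likelihood evaluations floor $g$ at $10^{-300}$
before taking logs, so underflow never produces `NaN`.

### Grids

Two named resolutions are used throughout. The *working grid*
(`fpt_grid()`: $\Delta t = 2\,$ms, $\Delta x = 0.02$) is accurate enough
for parameter estimation at interactive speed. The *fine grid*
(`fine_grid()`: $\Delta t = 0.5\,$ms, $\Delta x = 0.01$) is required for
residual-based model selection, where solver bias of the working grid
would masquerade as model misfit and reject even the true model. All four
backends converge to a common solution as the grid is refined; at the
working grid the first Volterra backend inflates the early-ISI density
most strongly, while the second Volterra stays closest to the fine-grid
reference. The sign of the Fokker–Planck CDF backend's early-ISI bias
depends on the test case in this implementation.

## The kernel table

Post-spike currents inside solver loops are evaluated through a
piecewise-constant table of $k_h$ (segment length equal to the solver time
step, midpoint values), truncated where $|k_h|$ falls below $10^{-8}$ of
its amplitude scale. The truncation horizon is derived from the kernel's
slowest decay rate, so even the long-tailed adaptation kernel
($\eta = (0, 0, 2, 0.5)$, horizon $\approx 37$ s) is represented to the
stated tolerance. The simulator does not need the table: because the kernel
is a difference of two exponentials, the simulation propagates two
exponential filter states exactly at every Euler step.

## The simulator and what it emulates

`simulate_train()` integrates the membrane SDE by Euler–Maruyama at
$\Delta t_{\mathrm{sim}} = 0.1$ ms (the protocol's resolution), records a
spike at the first grid time with $X \ge x_{\mathrm{th}}$ (no sub-step
interpolation), resets to $x_0$, and lets the stimulus clock and spike
history continue uninterrupted. Under PM the latent component is drawn once
per train and held fixed. OU stimulus paths start at their asymptotic mean
$s_1$ and are stored, so that every repetition of an experiment reuses a
single realization. Feller paths use full truncation
($X \leftarrow \max(X, 0)$) before taking the square root.

Per-train RNG substreams are derived deterministically from the dataset
seed, so any train can be regenerated in isolation and fixed seeds give
byte-identical datasets.

What the generator deliberately does *not* emulate: measurement jitter,
recording artefacts, non-stationary excitability, correlated noise across
trials, or any deviation from the LIF law itself. Passing tests therefore
demonstrate correct recovery of a *well-specified* model, not robustness of
the method on real recordings.

Grid-point crossing detection biases simulated crossings late by
$O(\sqrt{\Delta t_{\mathrm{sim}}})$. At 0.1 ms this is irrelevant for
estimation, but it dominates a $10^4$-sample Kolmogorov–Smirnov comparison
against the solvers. The solver cross-validation tests therefore use an
independent oracle written directly in the test code: vectorized Euler
with the Brownian-bridge crossing test (accepting a within-step crossing
with probability $e^{-2(x_{\mathrm{th}}-X_n)(x_{\mathrm{th}}-X_{n+1})/
(\sigma^2 \Delta t)}$), which removes the square-root boundary bias and
leaves only $O(\Delta t)$ weak error. Those tests draw their
configurations from the model's suprathreshold firing regime
($\mu \in [0.4, 0.6]$, $\sigma \in [0.8, 1.3]$, total current in
$[102, 112]$ — the range the sinusoidal baselines produce); with drive at
or below $\gamma x_{\mathrm{th}}$ the fine-grid solver biases reach the KS
test's detection limit, a regime the estimation study never enters.

## Estimation protocol

Estimation follows the two-stage design of the underlying experiment:

1. **Single-stimulus stage.** Trains responding to one known stimulus each
   (PM and RA coincide here). $(\mu, \sigma, \eta)$ are fitted jointly by
   Nelder–Mead on transformed parameters ($\log\sigma$, $\log\eta$). The
   four $\eta$ are not identifiable individually — different vectors give
   nearly identical kernels — so validation compares the fitted kernel
   *shape*, never raw $\eta$.
2. **Mixture stage.** $\eta$ is frozen (at the stage-1 estimate in the full
   protocol) and $(\mu, \sigma)$ plus the weights are estimated: under PM
   by direct marginal maximisation or by EM; under RA by the plain
   averaged-stimulus likelihood. Weights live on the simplex via a softmax
   parameterisation, so every optimizer iterate is a valid weight vector.
   $(\mu, \sigma)$ start from the stage-1 values; weights start uniform.

The EM algorithm treats the per-trial attended component as missing data:
the E-step computes posterior component probabilities per train by Bayes'
formula in log space; the M-step updates $\alpha_k$ in closed form (the
posterior average) and maximises the posterior-weighted ISI log-likelihood
over $(\mu, \sigma)$ numerically, warm-started at the previous iterate. EM
stops when the largest absolute parameter change drops below $10^{-4}$
(or after 200 iterations). The marginal log-likelihood is non-decreasing
across iterations up to the inner optimizer's tolerance, and EM and the
marginal MLE agree closely, with EM's $\alpha$ estimates slightly more
stable — the practical reason to prefer it for mixtures.

Nelder–Mead was chosen because the likelihood surface is produced by
numerical PDE/IE solvers: gradients are unavailable and finite-difference
gradients would inherit solver noise. The optimizer, bounds and starting
values are this package's choices (`fit()`'s `control` argument), made
once: stage-1 starts at $(\mu_0, \sigma_0) = (0.6, 1.5)$ — deliberately
displaced from the default generating values — and at the generating
kernel shape.

## Model selection

Three complementary diagnostics, all computed by `lifmix`:

* **Uniform residuals** (`uniform_residuals()`): $z^i_j = G(t^i_j)$, the
  fitted ISI CDF at each observed spike. Under the true model the pooled
  residuals are i.i.d. U(0,1); `ks_uniformity()` tests this (asymptotic
  null; pooled samples run to several hundred). Under a fitted PM model
  each train's residuals use the posterior-weighted mixture CDF
  $\sum_k P(y_i = k \mid d_i) G_k(t)$ by default; a hard most-probable
  assignment is available via `assignment = "hard"`. The posterior
  weighting was chosen because it is well defined for every train,
  including ambiguous ones.
* **DIC difference** (`dic_difference()`): with equal parameter counts the
  DIC difference reduces to $-2$ times the log-likelihood difference at
  the plugin MLE. Differences beyond 2 (`DIC_SUBSTANTIAL`) indicate
  substantial support, beyond 10 (`DIC_STRONG`) strong support.
* **Estimate drift** (`estimate_drift()`): if the assumed response model is
  wrong, $(\hat\mu, \hat\sigma)$ from mixture data drift far from the
  single-stimulus estimates (e.g. $\hat\sigma$ roughly doubling); under
  the correct model the two stages agree.

Model selection is the one place the fine grid is mandatory: at the working
grid, solver bias alone produces residual non-uniformity that rejects even
the correct model, so `study_ks_rejection()` fits on the working grid,
polishes the fit on the fine grid, and evaluates residuals there.

`selection_experiment()` sweeps the selection accuracy over mixture
weights, stimulus dissimilarity ($S + a\sin(10t)$ added to one of two
identical OU stimuli), stimulus scaling $bS$, and dataset size, scoring a
repetition as successful when the generating model's DIC beats the
competitor by more than 2. With identical stimuli and equal weights the
two models coincide and selection cannot (and does not) succeed —
a built-in negative control.

## Study drivers and problem sizes

`study_defaults()` reproduces the working parameter set: bursting kernel
$\eta = (50, 25, 40, 15)$, sinusoidal stimuli $(10, 12, 1, 50)$ and
$(20, 8, 0, 50)$, $\mu = 0.5$, $\sigma = 1$, $\gamma = 100$, $x_0 = 0.4$,
$x_{\mathrm{th}} = 1$, $x^- = 0$, weights $(0.4, 0.6)$; trains are 4 s
(about 60–70 spikes) and datasets hold 10 trains. The packaged drivers run
desk-scale versions of the study: 10 repetitions for the recovery studies
and 5 for the fine-grid KS study (the original analyses used 100 and 20).
These sizes were chosen so each driver completes in minutes on one core
while keeping across-repetition standard errors small enough for
meaningful comparison.

One design note on the mixture repetitions: the across-repetition spread
of $\hat\alpha_1$ reported for the original study is far smaller than the
allocation noise of a Binomial(10, 0.4) latent draw, and the stochastic
stimulus-mixture figure states a fixed 4/6 split; the recovery drivers
therefore fix the PM latent allocation at its expectation.
`simulate_dataset()` itself keeps the honest binomial draw by default.

## Known limitations

* $\gamma$ must be supplied; no profile-likelihood helper is included.
* The first Volterra backend is usable but visibly biased on the working
  grid; prefer it only for quick exploration.
* Residual-based selection inherits the KS test's sensitivity to sample
  size and stimulus similarity; the DIC comparison is the more robust of
  the two and the two should be read together.
* Optimizer non-convergence is reported via the `converged` flag rather
  than an error; stage-1 fits with six free parameters occasionally hit
  the iteration cap with estimates already stable to three decimals.
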