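# shared fixtures: the default study setting, cheap constant stimuli,
# a zero-amplitude kernel, a Monte-Carlo first-passage sampler, and lazily
# memoized simulated datasets (built once per test run)

default_setting <- study_defaults()

const_stim <- function(value) stimulus_sinusoidal(0, 0, 0, value)

null_kernel <- response_kernel(c(0, 1, 0, 1))

# first-passage times of the OU/Feller membrane under a constant total
# current, sampled by restarting Euler paths; returns the first crossing
# time of each of n trials
mc_first_passage <- function(lif, itot, n, T = 0.6, dt = 1e-4, seed = 1) {
  stim <- const_stim(itot - lif$gamma * lif$mu)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    tr <- simulate_train(lif, null_kernel, stim,
                         sim = sim_config(T = T, dt_sim = dt))
    if (length(tr$times)) tr$times[1] else NA_real_
  }, numeric(1))
}

# independent high-accuracy first-passage oracle: plain-R vectorized Euler
# with the Brownian-bridge crossing test, which removes the O(sqrt(dt))
# late-detection bias of grid-point threshold checks; shares no code with
# the package's solvers or simulator
bridge_first_passage <- function(lif, itot, n, T = 0.35, dt = 2e-5, seed = 1) {
  set.seed(seed)
  X <- rep(lif$x0, n)
  t_hit <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  s2dt <- lif$sigma^2 * dt
  for (k in seq_len(round(T / dt))) {
    if (!any(alive)) break
    Xa <- X[alive]
    Xn <- Xa + (itot - lif$gamma * Xa) * dt +
      lif$sigma * sqrt(dt) * rnorm(length(Xa))
    hit <- Xn >= lif$x_th
    sub <- !hit
    if (any(sub)) {
      p_bridge <- exp(-2 * (lif$x_th - Xa[sub]) * (lif$x_th - Xn[sub]) / s2dt)
      hit[sub] <- runif(sum(sub)) < p_bridge
    }
    idx <- which(alive)
    t_hit[idx[hit]] <- k * dt
    alive[idx[hit]] <- FALSE
    X[idx[!hit]] <- Xn[!hit]
  }
  t_hit
}

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 10 single-stimulus trains (5 per sinusoidal stimulus) at the default
# setting -- the stage-1 fixture
single_dataset <- function() memo_fixture("single_ds", function() {
  simulate_dataset(default_setting$lif, default_setting$kernel,
                   default_setting$stimuli, mixture = NULL,
                   sim = sim_config(seed = 42),
                   components = rep(1:2, each = 5))
})

# small probability-mixing dataset for estimator tests
pm_small_dataset <- function() memo_fixture("pm_small_ds", function() {
  mix <- mixture_params("probability_mixing", default_setting$alpha)
  simulate_dataset(default_setting$lif, default_setting$kernel,
                   default_setting$stimuli, mix,
                   sim = sim_config(T = 2, n_trains = 6, seed = 7),
                   components = c(1L, 2L, 2L, 1L, 2L, 2L))
})

# small response-averaging dataset
ra_small_dataset <- function() memo_fixture("ra_small_ds", function() {
  mix <- mixture_params("response_averaging", default_setting$alpha)
  simulate_dataset(default_setting$lif, default_setting$kernel,
                   default_setting$stimuli, mix,
                   sim = sim_config(T = 2, n_trains = 6, seed = 8))
})

# a hand-built fit object at given parameters (for residual tests that do
# not need an optimizer run)
manual_fit <- function(model, mu, sigma, eta, weights, grid = fpt_grid(),
                       method = "fp_pdf", loglik = 0) {
  structure(list(model = model, estimator = "marginal",
                 stage = if (model == "single") "single" else "mixture",
                 theta = list(mu = mu, sigma = sigma, eta = eta,
                              weights = weights),
                 loglik = loglik, iterations = 0L, converged = TRUE,
                 method = method, grid = grid),
            class = "lif_fit")
}
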