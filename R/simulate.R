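#' Simulation configuration
#'
#' @param dt_sim Euler-Maruyama step (seconds); 1e-4 (0.1 ms) is the study
#'   resolution.
#' @param T trial duration (seconds).
#' @param n_trains number of trials per dataset.
#' @param seed integer master seed; per-train seeds are derived
#'   deterministically so individual trains can be regenerated in isolation.
#' @param record_voltage keep the simulated membrane path.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_sim = 1e-4, T = 4, n_trains = 10, seed = NULL,
                       record_voltage = FALSE) {
  if (dt_sim <= 0 || T <= 0) stop("dt_sim and T must be positive")
  if (n_trains < 1) stop("need at least one train")
  structure(list(dt_sim = dt_sim, T = T, n_trains = n_trains, seed = seed,
                 record_voltage = record_voltage), class = "sim_config")
}

# deterministic per-train substream seed, kept below 2^31
train_seed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)

#' Simulate one spike train
#'
#' Euler-Maruyama integration of the membrane SDE at step `dt_sim`. A spike
#' is recorded at the first grid time with \eqn{X \ge x_{\mathrm{th}}}
#' (no sub-step interpolation), after which the potential resets to
#' \eqn{x_0} while the stimulus clock and the spike history continue
#' uninterrupted; all previous spikes of the trial feed the post-spike
#' current. Under probability-mixing the attended component is drawn once
#' per train from the mixing probabilities and held fixed for the whole
#' trial. With Feller noise the diffusion is \eqn{\sigma\sqrt{X}} with full
#' truncation at zero.
#'
#' @param lif a [lif_params()] object.
#' @param kernel a [response_kernel()] object.
#' @param stimuli a stimulus or list of stimuli.
#' @param mixture a [mixture_params()] object, or `NULL` for a single
#'   stimulus.
#' @param sim a [sim_config()] object.
#' @param component force the attended component (overrides the
#'   probability-mixing draw); used for single-stimulus designs.
#' @param seed optional integer seed for this train.
#' @return A [spike_train()]; with `record_voltage` the membrane path is
#'   attached as attribute `"voltage"`.
#' @export
simulate_train <- function(lif, kernel, stimuli, mixture = NULL,
                           sim = sim_config(), component = NULL, seed = NULL) {
  stopifnot(inherits(lif, "lif_params"), inherits(kernel, "lif_kernel"))
  if (inherits(stimuli, "lif_stimulus")) stimuli <- list(stimuli)
  if (!is.null(seed)) set.seed(seed)
  y <- NA_integer_
  if (!is.null(component)) {
    stim <- stimuli[[component]]
    y <- as.integer(component)
  } else if (is.null(mixture) || mixture$K == 1L) {
    stim <- if (is.null(mixture) || mixture$model == "probability_mixing")
      stimuli[[1]] else average_stimulus(stimuli, mixture$weights)
    y <- 1L
  } else if (mixture$model == "probability_mixing") {
    y <- sample.int(mixture$K, 1L, prob = mixture$weights)
    stim <- stimuli[[y]]
  } else {
    stim <- average_stimulus(stimuli, mixture$weights)
  }
  res <- cpp_simulate_train(lif$mu, lif$gamma, lif$sigma, lif$x0, lif$x_th,
                            lif$noise_model == "feller", kernel$eta,
                            stim_terms(stim), sim$T, sim$dt_sim,
                            sim$record_voltage)
  out <- spike_train(res$spikes, duration = sim$T,
                     condition = if (!is.na(y)) y else NA,
                     component = y)
  if (sim$record_voltage) attr(out, "voltage") <- res$voltage
  out
}

#' Simulate a dataset of spike trains
#'
#' Reproducible batch simulation: per-train seeds are derived from the
#' master seed, and for probability-mixing data the latent attended
#' component of each train is stored alongside the spike times.
#'
#' @inheritParams simulate_train
#' @param components optional fixed per-train component assignment of
#'   length `n_trains` (e.g. `rep(1:2, each = 5)` for the single-stimulus
#'   design of five trials per stimulus).
#' @return A list of [spike_train()] objects with class `lif_dataset`.
#' @export
simulate_dataset <- function(lif, kernel, stimuli, mixture = NULL,
                             sim = sim_config(), components = NULL) {
  if (!is.null(components) && length(components) != sim$n_trains)
    stop("'components' must have one entry per train")
  trains <- vector("list", sim$n_trains)
  for (i in seq_len(sim$n_trains)) {
    s <- if (!is.null(sim$seed)) train_seed(sim$seed, i) else NULL
    trains[[i]] <- simulate_train(lif, kernel, stimuli, mixture, sim,
                                  component = if (!is.null(components)) components[i],
                                  seed = s)
  }
  structure(trains, class = "lif_dataset",
            mixture = mixture, seed = sim$seed)
}

#' @export
print.lif_dataset <- function(x, ...) {
  n <- vapply(x, function(tr) length(tr$times), integer(1))
  cat(sprintf("LIF dataset: %d trains, %.1f spikes on average\n",
              length(x), mean(n)))
  invisible(x)
}

#' Simulate an Ornstein-Uhlenbeck stimulus path
#'
#' Euler-Maruyama realization of \eqn{dS = (s_1 - S)\,dt + s_2\,dW},
#' started at the asymptotic mean \eqn{s_1}. The path is stored in the
#' returned stimulus so that all repetitions of an experiment reuse a
#' single realization.
#'
#' @param s OU parameters \eqn{(s_1, s_2)}: asymptotic mean and noise
#'   intensity.
#' @param dt sampling step (seconds).
#' @param T path length (seconds).
#' @param seed optional integer seed.
#' @return A `lif_stimulus` of family `"ou_path"`.
#' @export
simulate_ou_stimulus <- function(s, dt = 1e-4, T = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  path <- cpp_simulate_ou_path(s[1], s[2], dt, T)
  stimulus_ou_path(path, t0 = 0, dt = dt, params = s)
}
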