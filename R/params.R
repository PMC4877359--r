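#' LIF model parameters
#'
#' The membrane potential follows
#' \deqn{dX = (-\gamma(X-\mu) + I(t) + H(t))\,dt + \sigma\,dW,}
#' resetting to \eqn{x_0} whenever it reaches the threshold
#' \eqn{x_{\mathrm{th}}}; spike times are the threshold crossings. Because
#' only spike times are observed, threshold and reset are numerical
#' conveniences and a reflecting boundary \eqn{x^-} bounds the
#' computational domain from below. With `noise_model = "feller"` the
#' diffusion term becomes \eqn{\sigma\sqrt{X}\,dW} (square-root noise,
#' keeping the process nonnegative).
#'
#' @param mu reversal potential.
#' @param sigma diffusion parameter, positive.
#' @param gamma membrane decay rate (1/s), positive; treated as known
#'   throughout (it is not identifiable from spike times alone).
#' @param x0 reset potential.
#' @param x_th firing threshold.
#' @param x_lower reflecting lower boundary \eqn{x^-}.
#' @param noise_model `"additive"` (Ornstein-Uhlenbeck) or `"feller"`.
#' @return An object of class `lif_params`.
#' @examples
#' lif_params(mu = 0.5, sigma = 1)
#' @export
lif_params <- function(mu, sigma, gamma = 100, x0 = 0.4, x_th = 1,
                       x_lower = 0, noise_model = c("additive", "feller")) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.finite(mu), is.finite(sigma), is.finite(gamma))
  if (sigma <= 0) stop("sigma must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (!(x_lower < x0 && x0 < x_th))
    stop("need x_lower < x0 < x_th")
  structure(list(mu = mu, sigma = sigma, gamma = gamma, x0 = x0,
                 x_th = x_th, x_lower = x_lower, noise_model = noise_model),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters (%s noise)\n  mu=%g sigma=%g gamma=%g x0=%g x_th=%g x_lower=%g\n",
    x$noise_model, x$mu, x$sigma, x$gamma, x$x0, x$x_th, x$x_lower))
  invisible(x)
}

#' Mixture parameters
#'
#' Weights over the K stimuli in the receptive field: mixing probabilities
#' \eqn{\alpha} under probability-mixing, averaging weights \eqn{\beta}
#' under response-averaging. Weights must be nonnegative and are normalised
#' to sum to one on construction.
#'
#' @param model `"probability_mixing"` or `"response_averaging"`.
#' @param weights nonnegative weights of length K.
#' @return An object of class `lif_mixture`.
#' @export
mixture_params <- function(model = c("probability_mixing", "response_averaging"),
                           weights) {
  model <- match.arg(model)
  weights <- as.numeric(weights)
  if (length(weights) < 1L || anyNA(weights) || any(weights < 0))
    stop("weights must be nonnegative numbers")
  s <- sum(weights)
  if (s <= 0) stop("weights must have positive sum")
  structure(list(model = model, weights = weights / s, K = length(weights)),
            class = "lif_mixture")
}

#' @export
print.lif_mixture <- function(x, ...) {
  cat("Mixture (", x$model, "): weights = (",
      paste(signif(x$weights, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Spike train container
#'
#' One trial's ordered spike times, with the trial duration and optional
#' metadata: a condition label (which stimulus setting the trial belongs
#' to) and, for simulated probability-mixing data, the latent attended
#' component.
#'
#' @param times strictly increasing spike times in `(0, duration]`, seconds.
#' @param duration trial length T in seconds.
#' @param condition optional label or stimulus index.
#' @param component latent attended-stimulus index (simulation only).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, condition = NA, component = NA_integer_) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
  if (length(times) && (times[1] <= 0 || times[length(times)] > duration + 1e-12))
    stop("spike times must lie in (0, duration]")
  structure(list(times = times, duration = duration,
                 condition = condition, component = component),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s", length(x$times), x$duration))
  if (!is.na(x$condition)) cat(", condition ", x$condition, sep = "")
  if (!is.na(x$component)) cat(", latent component ", x$component, sep = "")
  cat("\n")
  invisible(x)
}

#' Solver grid
#'
#' Discretization used by the first-passage-time backends: time step `dt`
#' and membrane-potential step `dx` (Fokker-Planck backends only). The
#' defaults, `dt = 0.002` s and `dx = 0.02`, are the working resolution for
#' parameter estimation; `fine_grid()` (`dt = 5e-4`, `dx = 0.01`) is the
#' reference resolution used for model selection, where solver bias must be
#' small.
#'
#' @param dt time step in seconds.
#' @param dx membrane-potential step.
#' @param t_max horizon for a standalone ISI solve, seconds.
#' @return An object of class `fpt_grid`.
#' @export
fpt_grid <- function(dt = 0.002, dx = 0.02, t_max = 1) {
  if (dt <= 0 || dx <= 0 || t_max <= 0) stop("dt, dx, t_max must be positive")
  structure(list(dt = dt, dx = dx, t_max = t_max), class = "fpt_grid")
}

#' @rdname fpt_grid
#' @export
fine_grid <- function(t_max = 1) fpt_grid(dt = 5e-4, dx = 0.01, t_max = t_max)
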