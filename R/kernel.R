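#' Post-spike response kernel
#'
#' The effect of each past spike on the membrane drift is the difference of
#' two decaying exponentials,
#' \deqn{k_h(t) = \eta_1 e^{-\eta_2 t} - \eta_3 e^{-\eta_4 t},}
#' with nonnegative parameters \eqn{\eta = (\eta_1,\eta_2,\eta_3,\eta_4)}.
#' Three qualitative regimes are distinguished: *bursting*
#' (\eqn{\eta_1>\eta_3}, \eqn{\eta_2>\eta_4}; an initial excitatory phase
#' followed by accumulated inhibition produces rhythmic bursts), *decaying*
#' (\eqn{\eta_1 = 0}; weak, long-lasting inhibition producing firing-rate
#' adaptation) and *delaying* (\eqn{\eta_1<\eta_3}, \eqn{\eta_2<\eta_4};
#' early inhibition modelling a refractory period).
#'
#' @param eta numeric vector of length 4, the kernel parameters
#'   \eqn{(\eta_1,\eta_2,\eta_3,\eta_4)}, all nonnegative. Amplitudes are in
#'   current units, rates in 1/s.
#' @param kind optional kernel regime, one of `"bursting"`, `"decaying"`,
#'   `"delaying"`. When supplied the parameters are checked against the
#'   regime's defining inequalities; when `NULL` the regime is inferred
#'   (`"other"` if the parameters fit none of the three).
#' @return An object of class `lif_kernel`.
#' @examples
#' k <- response_kernel(c(50, 25, 40, 15)) # bursting
#' eval_kernel(k, 0)                       # eta1 - eta3 = 10
#' @export
response_kernel <- function(eta, kind = NULL) {
  eta <- as.numeric(eta)
  if (length(eta) != 4L || anyNA(eta)) stop("'eta' must be four finite numbers")
  if (any(eta < 0)) stop("kernel parameters must be nonnegative")
  inferred <-
    if (eta[1] == 0) "decaying"
    else if (eta[1] > eta[3] && eta[2] > eta[4]) "bursting"
    else if (eta[1] < eta[3] && eta[2] < eta[4]) "delaying"
    else "other"
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("bursting", "decaying", "delaying"))
    ok <- switch(kind,
      bursting = eta[1] > eta[3] && eta[2] > eta[4],
      decaying = eta[1] == 0,
      delaying = eta[1] < eta[3] && eta[2] < eta[4])
    if (!ok) stop("parameters do not satisfy the '", kind, "' kernel inequalities")
  } else {
    kind <- inferred
  }
  structure(list(eta = eta, kind = kind), class = "lif_kernel")
}

#' @export
print.lif_kernel <- function(x, ...) {
  cat("LIF response kernel (", x$kind, ")\n  eta = (",
      paste(signif(x$eta, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Evaluate the response kernel
#'
#' @param kernel a [response_kernel()] object.
#' @param t nonnegative time(s) since the spike, in seconds.
#' @return \eqn{k_h(t)}, vectorised over `t`.
#' @export
eval_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "lif_kernel"))
  if (any(t < 0)) stop("kernel is only defined for nonnegative lags")
  e <- kernel$eta
  e[1] * exp(-e[2] * t) - e[3] * exp(-e[4] * t)
}

#' Piecewise-constant kernel lookup table
#'
#' Pre-tabulates \eqn{k_h} on a uniform grid of segment length `dt` (the
#' solver time step), using midpoint values, truncated where \eqn{|k_h|}
#' falls below `rel_tol` times its amplitude scale. All post-spike currents
#' inside solver and likelihood loops are evaluated through this table, so
#' the kernel is computed once per parameter update rather than once per
#' grid node and spike.
#'
#' @param kernel a [response_kernel()] object.
#' @param dt table segment length in seconds.
#' @param rel_tol relative truncation tolerance for the kernel tail.
#' @return A list with elements `values`, `dt` and `horizon`.
#' @export
kernel_table <- function(kernel, dt, rel_tol = 1e-8) {
  stopifnot(inherits(kernel, "lif_kernel"), dt > 0)
  e <- kernel$eta
  scale <- max(e[1], e[3], abs(e[1] - e[3]), .Machine$double.eps)
  cut <- rel_tol * scale
  horizon_term <- function(amp, rate) {
    if (amp <= cut) return(0)
    if (rate <= 0) return(120)  # non-decaying component: cap the horizon
    min(log(amp / cut) / rate, 120)
  }
  horizon <- max(horizon_term(e[1], e[2]), horizon_term(e[3], e[4]), dt)
  n <- ceiling(horizon / dt)
  mid <- (seq_len(n) - 0.5) * dt
  list(values = eval_kernel(kernel, mid), dt = dt, horizon = n * dt)
}

#' Post-spike current from a spike history
#'
#' Sums the response kernel over all past spikes,
#' \eqn{H(t) = \sum_{\tau < t} k_h(t - \tau)}, evaluated through the
#' piecewise-constant table of [kernel_table()]. Spikes older than the
#' table's truncation horizon contribute zero.
#'
#' @param kernel a [response_kernel()] object.
#' @param history strictly increasing past spike times (seconds), all `<= t`.
#' @param t evaluation time(s).
#' @param dt table segment length; ignored when `table` is given.
#' @param table optional precomputed [kernel_table()].
#' @return \eqn{H(t)}, vectorised over `t`.
#' @export
post_spike_current <- function(kernel, history, t, dt = 0.002, table = NULL) {
  if (is.null(table)) table <- kernel_table(kernel, dt)
  if (length(history) == 0L) return(rep(0, length(t)))
  cpp_post_spike_current(as.numeric(history), as.numeric(t),
                         table$values, table$dt)
}

#' Total drift current
#'
#' The drift of the membrane SDE is \eqn{-\gamma(X - \mu) + I(t) + H(t)};
#' the state-free part, \eqn{I_{\mathrm{total}}(t) = \gamma\mu + I(t) + H(t)},
#' is what the first-passage-time solvers consume. Under probability-mixing
#' the stimulus current is the single attended component,
#' \eqn{I(t) = S_k(t)}; under response-averaging it is the weighted average
#' \eqn{I(t) = \sum_k \beta_k S_k(t)}.
#'
#' @param lif a [lif_params()] object.
#' @param kernel a [response_kernel()] object.
#' @param stimuli list of stimulus objects (see [stimulus_sinusoidal()]).
#' @param mixture a [mixture_params()] object.
#' @param t evaluation time(s).
#' @param component attended stimulus index; required for
#'   probability-mixing, ignored for response-averaging.
#' @param history past spike times contributing post-spike current.
#' @param dt kernel table segment length.
#' @return \eqn{I_{\mathrm{total}}(t)}, vectorised over `t`.
#' @export
total_current <- function(lif, kernel, stimuli, mixture, t,
                          component = NULL, history = numeric(0), dt = 0.002) {
  stopifnot(inherits(lif, "lif_params"), inherits(mixture, "lif_mixture"))
  if (inherits(stimuli, "lif_stimulus")) stimuli <- list(stimuli)
  if (mixture$model == "probability_mixing") {
    if (is.null(component)) stop("probability-mixing requires a component index")
    stim <- stimuli[[component]]
  } else {
    stim <- average_stimulus(stimuli, mixture$weights)
  }
  lif$gamma * lif$mu + eval_stimulus(stim, t) +
    post_spike_current(kernel, history, t, dt = dt)
}
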