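logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-ISI g and G (and their log-density sum) for one train under one
# stimulus; the workhorse behind every likelihood
train_isi_gG <- function(train, lif, kernel, stimulus, grid, method,
                         ktab = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(ktab)) ktab <- kernel_table(kernel, grid$dt)
  cpp_train_isi_gG(train$times, lif$gamma * lif$mu, lif$gamma, lif$sigma,
                   lif$x0, lif$x_th, lif$x_lower,
                   lif$noise_model == "feller",
                   ktab$values, ktab$dt, stim_terms(stimulus),
                   grid$dt, grid$dx, method_code(method))
}

#' Single-stimulus spike-train log-likelihood
#'
#' Sum over the ISIs of a train of the log first-passage-time density
#' evaluated at each observed spike time given its history; the first ISI
#' is referenced to the trial start, where the membrane sits at the reset
#' state with empty history. Density values are floored at 1e-300 before
#' the logarithm, so underflow never produces `NaN`.
#'
#' @param train a [spike_train()].
#' @param lif a [lif_params()] object.
#' @param kernel a [response_kernel()] object.
#' @param stimulus the stimulus driving the train.
#' @param grid an [fpt_grid()].
#' @param method solver backend, see [solve_fpt()].
#' @return The log-likelihood (scalar).
#' @export
loglik_single <- function(train, lif, kernel, stimulus, grid = fpt_grid(),
                          method = "fp_pdf") {
  if (length(train$times) == 0L) stop("spike train is empty")
  train_isi_gG(train, lif, kernel, stimulus, grid, method)$loglik
}

#' Per-train, per-component log-likelihoods
#'
#' Matrix of \eqn{\sum_j \log g_k(t_j^i)} for every train i and mixture
#' component k (train i driven by stimulus k). This is the shared primitive
#' of the marginal likelihood and the EM algorithm.
#'
#' @inheritParams loglik_single
#' @param dataset a list of [spike_train()] objects.
#' @param stimuli list of the K component stimuli.
#' @return An N x K matrix of log-likelihoods.
#' @export
component_logliks <- function(dataset, lif, kernel, stimuli,
                              grid = fpt_grid(), method = "fp_pdf") {
  if (inherits(stimuli, "lif_stimulus")) stimuli <- list(stimuli)
  ktab <- kernel_table(kernel, grid$dt)
  N <- length(dataset); K <- length(stimuli)
  ll <- matrix(NA_real_, N, K)
  for (i in seq_len(N))
    for (k in seq_len(K))
      ll[i, k] <- train_isi_gG(dataset[[i]], lif, kernel, stimuli[[k]],
                               grid, method, ktab)$loglik
  ll
}

#' Marginal log-likelihood of the probability-mixing model
#'
#' \deqn{\ell(\theta; D) = \sum_i \log \sum_k \alpha_k
#'   \prod_j g_k(t_j^i; \theta),}
#' the latent per-trial stimulus assignment summed out. The inner sum is
#' evaluated with the log-sum-exp identity, so products of hundreds of
#' densities cannot underflow.
#'
#' @inheritParams component_logliks
#' @param alpha mixing probabilities on the simplex.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(dataset, lif, kernel, stimuli, alpha,
                            grid = fpt_grid(), method = "fp_pdf") {
  check_simplex(alpha, length(stimuli))
  ll <- component_logliks(dataset, lif, kernel, stimuli, grid, method)
  marginal_from_components(ll, alpha)
}

marginal_from_components <- function(ll, alpha) {
  la <- log(alpha)
  la[alpha == 0] <- -Inf
  sum(apply(ll, 1L, function(row) logsumexp(row + la)))
}

check_simplex <- function(w, K) {
  if (length(w) != K) stop("weight vector must have one entry per stimulus")
  if (any(w < -1e-12) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to one")
  invisible(TRUE)
}

#' Log-likelihood of the response-averaging model
#'
#' The response-averaging neuron is driven by the single averaged current
#' \eqn{\sum_k \beta_k S_k(t)}, so the likelihood is a plain product of
#' ISI densities under that one stimulus.
#'
#' @inheritParams component_logliks
#' @param beta averaging weights on the simplex.
#' @return The log-likelihood (scalar).
#' @export
loglik_ra <- function(dataset, lif, kernel, stimuli, beta,
                      grid = fpt_grid(), method = "fp_pdf") {
  if (inherits(stimuli, "lif_stimulus")) stimuli <- list(stimuli)
  check_simplex(beta, length(stimuli))
  avg <- average_stimulus(stimuli, beta)
  ktab <- kernel_table(kernel, grid$dt)
  sum(vapply(dataset, function(tr)
    train_isi_gG(tr, lif, kernel, avg, grid, method, ktab)$loglik,
    numeric(1)))
}
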