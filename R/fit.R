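softmax_weights <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

weights_to_z <- function(w) {
  w <- pmax(w, 1e-8)
  log(w[-length(w)] / w[length(w)])
}

fit_control <- function(control = list()) {
  modifyList(list(maxit = 500, reltol = 1e-8,
                  em_maxit = 200, em_tol = 1e-4, inner_maxit = 200),
             control)
}

# train i gets stimulus stimuli[[cond[i]]]; log-likelihood summed over trains
single_objective_factory <- function(dataset, stimuli, lif, grid, method, fit_eta,
                                     eta_fixed) {
  conds <- vapply(dataset, function(tr) as.integer(tr$condition), integer(1))
  if (anyNA(conds)) stop("stage-1 fitting needs a stimulus condition on every train")
  function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    eta <- if (fit_eta) exp(par[3:6]) else eta_fixed
    l <- tryCatch({
      lif2 <- lif; lif2$mu <- mu; lif2$sigma <- sigma
      kern <- response_kernel(eta)
      ktab <- kernel_table(kern, grid$dt)
      sum(vapply(seq_along(dataset), function(i)
        train_isi_gG(dataset[[i]], lif2, kern, stimuli[[conds[i]]],
                     grid, method, ktab)$loglik, numeric(1)))
    }, error = function(e) -Inf)
    if (!is.finite(l)) -1e10 else -l
  }
}

#' One EM iteration for the probability-mixing model
#'
#' E-step: per-train posteriors of the attended component by Bayes'
#' formula, computed in log space. M-step: the mixing probabilities have
#' the closed-form update \eqn{\alpha_k = N^{-1}\sum_i P(y_i = k | \cdot)};
#' \eqn{(\mu, \sigma)} maximise the posterior-weighted ISI log-likelihood
#' numerically (Nelder-Mead on \eqn{(\mu, \log\sigma)}), warm-started at
#' the previous iterate. The response kernel stays fixed.
#'
#' @param dataset a list of [spike_train()] objects.
#' @param theta_prev list with elements `mu`, `sigma`, `alpha`.
#' @param lif a [lif_params()] template (provides \eqn{\gamma}, boundaries,
#'   noise model).
#' @param kernel the fixed [response_kernel()].
#' @param stimuli list of the K component stimuli.
#' @param grid an [fpt_grid()].
#' @param method solver backend.
#' @param control optimizer control list.
#' @param comp_ll optional precomputed [component_logliks()] matrix at
#'   `theta_prev` (avoids one likelihood sweep).
#' @return List with `theta` (updated `mu`, `sigma`, `alpha`),
#'   `posteriors` (N x K), and `comp_ll` at the updated parameters.
#' @export
em_step <- function(dataset, theta_prev, lif, kernel, stimuli,
                    grid = fpt_grid(), method = "fp_pdf",
                    control = list(), comp_ll = NULL) {
  ctl <- fit_control(control)
  lif$mu <- theta_prev$mu; lif$sigma <- theta_prev$sigma
  if (is.null(comp_ll))
    comp_ll <- component_logliks(dataset, lif, kernel, stimuli, grid, method)
  post <- em_posteriors(comp_ll, theta_prev$alpha)
  alpha_new <- colMeans(post)
  obj <- function(par) {
    lif2 <- lif; lif2$mu <- par[1]; lif2$sigma <- exp(par[2])
    ll <- tryCatch(component_logliks(dataset, lif2, kernel, stimuli, grid, method),
                   error = function(e) NULL)
    if (is.null(ll) || !all(is.finite(ll))) return(1e10)
    -sum(post * ll)
  }
  opt <- optim(c(theta_prev$mu, log(theta_prev$sigma)), obj,
               method = "Nelder-Mead",
               control = list(maxit = ctl$inner_maxit, reltol = ctl$reltol))
  theta <- list(mu = opt$par[1], sigma = exp(opt$par[2]), alpha = alpha_new)
  lif$mu <- theta$mu; lif$sigma <- theta$sigma
  ll_new <- component_logliks(dataset, lif, kernel, stimuli, grid, method)
  list(theta = theta, posteriors = post, comp_ll = ll_new)
}

em_posteriors <- function(comp_ll, alpha) {
  lp <- sweep(comp_ll, 2L, log(pmax(alpha, 1e-300)), "+")
  w <- exp(lp - apply(lp, 1L, max))  # row-wise shift; recycled down columns
  w / rowSums(w)
}

# fingerprint of the dataset a fit was computed on, used to refuse DIC
# comparisons across different datasets
dataset_id <- function(dataset) {
  c(n_trains = length(dataset),
    n_spikes = sum(vapply(dataset, function(tr) length(tr$times), integer(1))),
    checksum = sum(vapply(dataset, function(tr) sum(tr$times), numeric(1))))
}

new_fit_result <- function(model, estimator, stage, theta, loglik, iterations,
                           converged, method, grid, posteriors = NULL,
                           loglik_trace = NULL) {
  structure(list(model = model, estimator = estimator, stage = stage,
                 theta = theta, loglik = loglik, iterations = iterations,
                 converged = converged, method = method, grid = grid,
                 posteriors = posteriors, loglik_trace = loglik_trace),
            class = "lif_fit")
}

#' @export
print.lif_fit <- function(x, ...) {
  cat(sprintf("LIF fit (%s, %s stage, %s estimator, %s backend)\n",
              x$model, x$stage, x$estimator, x$method))
  cat(sprintf("  mu = %.4f  sigma = %.4f\n", x$theta$mu, x$theta$sigma))
  if (!is.null(x$theta$eta))
    cat("  eta = (", paste(signif(x$theta$eta, 5), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$theta$weights))
    cat("  weights = (", paste(signif(x$theta$weights, 4), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  log-likelihood = %.3f  (converged: %s, %d iterations)\n",
              x$loglik, x$converged, x$iterations))
  invisible(x)
}

#' Maximum-likelihood fitting of the LIF stimulus-mixture models
#'
#' Two-stage estimation protocol. In the *single* stage, spike trains each
#' respond to one known stimulus (their `condition`) and
#' \eqn{(\mu, \sigma, \eta)} are estimated jointly by Nelder-Mead on
#' transformed parameters (\eqn{\log\sigma}, \eqn{\log\eta}). In the
#' *mixture* stage the response kernel is frozen (typically at its stage-1
#' estimate) and \eqn{(\mu, \sigma)} plus the mixture weights are
#' estimated: under probability-mixing by direct maximisation of the
#' marginal likelihood (`estimator = "marginal"`) or by the EM algorithm
#' (`estimator = "em"`); under response-averaging by maximising the plain
#' averaged-stimulus likelihood. Weights are parameterised through a
#' softmax, so the simplex constraint holds at every iterate. The decay
#' rate \eqn{\gamma} is always fixed.
#'
#' @param dataset a list of [spike_train()] objects.
#' @param stimuli list of the K component stimuli (single stage: indexed by
#'   each train's `condition`).
#' @param model `"pm"` (probability-mixing) or `"ra"`
#'   (response-averaging); ignored in the single stage, where both models
#'   coincide.
#' @param estimator `"marginal"` or `"em"` (probability-mixing only).
#' @param stage `"single"` or `"mixture"`.
#' @param lif a [lif_params()] object carrying the fixed constants
#'   (\eqn{\gamma}, boundaries, noise model) and the initial
#'   \eqn{(\mu, \sigma)}.
#' @param kernel a [response_kernel()]: initial value in the single stage,
#'   frozen value in the mixture stage.
#' @param weights_init initial mixture weights (default uniform).
#' @param grid an [fpt_grid()].
#' @param method solver backend, see [solve_fpt()].
#' @param control optimizer control: `maxit`, `reltol` (Nelder-Mead),
#'   `em_maxit`, `em_tol` (EM stops when the largest absolute parameter
#'   change drops below `em_tol`), `inner_maxit` (M-step).
#' @return An object of class `lif_fit`. Optimizer non-convergence is
#'   reported through the `converged` flag, not as an error.
#' @export
fit <- function(dataset, stimuli, model = c("pm", "ra"),
                estimator = c("marginal", "em"),
                stage = c("mixture", "single"),
                lif, kernel, weights_init = NULL,
                grid = fpt_grid(), method = "fp_pdf", control = list()) {
  model <- match.arg(model); estimator <- match.arg(estimator)
  stage <- match.arg(stage)
  ctl <- fit_control(control)
  if (inherits(stimuli, "lif_stimulus")) stimuli <- list(stimuli)
  stopifnot(inherits(lif, "lif_params"), inherits(kernel, "lif_kernel"))

  if (stage == "single") {
    obj <- single_objective_factory(dataset, stimuli, lif, grid, method,
                                    fit_eta = TRUE, eta_fixed = NULL)
    p0 <- c(lif$mu, log(lif$sigma), log(pmax(kernel$eta, 1e-6)))
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    theta <- list(mu = opt$par[1], sigma = exp(opt$par[2]),
                  eta = exp(opt$par[3:6]), weights = 1)
    res <- new_fit_result("single", "marginal", stage, theta, -opt$value,
                          opt$counts[1], opt$convergence == 0, method, grid)
    attr(res, "data_id") <- dataset_id(dataset)
    return(res)
  }

  K <- length(stimuli)
  w0 <- if (is.null(weights_init)) rep(1 / K, K) else weights_init / sum(weights_init)

  if (model == "ra" || (model == "pm" && estimator == "marginal")) {
    objfun <- function(par) {
      mu <- par[1]; sigma <- exp(par[2]); w <- softmax_weights(par[-(1:2)])
      lif2 <- lif; lif2$mu <- mu; lif2$sigma <- sigma
      l <- tryCatch({
        if (model == "ra") {
          loglik_ra(dataset, lif2, kernel, stimuli, w, grid, method)
        } else {
          ll <- component_logliks(dataset, lif2, kernel, stimuli, grid, method)
          marginal_from_components(ll, w)
        }
      }, error = function(e) -Inf)
      if (!is.finite(l)) 1e10 else -l
    }
    p0 <- c(lif$mu, log(lif$sigma), weights_to_z(w0))
    opt <- optim(p0, objfun, method = "Nelder-Mead",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    w <- softmax_weights(opt$par[-(1:2)])
    theta <- list(mu = opt$par[1], sigma = exp(opt$par[2]),
                  eta = kernel$eta, weights = w)
    post <- NULL
    if (model == "pm") {
      lif2 <- lif; lif2$mu <- theta$mu; lif2$sigma <- theta$sigma
      ll <- component_logliks(dataset, lif2, kernel, stimuli, grid, method)
      post <- em_posteriors(ll, w)
    }
    res <- new_fit_result(model, "marginal", stage, theta, -opt$value,
                          opt$counts[1], opt$convergence == 0, method, grid,
                          posteriors = post)
    attr(res, "data_id") <- dataset_id(dataset)
    return(res)
  }

  # probability-mixing via EM
  theta <- list(mu = lif$mu, sigma = lif$sigma, alpha = w0)
  lif2 <- lif
  comp_ll <- component_logliks(dataset, lif2, kernel, stimuli, grid, method)
  trace <- marginal_from_components(comp_ll, theta$alpha)
  post <- NULL
  converged <- FALSE
  it <- 0L
  while (it < ctl$em_maxit) {
    it <- it + 1L
    step <- em_step(dataset, theta, lif, kernel, stimuli, grid, method,
                    control = ctl, comp_ll = comp_ll)
    delta <- max(abs(c(step$theta$mu - theta$mu,
                       step$theta$sigma - theta$sigma,
                       step$theta$alpha - theta$alpha)))
    theta <- step$theta
    post <- step$posteriors
    comp_ll <- step$comp_ll
    trace <- c(trace, marginal_from_components(comp_ll, theta$alpha))
    if (delta < ctl$em_tol) { converged <- TRUE; break }
  }
  theta_out <- list(mu = theta$mu, sigma = theta$sigma, eta = kernel$eta,
                    weights = theta$alpha)
  res <- new_fit_result("pm", "em", stage, theta_out, trace[length(trace)], it,
                        converged, method, grid,
                        posteriors = em_posteriors(comp_ll, theta$alpha),
                        loglik_trace = trace)
  attr(res, "data_id") <- dataset_id(dataset)
  res
}

#' Serialize a fit result to JSON
#'
#' @param x an `lif_fit`.
#' @param file output path.
#' @export
fit_to_json <- function(x, file) {
  out <- list(model = x$model, estimator = x$estimator, stage = x$stage,
              mu = x$theta$mu, sigma = x$theta$sigma, eta = x$theta$eta,
              weights = x$theta$weights, loglik = x$loglik,
              iterations = x$iterations, converged = x$converged,
              method = x$method,
              grid = list(dt = x$grid$dt, dx = x$grid$dx))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
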