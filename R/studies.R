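#' Default simulation-study setting
#'
#' The working parameter set of the simulation study: bursting response
#' kernel \eqn{\eta = (50, 25, 40, 15)}, two sinusoidal stimuli
#' \eqn{s_1 = (10, 12, 1, 50)} and \eqn{s_2 = (20, 8, 0, 50)}, membrane
#' parameters \eqn{\mu = 0.5}, \eqn{\sigma = 1}, \eqn{\gamma = 100},
#' \eqn{x_0 = 0.4}, \eqn{x_{\mathrm{th}} = 1}, \eqn{x^- = 0}, and mixture
#' weights \eqn{(0.4, 0.6)}.
#'
#' @return A list with elements `lif`, `kernel`, `stimuli`, `alpha`.
#' @export
study_defaults <- function() {
  list(lif = lif_params(mu = 0.5, sigma = 1, gamma = 100, x0 = 0.4,
                        x_th = 1, x_lower = 0),
       kernel = response_kernel(c(50, 25, 40, 15)),
       stimuli = list(stimulus_sinusoidal(10, 12, 1, 50),
                      stimulus_sinusoidal(20, 8, 0, 50)),
       alpha = c(0.4, 0.6))
}

#' Single-stimulus parameter-recovery study
#'
#' Repeats the stage-1 protocol: simulate `n_trains` four-second spike
#' trains (half attending each sinusoidal stimulus), then estimate
#' \eqn{(\mu, \sigma, \eta)} jointly by maximum likelihood with the chosen
#' backend. Optimisation starts from a deliberately displaced
#' \eqn{(\mu_0, \sigma_0)} and the generating kernel shape.
#'
#' @param n_rep number of repetitions.
#' @param method solver backend.
#' @param grid an [fpt_grid()].
#' @param seed master seed.
#' @param n_trains trains per repetition.
#' @param T trial duration (seconds).
#' @param setting study setting as from [study_defaults()].
#' @param init_mu,init_sigma optimizer starting values.
#' @param control optimizer control passed to [fit()].
#' @return data.frame with one row per repetition: `mu_hat`, `sigma_hat`,
#'   `eta1..eta4`, `loglik`, `converged`.
#' @export
study_single_recovery <- function(n_rep = 10, method = "fp_pdf",
                                  grid = fpt_grid(), seed = 1,
                                  n_trains = 10, T = 4,
                                  setting = study_defaults(),
                                  init_mu = 0.6, init_sigma = 1.5,
                                  control = list()) {
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    ds <- simulate_dataset(setting$lif, setting$kernel, setting$stimuli,
                           mixture = NULL,
                           sim = sim_config(T = T, n_trains = n_trains,
                                            seed = train_seed(seed, 31 * r)),
                           components = rep(seq_along(setting$stimuli),
                                            length.out = n_trains))
    lif0 <- setting$lif; lif0$mu <- init_mu; lif0$sigma <- init_sigma
    f <- fit(ds, setting$stimuli, stage = "single", lif = lif0,
             kernel = setting$kernel, grid = grid, method = method,
             control = control)
    out[[r]] <- data.frame(rep = r, mu_hat = f$theta$mu,
                           sigma_hat = f$theta$sigma,
                           eta1 = f$theta$eta[1], eta2 = f$theta$eta[2],
                           eta3 = f$theta$eta[3], eta4 = f$theta$eta[4],
                           loglik = f$loglik, converged = f$converged)
  }
  do.call(rbind, out)
}

# latent allocation fixed at its expectation (e.g. 4 of 10 trains on the
# first stimulus for alpha = (0.4, 0.6)), as in the study's mixture
# repetitions; this isolates the estimator's own spread from binomial
# allocation noise
stratified_components <- function(weights, n_trains) {
  counts <- round(weights * n_trains)
  while (sum(counts) > n_trains) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_trains) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  rep(seq_along(weights), times = counts)
}

# stage-2 fit of one model to one dataset, optionally refined on a second
# (finer) grid starting from the first stage's optimum
fit_mixture_model <- function(ds, stimuli, model, estimator, setting,
                              init_mu, init_sigma, grid, method,
                              control = list(), refine = NULL) {
  lif0 <- setting$lif; lif0$mu <- init_mu; lif0$sigma <- init_sigma
  f <- fit(ds, stimuli, model = model, estimator = estimator,
           stage = "mixture", lif = lif0, kernel = setting$kernel,
           grid = grid, method = method, control = control)
  if (!is.null(refine)) {
    lif1 <- setting$lif; lif1$mu <- f$theta$mu; lif1$sigma <- f$theta$sigma
    f <- fit(ds, stimuli, model = model, estimator = estimator,
             stage = "mixture", lif = lif1, kernel = setting$kernel,
             weights_init = f$theta$weights,
             grid = refine$grid, method = refine$method,
             control = refine$control)
  }
  f
}

#' Mixture-fit recovery and misspecification study
#'
#' Repeats the stage-2 protocol: simulate probability-mixing and
#' response-averaging datasets at the default setting and fit selected
#' model/data combinations with the response kernel frozen. The
#' combinations follow the naming `"<fit>_on_<data>"`; `pm_on_pm` is fitted
#' with the chosen estimator(s).
#'
#' @inheritParams study_single_recovery
#' @param combos character vector among `"pm_on_pm"` (marginal),
#'   `"pm_on_pm_em"`, `"ra_on_ra"`, `"pm_on_ra"`, `"ra_on_pm"`.
#' @param init_mu,init_sigma stage-2 starting values for \eqn{(\mu,\sigma)}
#'   (in the full protocol these come from a stage-1 fit).
#' @return data.frame with one row per repetition and combination:
#'   estimates, log-likelihood, convergence.
#' @export
study_mixture_recovery <- function(n_rep = 10, method = "fp_cdf",
                                   grid = fpt_grid(), seed = 1,
                                   n_trains = 10, T = 4,
                                   setting = study_defaults(),
                                   combos = c("pm_on_pm_em", "ra_on_ra",
                                              "pm_on_ra", "ra_on_pm"),
                                   init_mu = 0.6, init_sigma = 1.5,
                                   control = list()) {
  pm_mix <- mixture_params("probability_mixing", setting$alpha)
  ra_mix <- mixture_params("response_averaging", setting$alpha)
  rows <- list()
  for (r in seq_len(n_rep)) {
    ds_pm <- simulate_dataset(setting$lif, setting$kernel, setting$stimuli,
                              pm_mix, sim_config(T = T, n_trains = n_trains,
                                                 seed = train_seed(seed, 101 * r)),
                              components = stratified_components(pm_mix$weights,
                                                                 n_trains))
    ds_ra <- simulate_dataset(setting$lif, setting$kernel, setting$stimuli,
                              ra_mix, sim_config(T = T, n_trains = n_trains,
                                                 seed = train_seed(seed, 101 * r + 50)))
    for (cmb in combos) {
      model <- if (startsWith(cmb, "pm")) "pm" else "ra"
      estimator <- if (cmb == "pm_on_pm_em") "em" else "marginal"
      ds <- if (endsWith(cmb, "pm") || endsWith(cmb, "pm_em")) ds_pm else ds_ra
      f <- fit_mixture_model(ds, setting$stimuli, model, estimator, setting,
                             init_mu, init_sigma, grid, method, control)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, combo = cmb, mu_hat = f$theta$mu,
                   sigma_hat = f$theta$sigma, w1_hat = f$theta$weights[1],
                   loglik = f$loglik, converged = f$converged)
    }
  }
  do.call(rbind, rows)
}

#' KS rejection study for model selection
#'
#' Repeats the residual goodness-of-fit protocol: simulate
#' probability-mixing and response-averaging datasets, fit both models to
#' both, and test the pooled uniform residuals of each fit with the KS
#' test at the 5% level. Model selection requires accurate spike-time
#' CDFs, so fits are first run on a coarse working grid and then refined
#' on the reporting grid (default the fine reference grid with the
#' Fokker-Planck PDF backend).
#'
#' @inheritParams study_mixture_recovery
#' @param coarse_grid,coarse_method working grid for the initial fit.
#' @param grid,method reporting grid on which fits are refined and
#'   residuals are evaluated.
#' @return data.frame with one row per repetition and combination:
#'   KS statistic, p-value, rejection at 5%.
#' @export
study_ks_rejection <- function(n_rep = 5, grid = fine_grid(),
                               method = "fp_pdf", seed = 1,
                               coarse_grid = fpt_grid(),
                               coarse_method = "fp_cdf",
                               n_trains = 10, T = 4,
                               setting = study_defaults(),
                               init_mu = 0.6, init_sigma = 1.5,
                               control = list()) {
  pm_mix <- mixture_params("probability_mixing", setting$alpha)
  ra_mix <- mixture_params("response_averaging", setting$alpha)
  # the refinement is warm-started at the coarse optimum, so a short
  # Nelder-Mead polish on the reporting grid suffices
  refine <- list(grid = grid, method = method,
                 control = modifyList(list(maxit = 40, reltol = 1e-6), control))
  rows <- list()
  for (r in seq_len(n_rep)) {
    ds_pm <- simulate_dataset(setting$lif, setting$kernel, setting$stimuli,
                              pm_mix, sim_config(T = T, n_trains = n_trains,
                                                 seed = train_seed(seed, 211 * r)),
                              components = stratified_components(pm_mix$weights,
                                                                 n_trains))
    ds_ra <- simulate_dataset(setting$lif, setting$kernel, setting$stimuli,
                              ra_mix, sim_config(T = T, n_trains = n_trains,
                                                 seed = train_seed(seed, 211 * r + 97)))
    for (cmb in c("pm_on_pm", "ra_on_pm", "pm_on_ra", "ra_on_ra")) {
      model <- substr(cmb, 1, 2)
      ds <- if (endsWith(cmb, "_pm")) ds_pm else ds_ra
      f <- fit_mixture_model(ds, setting$stimuli, model, "marginal", setting,
                             init_mu, init_sigma, coarse_grid, coarse_method,
                             control, refine = refine)
      res <- uniform_residuals(ds, f, setting$stimuli, setting$lif)
      ks <- ks_uniformity(res)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, combo = cmb, statistic = ks$statistic,
                   p_value = ks$p_value, reject = ks$reject,
                   correct_model = cmb %in% c("pm_on_pm", "ra_on_ra"))
    }
  }
  do.call(rbind, rows)
}
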