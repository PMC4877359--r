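st <- default_setting

test_that("single-train log-likelihood composes per-ISI densities", {
  one <- spike_train(0.045, duration = 0.2, condition = 1)
  ll <- loglik_single(one, st$lif, st$kernel, st$stimuli[[1]],
                      fpt_grid(t_max = 0.2), "fp_pdf")
  d <- isi_density(st$lif, st$kernel, st$stimuli[[1]], numeric(0), 0.045,
                   fpt_grid(t_max = 0.2), "fp_pdf")
  expect_equal(ll, log(d$g), tolerance = 1e-10)

  expect_error(loglik_single(spike_train(numeric(0), 1), st$lif, st$kernel,
                             st$stimuli[[1]]), "empty")
  # underflow is floored, never NaN: force an absurd parameter value
  bad <- st$lif; bad$mu <- -5
  expect_true(is.finite(loglik_single(one, bad, st$kernel, st$stimuli[[1]],
                                      fpt_grid(t_max = 0.2), "fp_pdf")))
})

test_that("marginal likelihood reduces, permutes and log-sum-exps correctly", {
  ds <- pm_small_dataset()[1:2]
  grid <- fpt_grid()
  ll <- component_logliks(ds, st$lif, st$kernel, st$stimuli, grid, "fp_cdf")
  expect_equal(dim(ll), c(2L, 2L))

  # alpha = (1, 0) degenerates to the single-stimulus likelihood
  expect_equal(marginal_loglik(ds, st$lif, st$kernel, st$stimuli, c(1, 0),
                               grid, "fp_cdf"),
               sum(vapply(ds, loglik_single, numeric(1), st$lif, st$kernel,
                          st$stimuli[[1]], grid, "fp_cdf")),
               tolerance = 1e-10)
  # K = 1 marginal equals the plain likelihood
  expect_equal(marginal_loglik(ds, st$lif, st$kernel, st$stimuli[1], 1,
                               grid, "fp_cdf"),
               sum(vapply(ds, loglik_single, numeric(1), st$lif, st$kernel,
                          st$stimuli[[1]], grid, "fp_cdf")),
               tolerance = 1e-10)
  # joint permutation invariance
  expect_equal(marginal_loglik(ds, st$lif, st$kernel, st$stimuli, c(0.4, 0.6),
                               grid, "fp_cdf"),
               marginal_loglik(ds, st$lif, st$kernel, rev(st$stimuli),
                               c(0.6, 0.4), grid, "fp_cdf"),
               tolerance = 1e-12)
  # against direct summation of the mixture on the same component table
  direct <- sum(log(0.4 * exp(ll[, 1] - 200) + 0.6 * exp(ll[, 2] - 200)) + 200)
  expect_equal(marginal_loglik(ds, st$lif, st$kernel, st$stimuli, c(0.4, 0.6),
                               grid, "fp_cdf"), direct, tolerance = 1e-9)
  expect_error(marginal_loglik(ds, st$lif, st$kernel, st$stimuli, c(0.7, 0.6)),
               "sum to one")
})

test_that("response-averaging likelihood handles degenerate and constant cases", {
  ds <- ra_small_dataset()[1:2]
  grid <- fpt_grid()
  # beta = e_2 equals the single-stimulus likelihood for stimulus 2
  expect_equal(loglik_ra(ds, st$lif, st$kernel, st$stimuli, c(0, 1), grid, "fp_cdf"),
               sum(vapply(ds, loglik_single, numeric(1), st$lif, st$kernel,
                          st$stimuli[[2]], grid, "fp_cdf")),
               tolerance = 1e-10)
  # equal constant stimuli: likelihood independent of the weights
  consts <- list(const_stim(50), const_stim(50))
  expect_equal(loglik_ra(ds, st$lif, st$kernel, consts, c(0.2, 0.8), grid, "fp_cdf"),
               loglik_ra(ds, st$lif, st$kernel, consts, c(0.9, 0.1), grid, "fp_cdf"),
               tolerance = 1e-10)
})

test_that("likelihood surfaces peak near the generating parameters", {
  ds <- single_dataset()[1:5]
  grid <- fpt_grid()
  ll_mu <- vapply(c(0.3, 0.5, 0.7), function(mu) {
    lif <- st$lif; lif$mu <- mu
    sum(vapply(ds, loglik_single, numeric(1), lif, st$kernel,
               st$stimuli[[1]], grid, "fp_cdf"))
  }, numeric(1))
  expect_gt(ll_mu[2], ll_mu[1])
  expect_gt(ll_mu[2], ll_mu[3])

  ds_ra <- ra_small_dataset()
  ll_b <- vapply(c(0.1, 0.25, 0.4), function(b1)
    loglik_ra(ds_ra, st$lif, st$kernel, st$stimuli, c(b1, 1 - b1), grid, "fp_cdf"),
    numeric(1))
  expect_true(all(diff(ll_b) > 0))  # improves toward the generating beta1 = 0.4
})

test_that("EM posteriors are normalized and reduce to the prior under flat evidence", {
  flat <- matrix(-123.4, nrow = 3, ncol = 2)
  post <- lifmix:::em_posteriors(flat, c(0.3, 0.7))
  expect_equal(post, matrix(rep(c(0.3, 0.7), each = 3), 3, 2))
  set.seed(2)
  rnd <- matrix(rnorm(8, -100, 5), 4, 2)
  post <- lifmix:::em_posteriors(rnd, c(0.5, 0.5))
  expect_equal(rowSums(post), rep(1, 4))
  expect_true(all(post >= 0))
})

test_that("EM is monotone, agrees with the marginal MLE, and handles K = 1", {
  ds <- pm_small_dataset()
  grid <- fpt_grid()
  lif0 <- st$lif; lif0$mu <- 0.55; lif0$sigma <- 1.2
  f_em <- fit(ds, st$stimuli, model = "pm", estimator = "em",
              lif = lif0, kernel = st$kernel, grid = grid, method = "fp_cdf",
              control = list(inner_maxit = 80))
  # marginal log-likelihood never decreases across EM iterations
  expect_true(all(diff(f_em$loglik_trace) > -1e-3))
  expect_equal(rowSums(f_em$posteriors), rep(1, length(ds)))

  f_mg <- fit(ds, st$stimuli, model = "pm", estimator = "marginal",
              lif = lif0, kernel = st$kernel, grid = grid, method = "fp_cdf")
  expect_lt(abs(f_em$theta$weights[1] - f_mg$theta$weights[1]), 0.05)
  expect_lt(abs(f_em$theta$mu - f_mg$theta$mu), 0.02)
  expect_lt(abs(f_em$theta$sigma - f_mg$theta$sigma), 0.02)

  # K = 1: the EM degenerates to a single-stimulus fit with alpha = 1
  f1 <- fit(ds[1:2], st$stimuli[1], model = "pm", estimator = "em",
            lif = lif0, kernel = st$kernel, grid = grid, method = "fp_cdf",
            control = list(em_maxit = 5, inner_maxit = 60))
  expect_equal(f1$theta$weights, 1)
})
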