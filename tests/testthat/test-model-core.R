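test_that("response kernel evaluates its closed form and classifies regimes", {
  burst <- response_kernel(c(50, 25, 40, 15))
  expect_identical(burst$kind, "bursting")
  expect_equal(eval_kernel(burst, 0), 10)

  decay <- response_kernel(c(0, 0, 2, 0.5))
  expect_identical(decay$kind, "decaying")
  expect_equal(eval_kernel(decay, 0), -2)

  delay <- response_kernel(c(20, 8, 50, 15))
  expect_identical(delay$kind, "delaying")

  # vanishing tail and closed form at random draws
  expect_lt(abs(eval_kernel(burst, 50)), 1e-12)
  set.seed(1)
  for (i in 1:50) {
    eta <- runif(4, 0, 60)
    tt <- runif(20, 0, 0.5)
    expect_equal(eval_kernel(response_kernel(eta), tt),
                 eta[1] * exp(-eta[2] * tt) - eta[3] * exp(-eta[4] * tt),
                 tolerance = 1e-12)
  }

  expect_error(eval_kernel(burst, -0.1), "nonnegative")
  expect_error(response_kernel(c(-1, 1, 1, 1)), "nonnegative")
  expect_error(response_kernel(c(50, 25, 40, 15), kind = "delaying"),
               "inequalities")
})

test_that("tabulated post-spike current matches exact superposition and improves with resolution", {
  kern <- default_setting$kernel
  history <- c(0.05, 0.081, 0.12)
  tt <- seq(0.121, 0.6, by = 0.0013)
  exact <- rowSums(vapply(history, function(tau) eval_kernel(kern, tt - tau),
                          numeric(length(tt))))
  err <- function(dt) {
    approxed <- post_spike_current(kern, history, tt, dt = dt)
    max(abs(approxed - exact))
  }
  expect_lt(err(5e-4), err(2e-3))      # finer table, smaller error
  expect_lt(err(2e-3), 0.7)            # within stated tolerance at dt = 2 ms
  expect_lt(err(5e-4), 0.2)

  expect_equal(post_spike_current(kern, numeric(0), tt), rep(0, length(tt)))
  single <- post_spike_current(kern, 0.05, 0.3, dt = 5e-4)
  expect_equal(single, eval_kernel(kern, 0.25), tolerance = 0.02)
  expect_error(post_spike_current(kern, c(0.2, 0.1), 0.3), "increasing")
})

test_that("stimulus families evaluate per their definitions", {
  expect_equal(eval_stimulus(const_stim(60), c(0, 1.7, 3)), rep(60, 3))
  s1 <- stimulus_sinusoidal(10, 12, 1, 50)
  expect_equal(eval_stimulus(s1, 0), 10 * sin(1) + 50, tolerance = 1e-12)

  # piecewise-constant stimulus of the generalized single-stimulus study
  pw <- stimulus_piecewise(c(50, 70, 50, 30, 50, 60),
                           c(0, 1.3, 1.7, 2.3, 2.7, 3.8, 5))
  expect_equal(eval_stimulus(pw, 0.5), 50)
  expect_equal(eval_stimulus(pw, c(1.3, 2.5, 4)), c(70, 30, 60))
  expect_error(eval_stimulus(pw, 5.5), "domain")
  expect_error(stimulus_piecewise(c(1, 2), c(0, 1)), "breakpoint")
  expect_error(stimulus_piecewise(c(1, 2), c(0, 1, 0.5)), "increasing")

  # sampled path: previous-point hold at its own sampling step
  path <- stimulus_ou_path(c(1, 3, 5), t0 = 0, dt = 0.1)
  expect_equal(eval_stimulus(path, c(0.0, 0.05, 0.1, 0.25)), c(1, 1, 3, 5))
  expect_error(eval_stimulus(path, -0.2), "before")
})

test_that("stimulus algebra supports scaling, sums and weighted averages", {
  a <- const_stim(10); b <- const_stim(20)
  expect_equal(eval_stimulus(stim_scale(a, 3), 1), 30)
  expect_equal(eval_stimulus(stim_add(a, b), 0.3), 30)
  expect_equal(eval_stimulus(average_stimulus(list(a, b), c(0.4, 0.6)), 2), 16)
  pert <- stim_add(stim_scale(const_stim(50), 1.2), stimulus_sinusoidal(3, 10, 0, 0))
  expect_equal(eval_stimulus(pert, 0.5), 60 + 3 * sin(5), tolerance = 1e-12)
})

test_that("mixture weights are validated and normalized on construction", {
  m <- mixture_params("probability_mixing", c(2, 3))
  expect_equal(m$weights, c(0.4, 0.6))
  expect_equal(sum(m$weights), 1)
  expect_error(mixture_params("probability_mixing", c(-0.1, 1.1)), "nonnegative")
  expect_error(mixture_params("response_averaging", c(0, 0)), "positive sum")
})

test_that("total drift current combines leak, stimulus and post-spike terms", {
  lif <- default_setting$lif
  kern <- default_setting$kernel
  a <- const_stim(10); b <- const_stim(20)
  ra <- mixture_params("response_averaging", c(0.4, 0.6))
  pm <- mixture_params("probability_mixing", c(0.4, 0.6))

  # weighted average of constant stimuli plus gamma*mu, no history
  expect_equal(total_current(lif, kern, list(a, b), ra, t = 1),
               lif$gamma * lif$mu + 16)
  # degenerate RA weights equal the PM component
  ra10 <- mixture_params("response_averaging", c(1, 0))
  expect_equal(total_current(lif, kern, list(a, b), ra10, t = 0.7),
               total_current(lif, kern, list(a, b), pm, t = 0.7, component = 1))
  # K = 1: both models coincide
  ra1 <- mixture_params("response_averaging", 1)
  pm1 <- mixture_params("probability_mixing", 1)
  expect_equal(total_current(lif, kern, list(a), ra1, t = 0.2, history = 0.1),
               total_current(lif, kern, list(a), pm1, t = 0.2, component = 1,
                             history = 0.1))
  expect_error(total_current(lif, kern, list(a, b), pm, t = 1), "component")

  # history contributes through the kernel table
  with_h <- total_current(lif, kern, list(a, b), ra, t = 0.5, history = 0.45)
  expect_equal(with_h - total_current(lif, kern, list(a, b), ra, t = 0.5),
               eval_kernel(kern, 0.05), tolerance = 0.05)
})

test_that("spike trains and LIF parameters enforce their invariants", {
  expect_error(spike_train(c(0.2, 0.1), 1), "increasing")
  expect_error(spike_train(c(0, 0.1), 1), "\\(0, duration\\]")
  expect_error(spike_train(0.5, 0.3), "\\(0, duration\\]")
  expect_silent(spike_train(c(0.1, 0.2), 1, condition = 2))
  expect_error(lif_params(mu = 0.5, sigma = -1), "sigma")
  expect_error(lif_params(mu = 0.5, sigma = 1, x0 = 1.2), "x_lower < x0 < x_th")
  expect_error(fpt_grid(dt = 0), "positive")
})
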