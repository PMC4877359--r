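test_that("noise-free simulation matches the deterministic crossing time", {
  # sigma -> 0: X' = -gamma X + c, crossing time has the closed form
  # t* = log((c/gamma - x0)/(c/gamma - x_th))/gamma for c/gamma > x_th
  lif <- lif_params(mu = 0.5, sigma = 1e-12)
  cc <- 105  # total current; stimulus supplies c - gamma*mu
  tstar <- log((cc / lif$gamma - lif$x0) / (cc / lif$gamma - lif$x_th)) / lif$gamma
  tr <- simulate_train(lif, null_kernel, const_stim(cc - lif$gamma * lif$mu),
                       sim = sim_config(T = 0.3, dt_sim = 1e-5), seed = 1)
  expect_equal(tr$times[1], tstar, tolerance = 1e-3)
  # constant drive, no kernel: deterministic periodic spiking
  isis <- diff(tr$times)
  expect_lt(diff(range(isis)), 2.1e-5)
  expect_equal(mean(isis), tstar, tolerance = 1e-3)
})

test_that("simulated trains satisfy the threshold/reset contract and are reproducible", {
  st <- default_setting
  tr <- simulate_train(st$lif, st$kernel, st$stimuli[[1]],
                       sim = sim_config(T = 2, record_voltage = TRUE), seed = 5)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$times > 0 & tr$times <= 2))
  # voltage resets to x0 right after each detected crossing
  v <- attr(tr, "voltage")
  idx <- round(tr$times / 1e-4) + 1L
  expect_true(all(v[idx] == st$lif$x0))

  tr2 <- simulate_train(st$lif, st$kernel, st$stimuli[[1]],
                        sim = sim_config(T = 2), seed = 5)
  expect_identical(tr$times, tr2$times)

  ds1 <- simulate_dataset(st$lif, st$kernel, st$stimuli, mixture = NULL,
                          sim = sim_config(T = 1, n_trains = 3, seed = 9),
                          components = c(1, 2, 1))
  ds2 <- simulate_dataset(st$lif, st$kernel, st$stimuli, mixture = NULL,
                          sim = sim_config(T = 1, n_trains = 3, seed = 9),
                          components = c(1, 2, 1))
  expect_identical(lapply(ds1, `[[`, "times"), lapply(ds2, `[[`, "times"))
  expect_error(simulate_train(st$lif, st$kernel, st$stimuli[[1]],
                              sim_config(T = -1)), "positive")
})

test_that("probability-mixing draws one latent component per train with the right frequencies", {
  st <- default_setting
  mix <- mixture_params("probability_mixing", c(0.3, 0.7))
  labels <- vapply(1:400, function(i) {
    simulate_train(st$lif, null_kernel, lapply(c(40, 60), const_stim), mix,
                   sim = sim_config(T = 0.01), seed = i)$component
  }, integer(1))
  expect_true(all(labels %in% 1:2))
  # Binomial(400, 0.3): 4 sd band around the mean frequency
  expect_lt(abs(mean(labels == 1L) - 0.3), 4 * sqrt(0.3 * 0.7 / 400))
})

test_that("OU stimulus paths have the stationary mean and variance and stay fixed", {
  quiet <- simulate_ou_stimulus(c(50, 0), dt = 0.01, T = 1, seed = 2)
  expect_equal(eval_stimulus(quiet, c(0, 0.5, 0.99)), rep(50, 3))

  s <- c(50, 20)
  ou <- simulate_ou_stimulus(s, dt = 1e-3, T = 200, seed = 4)
  path <- ou$terms[[1]]$path
  expect_equal(mean(path), s[1], tolerance = 0.1)          # stationary mean s1
  expect_equal(var(path), s[2]^2 / 2, tolerance = 0.15)    # stationary var s2^2/2

  # a stored realization evaluates identically across uses
  tt <- seq(0, 100, by = 0.37)
  expect_identical(eval_stimulus(ou, tt), eval_stimulus(ou, tt))
})

test_that("Feller paths stay nonnegative under square-root noise", {
  lif <- lif_params(mu = 0.3, sigma = 1.5, x0 = 0.4, noise_model = "feller")
  tr <- simulate_train(lif, default_setting$kernel, const_stim(20),
                       sim = sim_config(T = 2, record_voltage = TRUE), seed = 6)
  expect_true(all(attr(tr, "voltage") >= 0))
})

test_that("halving the Euler step leaves the mean ISI within Monte-Carlo error", {
  lif <- default_setting$lif
  n <- 400
  fp1 <- mc_first_passage(lif, 105, n, T = 0.4, dt = 1e-4, seed = 11)
  fp2 <- mc_first_passage(lif, 105, n, T = 0.4, dt = 5e-5, seed = 12)
  se <- sqrt(var(fp1) / n + var(fp2) / n)
  expect_lt(abs(mean(fp1) - mean(fp2)), 3 * se)
})
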