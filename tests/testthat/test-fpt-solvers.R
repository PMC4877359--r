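lif0 <- default_setting$lif

test_that("threshold-free transition moments match their closed forms", {
  cur <- function(t) rep(105, length(t))
  mv <- transition_mean_var(lif0, cur, v = 0.4, s = 0.2, t = 0.2)
  expect_equal(unname(mv), c(0.4, 0))

  # constant current: M = v e^{-g D} + (c/g)(1 - e^{-g D})
  D <- 0.013
  mv <- transition_mean_var(lif0, cur, v = 0.4, s = 0.1, t = 0.1 + D, dt = 1e-4)
  expect_equal(mv[["M"]],
               0.4 * exp(-100 * D) + 1.05 * (1 - exp(-100 * D)),
               tolerance = 1e-4)  # trapezoid quadrature accuracy at dt = 1e-4
  expect_equal(mv[["V"]], 1 / 200 * (1 - exp(-200 * D)), tolerance = 1e-12)

  # long-lag variance saturates at sigma^2 / (2 gamma)
  mv <- transition_mean_var(lif0, cur, v = 0.4, s = 0, t = 1)
  expect_equal(mv[["V"]], lif0$sigma^2 / (2 * lif0$gamma), tolerance = 1e-8)
  expect_error(transition_mean_var(lif0, cur, 0.4, s = 1, t = 0.5), ">=")
})

test_that("PDE backends conserve probability and keep CDF structure", {
  grid <- fpt_grid(t_max = 0.25)
  cur <- function(t) 105 + 5 * sin(12 * t)
  pdf <- solve_fpt(lif0, cur, grid, "fp_pdf", return_field = TRUE)
  f <- attr(pdf, "field")
  # interior mass + absorbed mass stays 1 (finite-volume bookkeeping)
  mass <- rowSums(f) * grid$dx
  expect_lt(max(abs(mass + pdf$G - 1)), 1e-9)
  # and absorbed mass matches the time-integrated density
  expect_equal(pdf$G[length(pdf$G)],
               sum(0.5 * grid$dt * (pdf$g[-1] + pdf$g[-length(pdf$g)])),
               tolerance = 5e-3)

  cdf <- solve_fpt(lif0, cur, grid, "fp_cdf", return_field = TRUE)
  Ffield <- attr(cdf, "field")
  # Heaviside initial condition at x0
  xs <- lif0$x_lower + seq_len(ncol(Ffield)) * grid$dx
  expect_equal(unname(Ffield[1, ]), as.numeric(xs >= lif0$x0 - 1e-12))
  # F is monotone nondecreasing in x at every time step up to a small
  # discretization wiggle that shrinks under grid refinement
  wiggle <- function(g2) {
    s <- solve_fpt(lif0, cur, g2, "fp_cdf", return_field = TRUE)
    -min(apply(attr(s, "field"), 1, function(row) min(diff(c(0, row)))))
  }
  w_coarse <- wiggle(grid)
  w_fine <- wiggle(fine_grid(t_max = 0.25))
  expect_lt(w_coarse, 0.03)
  expect_lt(w_fine, w_coarse)
  expect_lt(w_fine, 0.003)

  for (m in c("fp_pdf", "fp_cdf", "volterra1", "volterra2")) {
    s <- solve_fpt(lif0, cur, grid, m)
    expect_true(all(s$g >= 0))
    expect_true(all(diff(s$G) >= 0))
    expect_true(all(s$G >= 0 & s$G <= 1))
    expect_equal(s$g[1], 0)                       # g(0) = 0 for every backend
    expect_lte(sum(s$g) * grid$dt, 1 + 1e-6)      # sub-density on finite horizon
  }
})

test_that("PDF and CDF formulations agree and their gap shrinks under refinement", {
  cur <- function(t) 105 + 5 * sin(12 * t)
  gap <- function(grid) {
    a <- solve_fpt(lif0, cur, grid, "fp_pdf")
    b <- solve_fpt(lif0, cur, grid, "fp_cdf")
    max(abs(a$G - b$G))
  }
  g_coarse <- gap(fpt_grid(t_max = 0.25))
  g_fine <- gap(fine_grid(t_max = 0.25))
  expect_lt(g_fine, g_coarse)
  expect_lt(g_fine, 0.02)
})

test_that("all four backends converge to a common fine-grid solution", {
  cur <- function(t) rep(105, length(t))
  ref <- solve_fpt(lif0, cur, fine_grid(t_max = 0.3), "volterra2")
  for (m in c("fp_pdf", "fp_cdf", "volterra1")) {
    s <- solve_fpt(lif0, cur, fine_grid(t_max = 0.3), m)
    expect_lt(max(abs(s$G - ref$G)), 0.02)
  }
  # coarse solutions differ visibly more than fine ones
  worst_coarse <- max(vapply(c("fp_pdf", "fp_cdf", "volterra1"), function(m) {
    s <- solve_fpt(lif0, cur, fpt_grid(t_max = 0.3), m)
    max(abs(s$G - approx(ref$times, ref$G, s$times)$y))
  }, numeric(1)))
  expect_gt(worst_coarse, 0.02)
})

test_that("Volterra backends refuse state-dependent noise; Fokker-Planck accepts it", {
  feller <- lif_params(mu = 0.5, sigma = 1, noise_model = "feller")
  cur <- function(t) rep(105, length(t))
  expect_error(solve_fpt(feller, cur, fpt_grid(t_max = 0.1), "volterra1"),
               "additive")
  expect_error(solve_fpt(feller, cur, fpt_grid(t_max = 0.1), "volterra2"),
               "additive")
  s <- solve_fpt(feller, cur, fpt_grid(t_max = 0.4), "fp_pdf")
  expect_true(all(s$g >= 0) && all(diff(s$G) >= 0))
  s2 <- solve_fpt(feller, cur, fpt_grid(t_max = 0.4), "fp_cdf")
  expect_equal(s2$G[length(s2$G)], s$G[length(s$G)], tolerance = 0.05)
})

test_that("isi_density is pure, respects degenerate weights, and guards its horizon", {
  st <- default_setting
  hist <- c(0.05, 0.08)
  a <- isi_density(st$lif, st$kernel, st$stimuli[[1]], hist, 0.04,
                   fpt_grid(t_max = 0.2), "fp_cdf")
  b <- isi_density(st$lif, st$kernel, st$stimuli[[1]], hist, 0.04,
                   fpt_grid(t_max = 0.2), "fp_cdf")
  expect_identical(a$g, b$g)
  expect_identical(a$G, b$G)

  # probability-mixing component k equals response-averaging with weight e_k
  avg <- average_stimulus(st$stimuli, c(0, 1))
  pm_k <- isi_density(st$lif, st$kernel, st$stimuli[[2]], hist, 0.04,
                      fpt_grid(t_max = 0.2), "fp_pdf")
  ra_ek <- isi_density(st$lif, st$kernel, avg, hist, 0.04,
                       fpt_grid(t_max = 0.2), "fp_pdf")
  expect_equal(pm_k$g, ra_ek$g, tolerance = 1e-12)

  expect_error(isi_density(st$lif, st$kernel, st$stimuli[[1]], hist, 0.5,
                           fpt_grid(t_max = 0.2), "fp_pdf"), "t_max")
})

test_that("coarse-grid bias is largest and positive for the first Volterra, smallest for the second", {
  st <- default_setting
  hist <- 0.07
  ref <- isi_density(st$lif, st$kernel, st$stimuli[[1]], hist, 0.05,
                     fine_grid(t_max = 0.06), "volterra2")$solution
  reff <- approxfun(ref$times, ref$g)
  tt <- seq(0.002, 0.01, by = 0.002)  # beginning of the ISI
  bias <- vapply(c("fp_pdf", "fp_cdf", "volterra1", "volterra2"), function(m) {
    s <- isi_density(st$lif, st$kernel, st$stimuli[[1]], hist, 0.05,
                     fpt_grid(t_max = 0.06), m)$solution
    mean(approx(s$times, s$g, tt)$y - reff(tt))
  }, numeric(1))
  expect_gt(bias[["volterra1"]], 0)                       # inflates early density
  expect_equal(which.max(abs(bias)), c(volterra1 = 3L))   # and is the worst offender
  expect_equal(which.min(abs(bias)), c(volterra2 = 4L))   # V2 closest to the reference
})
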