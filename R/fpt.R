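#' Threshold-free Gaussian transition moments
#'
#' For the additive-noise (OU) membrane process without threshold, the
#' transition law from state `v` at time `s` is Gaussian with mean
#' \deqn{M(t|v,s) = v e^{-\gamma(t-s)} +
#'   \int_s^t I_{\mathrm{total}}(u) e^{-\gamma(t-u)}\,du}
#' and variance
#' \eqn{V(t|s) = \sigma^2 (1 - e^{-2\gamma(t-s)}) / (2\gamma)}.
#' The mean integral is computed by the trapezoid rule on the solver grid;
#' the variance is closed form.
#'
#' @param lif a [lif_params()] object (additive noise).
#' @param current_fn function of time returning the total current
#'   \eqn{I_{\mathrm{total}}(u) = \gamma\mu + I(u) + H(u)}.
#' @param v state at time `s`.
#' @param s,t start and end times, `t >= s`.
#' @param dt quadrature step.
#' @return `c(M = ..., V = ...)`.
#' @export
transition_mean_var <- function(lif, current_fn, v, s, t, dt = 0.002) {
  stopifnot(inherits(lif, "lif_params"))
  if (t < s) stop("t must be >= s")
  g <- lif$gamma
  if (t == s) return(c(M = v, V = 0))
  u <- seq(s, t, length.out = max(2L, ceiling((t - s) / dt) + 1L))
  integrand <- current_fn(u) * exp(-g * (t - u))
  M <- v * exp(-g * (t - s)) + sum(diff(u) * (integrand[-1] + integrand[-length(u)]) / 2)
  V <- lif$sigma^2 / (2 * g) * (1 - exp(-2 * g * (t - s)))
  c(M = M, V = V)
}

method_code <- function(method) {
  switch(match.arg(method, c("fp_pdf", "fp_cdf", "volterra1", "volterra2")),
         fp_pdf = 1L, fp_cdf = 2L, volterra1 = 3L, volterra2 = 4L)
}

new_fpt_solution <- function(times, g, G, method, itot) {
  structure(list(times = times, g = g, G = G, method = method, itot = itot),
            class = "fpt_solution")
}

#' @export
print.fpt_solution <- function(x, ...) {
  cat(sprintf("First-passage-time solution (%s): %d steps, G(t_max) = %.4f\n",
              x$method, length(x$times) - 1L, x$G[length(x$G)]))
  invisible(x)
}

#' @export
as.data.frame.fpt_solution <- function(x, ...) {
  data.frame(t = x$times, g = x$g, G = x$G)
}

#' Export a first-passage-time solution to CSV
#'
#' @param x an `fpt_solution`.
#' @param file output path; columns `(t, g, G)`.
#' @export
fpt_solution_to_csv <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Solve the first-passage-time problem of one ISI
#'
#' Computes the spike-time density \eqn{g(t)} and CDF \eqn{G(t)} of a
#' single interspike interval for a given total-current trajectory, by one
#' of four numerical backends:
#' \describe{
#'   \item{`fp_pdf`}{Fokker-Planck equation for the membrane PDF
#'     \eqn{f(x,t)}, Crank-Nicolson in time with Thomas tridiagonal solves,
#'     absorbing boundary at \eqn{x_{\mathrm{th}}}, zero-flux reflecting
#'     boundary at \eqn{x^-}, Dirac initial mass in the cell containing
#'     \eqn{x_0}; \eqn{g} is minus the backward time difference of the
#'     interior mass.}
#'   \item{`fp_cdf`}{the analogous PDE for the membrane CDF \eqn{F(x,t)}
#'     with \eqn{\partial_x F(x_{\mathrm{th}},t) = 0}, \eqn{F(x^-,t) = 0}
#'     and Heaviside initial condition; the ISI survival function is
#'     \eqn{F(x_{\mathrm{th}}, t)}.}
#'   \item{`volterra1`}{the first-kind Volterra (Fortet) equation linking
#'     the threshold-free Gaussian transition density to \eqn{g}, solved by
#'     forward substitution (additive noise only).}
#'   \item{`volterra2`}{the second-kind Volterra equation with the
#'     singularity-removed kernel, solved by forward substitution
#'     (additive noise only); the most accurate backend on fine grids.}
#' }
#' Negative density values arising from finite differencing are clipped at
#' zero and the CDF is forced monotone into \eqn{[0,1]}.
#'
#' @param lif a [lif_params()] object.
#' @param current the total current \eqn{I_{\mathrm{total}}}: a function
#'   of time or a numeric vector on the grid times
#'   \eqn{0, dt, \ldots, t_{\max}}.
#' @param grid an [fpt_grid()].
#' @param method backend name.
#' @param return_field for the PDE backends, also return the full
#'   space-time field (membrane PDF or CDF) as attribute `"field"`,
#'   a (time x space) matrix.
#' @return An `fpt_solution` with `times`, `g`, `G`.
#' @export
solve_fpt <- function(lif, current, grid = fpt_grid(),
                      method = c("fp_pdf", "fp_cdf", "volterra1", "volterra2"),
                      return_field = FALSE) {
  stopifnot(inherits(lif, "lif_params"), inherits(grid, "fpt_grid"))
  method <- match.arg(method)
  n <- ceiling(grid$t_max / grid$dt)
  times <- (0:n) * grid$dt
  itot <- if (is.function(current)) current(times) else as.numeric(current)
  if (length(itot) != n + 1L)
    stop("current vector must have length t_max/dt + 1")
  res <- cpp_fpt_solve(itot, grid$dt, lif$gamma, lif$sigma, lif$x0, lif$x_th,
                       lif$x_lower, grid$dx, lif$noise_model == "feller",
                       method_code(method), return_field)
  out <- new_fpt_solution(times, res$g, res$G, method, itot)
  if (return_field && !is.null(res$field)) attr(out, "field") <- res$field
  out
}

#' @rdname solve_fpt
#' @export
solve_fp_pdf <- function(lif, current, grid = fpt_grid())
  solve_fpt(lif, current, grid, "fp_pdf")

#' @rdname solve_fpt
#' @export
solve_fp_cdf <- function(lif, current, grid = fpt_grid())
  solve_fpt(lif, current, grid, "fp_cdf")

#' @rdname solve_fpt
#' @export
solve_volterra1 <- function(lif, current, grid = fpt_grid())
  solve_fpt(lif, current, grid, "volterra1")

#' @rdname solve_fpt
#' @export
solve_volterra2 <- function(lif, current, grid = fpt_grid())
  solve_fpt(lif, current, grid, "volterra2")

#' ISI density given history and stimulus
#'
#' Builds the total-current trajectory for one interspike interval (time
#' origin at the last spike, post-spike current from the full history) and
#' dispatches to the selected backend. The density and CDF at the observed
#' ISI length are obtained by linear interpolation on the solver grid.
#'
#' @inheritParams solve_fpt
#' @param kernel a [response_kernel()] object.
#' @param stimulus the attended stimulus (probability-mixing component) or
#'   averaged stimulus (response-averaging).
#' @param history past spike times (trial clock); the ISI starts at the
#'   last of these, or at 0 for the first ISI of a trial.
#' @param isi observed ISI length (seconds); must not exceed
#'   `grid$t_max`.
#' @return A list with the interpolated `g` and `G` at `isi` and the full
#'   `fpt_solution`.
#' @export
isi_density <- function(lif, kernel, stimulus, history = numeric(0), isi,
                        grid = fpt_grid(),
                        method = c("fp_pdf", "fp_cdf", "volterra1", "volterra2")) {
  method <- match.arg(method)
  if (isi > grid$t_max)
    stop("observed ISI (", isi, " s) exceeds the solver horizon t_max = ",
         grid$t_max, " s; enlarge t_max")
  t0 <- if (length(history)) max(history) else 0
  n <- ceiling(grid$t_max / grid$dt)
  times <- t0 + (0:n) * grid$dt
  tab <- kernel_table(kernel, grid$dt)
  itot <- lif$gamma * lif$mu + eval_stimulus(stimulus, times) +
    post_spike_current(kernel, history, times, table = tab)
  sol <- solve_fpt(lif, itot, grid, method)
  pos <- isi / grid$dt
  i0 <- min(floor(pos), n - 1)
  frac <- pos - i0
  list(g = sol$g[i0 + 1] + frac * (sol$g[i0 + 2] - sol$g[i0 + 1]),
       G = sol$G[i0 + 1] + frac * (sol$G[i0 + 2] - sol$G[i0 + 1]),
       solution = sol)
}
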