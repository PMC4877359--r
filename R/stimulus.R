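#' Stimulus specifications
#'
#' Three stimulus families drive the LIF model. A *sinusoidal* stimulus is
#' \eqn{S(t) = s_1 \sin(s_2 t + s_3) + s_4} (constant for \eqn{s_1 = 0}).
#' A *piecewise-constant* stimulus takes value \eqn{s_i} on
#' \eqn{[t_i, t_{i+1})}. A *stochastic* stimulus is a stored realization of
#' the Ornstein-Uhlenbeck process \eqn{dS = (s_1 - S)\,dt + s_2\,dW},
#' evaluated by previous-point hold between its sample points (matching the
#' Euler scheme that generated it). Stimuli are closed under scaling and
#' addition ([stim_scale()], [stim_add()]), which is how perturbed
#' (\eqn{S + a\sin(10t)}) and rescaled (\eqn{bS}) stimuli, and
#' response-averaging combinations, are represented.
#'
#' @param s1,s2,s3,s4 sinusoidal parameters: amplitude, angular frequency
#'   (rad/s), phase, baseline.
#' @return An object of class `lif_stimulus`.
#' @name stimulus
NULL

new_stimulus <- function(terms, family, params = NULL) {
  structure(list(terms = terms, family = family, params = params),
            class = "lif_stimulus")
}

#' @rdname stimulus
#' @export
stimulus_sinusoidal <- function(s1, s2, s3, s4) {
  par <- as.numeric(c(s1, s2, s3, s4))
  if (anyNA(par)) stop("sinusoidal parameters must be finite")
  new_stimulus(list(list(type = 1L, coef = 1, par = par)),
               family = "sinusoidal", params = par)
}

#' @rdname stimulus
#' @param values segment values \eqn{s_1, \ldots, s_n}.
#' @param breakpoints strictly increasing segment boundaries
#'   \eqn{t_1 < \cdots < t_{n+1}}; the stimulus is defined on
#'   \eqn{[t_1, t_{n+1}]}.
#' @export
stimulus_piecewise <- function(values, breakpoints) {
  values <- as.numeric(values); breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != length(values) + 1L)
    stop("need one more breakpoint than segment values")
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  new_stimulus(list(list(type = 2L, coef = 1, par = values, brk = breakpoints)),
               family = "piecewise_constant",
               params = list(values = values, breakpoints = breakpoints))
}

#' @rdname stimulus
#' @param path sampled stimulus values on a uniform time grid.
#' @param t0 time of the first path sample.
#' @param dt path sampling step (seconds).
#' @param params generating OU parameters \eqn{(s_1, s_2)}, kept as metadata.
#' @export
stimulus_ou_path <- function(path, t0 = 0, dt, params = NULL) {
  path <- as.numeric(path)
  if (length(path) < 1L || dt <= 0) stop("need a nonempty path and dt > 0")
  new_stimulus(list(list(type = 3L, coef = 1, t0 = t0, dt = dt, path = path)),
               family = "ou_path",
               params = list(s = params, t0 = t0, dt = dt, n = length(path)))
}

#' @export
print.lif_stimulus <- function(x, ...) {
  cat("LIF stimulus (", x$family, "), ", length(x$terms), " term(s)\n", sep = "")
  invisible(x)
}

# terms in the list form consumed by the C++ evaluator
stim_terms <- function(spec) {
  stopifnot(inherits(spec, "lif_stimulus"))
  spec$terms
}

#' Evaluate a stimulus
#'
#' @param spec an `lif_stimulus` object.
#' @param t time(s) inside the stimulus domain. Outside the domain of a
#'   piecewise-constant stimulus or a stored path this is an error.
#' @return \eqn{S(t)}, vectorised over `t`.
#' @export
eval_stimulus <- function(spec, t) {
  cpp_stim_eval(stim_terms(spec), as.numeric(t))
}

#' Scale and combine stimuli
#'
#' `stim_scale(spec, b)` is the stimulus \eqn{bS(t)}; `stim_add(a, b)` is
#' the pointwise sum of two stimuli; `average_stimulus(stimuli, beta)` is
#' the response-averaging input \eqn{\sum_k \beta_k S_k(t)}.
#'
#' @param spec,a,b stimuli (`b` in `stim_scale` is a scalar).
#' @export
stim_scale <- function(spec, b) {
  stopifnot(inherits(spec, "lif_stimulus"), is.numeric(b), length(b) == 1L)
  terms <- lapply(spec$terms, function(tm) { tm$coef <- tm$coef * b; tm })
  new_stimulus(terms, family = "combination")
}

#' @rdname stim_scale
#' @export
stim_add <- function(a, b) {
  stopifnot(inherits(a, "lif_stimulus"), inherits(b, "lif_stimulus"))
  new_stimulus(c(a$terms, b$terms), family = "combination")
}

#' @rdname stim_scale
#' @param stimuli list of stimuli.
#' @param beta nonnegative weights, one per stimulus.
#' @export
average_stimulus <- function(stimuli, beta) {
  stopifnot(length(stimuli) == length(beta))
  terms <- list()
  for (k in seq_along(stimuli)) {
    sc <- stim_scale(stimuli[[k]], beta[k])
    terms <- c(terms, sc$terms)
  }
  new_stimulus(terms, family = "combination")
}

#' Serialize stimuli
#'
#' Primitive stimuli round-trip through a small named list (and hence JSON
#' or YAML); OU paths additionally export to a two-column CSV
#' `(time, value)`.
#'
#' @param spec an `lif_stimulus` object (primitive, not a combination).
#' @export
stimulus_to_list <- function(spec) {
  stopifnot(inherits(spec, "lif_stimulus"))
  switch(spec$family,
    sinusoidal = list(family = "sinusoidal", params = spec$params),
    piecewise_constant = list(family = "piecewise_constant",
                              values = spec$params$values,
                              breakpoints = spec$params$breakpoints),
    ou_path = list(family = "ou_path", t0 = spec$terms[[1]]$t0,
                   dt = spec$terms[[1]]$dt, path = spec$terms[[1]]$path,
                   s = spec$params$s),
    stop("only primitive stimuli serialize; combinations are derived objects"))
}

#' @rdname stimulus_to_list
#' @param x a list as produced by [stimulus_to_list()] (e.g. parsed from
#'   JSON or YAML).
#' @export
stimulus_from_list <- function(x) {
  switch(x$family,
    sinusoidal = stimulus_sinusoidal(x$params[1], x$params[2], x$params[3], x$params[4]),
    piecewise_constant = stimulus_piecewise(x$values, x$breakpoints),
    ou_path = stimulus_ou_path(x$path, t0 = x$t0, dt = x$dt, params = x$s),
    stop("unknown stimulus family: ", x$family))
}

#' @rdname stimulus_to_list
#' @param file path of the JSON/YAML/CSV file.
#' @export
stimulus_to_json <- function(spec, file) {
  jsonlite::write_json(stimulus_to_list(spec), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname stimulus_to_list
#' @export
stimulus_from_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  stimulus_from_list(x)
}

#' @rdname stimulus_to_list
#' @export
stimulus_to_yaml <- function(spec, file) {
  yaml::write_yaml(stimulus_to_list(spec), file)
  invisible(file)
}

#' @rdname stimulus_to_list
#' @export
stimulus_from_yaml <- function(file) {
  stimulus_from_list(yaml::read_yaml(file))
}

#' @rdname stimulus_to_list
#' @export
ou_path_to_csv <- function(spec, file) {
  stopifnot(spec$family == "ou_path")
  tm <- spec$terms[[1]]
  df <- data.frame(time = tm$t0 + (seq_along(tm$path) - 1) * tm$dt,
                   value = tm$path)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname stimulus_to_list
#' @param params generating OU parameters attached as metadata on read.
#' @export
ou_path_from_csv <- function(file, params = NULL) {
  df <- read.csv(file)
  dt <- if (nrow(df) > 1) df$time[2] - df$time[1] else 1
  stimulus_ou_path(df$value, t0 = df$time[1], dt = dt, params = params)
}
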