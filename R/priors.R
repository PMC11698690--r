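#' Empirical priors for the dual-system model parameters
#'
#' The default prior set used for maximum a posteriori fitting: a
#' Beta(2, 2) prior for every unit-interval parameter (learning rate
#' `alpha`, eligibility decay `lam`, mixing weights `w_low` and `w_high`),
#' a Gamma(3, 0.2) prior for the inverse temperature `beta`, and standard
#' normal priors for the stickiness parameters `pi` and `rho`.
#'
#' The Gamma hyperparameters are read as shape and scale (mode
#' `(3 - 1) * 0.2 = 0.4`); set `gamma_parameterisation = "rate"` to read
#' the second hyperparameter as a rate instead. `rho` can optionally be
#' bounded to the unit interval with a Beta(2, 2) prior via
#' `rho_prior = "beta"` (the stickiness reading, an unbounded N(0, 1), is
#' the default).
#'
#' @param gamma_parameterisation `"scale"` (default) or `"rate"`.
#' @param rho_prior `"normal"` (default) or `"beta"`.
#' @return A named list of prior descriptors, class `"prior_spec"`. Each
#'   element is a list with a `family` field (`"beta"`, `"gamma"`,
#'   `"normal"` or `"flat"`) and its hyperparameters.
#' @export
#' @examples
#' pr <- hybrid_priors()
#' prior_modes(pr)
hybrid_priors <- function(gamma_parameterisation = c("scale", "rate"),
                          rho_prior = c("normal", "beta")) {
  gamma_parameterisation <- match.arg(gamma_parameterisation)
  rho_prior <- match.arg(rho_prior)
  beta22 <- list(family = "beta", a = 2, b = 2)
  g <- if (gamma_parameterisation == "scale") {
    list(family = "gamma", shape = 3, scale = 0.2)
  } else {
    list(family = "gamma", shape = 3, rate = 0.2)
  }
  rho <- if (rho_prior == "normal") {
    list(family = "normal", mean = 0, sd = 1)
  } else {
    beta22
  }
  structure(
    list(alpha = beta22, beta = g, lam = beta22, w_low = beta22,
         w_high = beta22, pi = list(family = "normal", mean = 0, sd = 1),
         rho = rho),
    class = "prior_spec"
  )
}

#' Flat priors over the parameter supports
#'
#' Useful for maximum-likelihood fitting through the same interface.
#' @param params Character vector of parameter names.
#' @return A `prior_spec` of flat priors.
#' @export
flat_priors <- function(params = names(hybrid_priors())) {
  structure(
    stats::setNames(lapply(params, function(p) list(family = "flat")),
                    params),
    class = "prior_spec"
  )
}

prior_log_density_1 <- function(spec, x) {
  switch(spec$family,
    beta = stats::dbeta(x, spec$a, spec$b, log = TRUE),
    gamma = if (!is.null(spec$scale)) {
      stats::dgamma(x, shape = spec$shape, scale = spec$scale, log = TRUE)
    } else {
      stats::dgamma(x, shape = spec$shape, rate = spec$rate, log = TRUE)
    },
    normal = stats::dnorm(x, spec$mean, spec$sd, log = TRUE),
    flat = 0,
    stop("unknown prior family: ", spec$family, call. = FALSE)
  )
}

prior_mode_1 <- function(spec) {
  switch(spec$family,
    beta = if (spec$a > 1 && spec$b > 1) {
      (spec$a - 1) / (spec$a + spec$b - 2)
    } else {
      NA_real_
    },
    gamma = {
      sc <- if (!is.null(spec$scale)) spec$scale else 1 / spec$rate
      if (spec$shape >= 1) (spec$shape - 1) * sc else 0
    },
    normal = spec$mean,
    flat = NA_real_
  )
}

prior_sample_1 <- function(spec, n = 1) {
  switch(spec$family,
    beta = stats::rbeta(n, spec$a, spec$b),
    gamma = if (!is.null(spec$scale)) {
      stats::rgamma(n, shape = spec$shape, scale = spec$scale)
    } else {
      stats::rgamma(n, shape = spec$shape, rate = spec$rate)
    },
    normal = stats::rnorm(n, spec$mean, spec$sd),
    flat = stats::runif(n)  # support taken as [0, 1] for sampling only
  )
}

prior_support_1 <- function(spec) {
  switch(spec$family,
    beta = c(0, 1),
    gamma = c(0, Inf),
    normal = c(-Inf, Inf),
    flat = c(-Inf, Inf)
  )
}

#' Evaluate, summarise and sample a prior specification
#'
#' `log_prior_density()` sums the log prior densities of a named parameter
#' vector; values where any density is zero return `-Inf`.
#' `prior_modes()` returns the analytic mode of each prior.
#' `sample_from_priors()` draws one value per parameter.
#'
#' @param priors A `prior_spec` (see [hybrid_priors()]).
#' @param params Named numeric vector; names must be a subset of
#'   `names(priors)`.
#' @return A scalar log density, a named vector of modes, or a named
#'   vector of draws.
#' @export
log_prior_density <- function(priors, params) {
  stopifnot(all(names(params) %in% names(priors)))
  sum(vapply(names(params), function(p) {
    prior_log_density_1(priors[[p]], params[[p]])
  }, numeric(1)))
}

#' @rdname log_prior_density
#' @export
prior_modes <- function(priors) {
  vapply(priors, prior_mode_1, numeric(1))
}

#' @rdname log_prior_density
#' @export
sample_from_priors <- function(priors) {
  vapply(priors, prior_sample_1, numeric(1))
}

#' Read and write prior specifications as JSON
#'
#' @param priors A `prior_spec`.
#' @param path File path.
#' @export
write_priors <- function(priors, path) {
  jsonlite::write_json(unclass(priors), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(lapply(x, function(p) {
    p$family <- as.character(p$family)
    p
  }), class = "prior_spec")
}
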