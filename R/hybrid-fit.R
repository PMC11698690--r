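#' Maximum a posteriori fit of the dual-system model
#'
#' Maximises [log_posterior()] for one subject's session by bounded
#' quasi-Newton optimisation (`optim(method = "L-BFGS-B")`) restarted from
#' `n_restarts` initial points drawn from the priors, returning the restart
#' with the highest log posterior (ties broken by first occurrence). Because
#' the Beta(2, 2) priors vanish at the support boundaries, the box
#' constraints are pulled a hair inside the support so the objective stays
#' finite everywhere the optimiser can step.
#'
#' @param session Single-subject session tibble.
#' @param priors A `prior_spec` (default [hybrid_priors()]).
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Integer seed; the same seed reproduces the fit exactly.
#' @param config A [task_config()].
#' @param fixed Optional named list of parameters to clamp at given values
#'   (these are excluded from the optimisation).
#' @param beta_max Upper box bound for the inverse temperature (the
#'   Gamma(3, 0.2) prior makes values beyond this astronomically
#'   improbable).
#' @param stickiness_bound Symmetric box bound for `pi` and `rho`.
#' @return A `stakerl_fit` object: a list with `estimates` (named vector),
#'   `log_likelihood`, `log_posterior`, `n_restarts_run`, `best_restart`,
#'   `converged`, `seed` and `model`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] to get tibbles.
#' @export
fit_hybrid_map <- function(session, priors = hybrid_priors(),
                           n_restarts = 100, seed = 1,
                           config = task_config(), fixed = NULL,
                           beta_max = 30, stickiness_bound = 10) {
  bounds <- hybrid_bounds(names(hybrid_param_template()), priors,
                          beta_max, stickiness_bound)
  fit_map_generic(
    param_names = names(hybrid_param_template()),
    bounds = bounds, session = session, priors = priors,
    n_restarts = n_restarts, seed = seed, config = config, fixed = fixed,
    model = "hybrid"
  )
}

#' @rdname fit_hybrid_map
#' @export
fit_exhaustive_map <- function(session, priors = hybrid_priors(),
                               n_restarts = 100, seed = 1,
                               config = task_config(), fixed = NULL,
                               beta_max = 30, stickiness_bound = 10) {
  nms <- exhaustive_param_names()
  bounds <- hybrid_bounds(nms, priors, beta_max, stickiness_bound)
  fit_map_generic(
    param_names = nms, bounds = bounds, session = session,
    priors = priors, n_restarts = n_restarts, seed = seed,
    config = config, fixed = fixed, model = "exhaustive"
  )
}

hybrid_param_template <- function() {
  c(alpha = 0.5, beta = 0.4, lam = 0.5, w_low = 0.5, w_high = 0.5,
    pi = 0, rho = 0)
}

exhaustive_param_names <- function() {
  base <- c("alpha", "beta", "lam", "w", "pi", "rho")
  as.vector(t(outer(base, c("_low", "_high"), paste0)))
}

prior_name_for <- function(nm, priors) {
  if (nm %in% names(priors)) return(nm)
  base <- sub("_(low|high)$", "", nm)
  if (base %in% names(priors)) return(base)
  stop("no prior found for parameter ", nm, call. = FALSE)
}

# box bounds: prior support pulled strictly inside where the density
# vanishes at the edge
hybrid_bounds <- function(param_names, priors, beta_max, stickiness_bound) {
  eps <- 1e-6
  lower <- upper <- stats::setNames(numeric(length(param_names)),
                                    param_names)
  for (nm in param_names) {
    sp <- priors[[prior_name_for(nm, priors)]]
    sup <- prior_support_1(sp)
    lo <- sup[1]; hi <- sup[2]
    if (identical(sp$family, "beta")) { lo <- eps; hi <- 1 - eps }
    if (identical(sp$family, "gamma")) { lo <- eps; hi <- beta_max }
    if (identical(sp$family, "normal")) {
      lo <- -stickiness_bound; hi <- stickiness_bound
    }
    if (identical(sp$family, "flat")) {
      base <- sub("_(low|high)$", "", nm)
      if (base %in% c("alpha", "lam", "w")) { lo <- 0; hi <- 1 }
      if (base == "beta") { lo <- 0; hi <- beta_max }
      if (base %in% c("pi", "rho")) {
        lo <- -stickiness_bound; hi <- stickiness_bound
      }
    }
    lower[nm] <- lo; upper[nm] <- hi
  }
  list(lower = lower, upper = upper)
}

fit_map_generic <- function(param_names, bounds, session, priors,
                            n_restarts, seed, config, fixed, model) {
  stopifnot(n_restarts >= 1)
  fixed <- fixed %||% list()
  bad_fixed <- setdiff(names(fixed), param_names)
  if (length(bad_fixed)) {
    stop("unknown fixed parameter(s): ", paste(bad_fixed, collapse = ", "),
         call. = FALSE)
  }
  free <- setdiff(param_names, names(fixed))
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]

  # the objective is evaluated tens of thousands of times per subject, so
  # the session encoding, transition table and per-parameter prior
  # density functions are all prepared once up front
  enc <- if (nrow(session) > 0) encode_session(session, config) else NULL
  tp <- as.numeric(aperm(transition_prob_array(config), c(3, 2, 1)))
  prior_fns <- lapply(param_names, function(nm) {
    sp <- priors[[prior_name_for(nm, priors)]]
    switch(sp$family,
      beta = local({a <- sp$a; b <- sp$b
        function(x) stats::dbeta(x, a, b, log = TRUE)}),
      gamma = local({sh <- sp$shape
        sc <- if (!is.null(sp$scale)) sp$scale else 1 / sp$rate
        function(x) stats::dgamma(x, shape = sh, scale = sc, log = TRUE)}),
      normal = local({m <- sp$mean; s <- sp$sd
        function(x) stats::dnorm(x, m, s, log = TRUE)}),
      flat = function(x) 0)
  })
  if (identical(model, "hybrid")) {
    base6 <- c("alpha", "beta", "lam", "w_low", "pi", "rho")
    low_idx <- match(base6, param_names)
    high_idx <- match(c("alpha", "beta", "lam", "w_high", "pi", "rho"),
                      param_names)
  } else {
    base6 <- c("alpha", "beta", "lam", "w", "pi", "rho")
    low_idx <- match(paste0(base6, "_low"), param_names)
    high_idx <- match(paste0(base6, "_high"), param_names)
  }
  free_idx <- match(free, param_names)
  full <- stats::setNames(numeric(length(param_names)), param_names)
  for (nm in names(fixed)) full[nm] <- fixed[[nm]]

  assemble <- function(theta) {
    full[free_idx] <- theta
    full
  }
  negobj <- function(theta) {
    full[free_idx] <- theta
    lp <- 0
    for (j in seq_along(param_names)) lp <- lp + prior_fns[[j]](full[[j]])
    if (!is.finite(lp)) return(1e10)
    if (!is.null(enc)) {
      lp <- lp + hybrid_loglik_cpp(enc$stake, enc$state, enc$action,
                                   enc$planet, enc$keyidx, enc$reward,
                                   full[low_idx], full[high_idx], tp)
    }
    -lp
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      th <- vapply(free, function(nm) {
        prior_sample_1(priors[[prior_name_for(nm, priors)]])
      }, numeric(1))
      pmin(pmax(th, lower + 1e-6), upper - 1e-6)
    })
  })

  best <- NULL
  best_val <- -Inf
  best_idx <- NA_integer_
  n_ok <- 0L
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], negobj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (-res$value > best_val) {
      best_val <- -res$value
      best <- res
      best_idx <- i
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restarts failed to evaluate the posterior ",
         "(model ", model, ", ", nrow(session), " trials).", call. = FALSE)
  }
  est <- assemble(best$par)
  ll <- session_log_likelihood(est, session, config)
  structure(
    list(
      estimates = est,
      log_likelihood = ll,
      log_posterior = best_val,
      n_restarts_run = n_ok,
      best_restart = best_idx,
      converged = best$convergence == 0,
      seed = seed,
      model = model
    ),
    class = "stakerl_fit"
  )
}

#' @export
print.stakerl_fit <- function(x, ...) {
  cat("<stakerl_fit: ", x$model, " model>\n", sep = "")
  print(round(x$estimates, 4))
  cat("log-likelihood: ", format(x$log_likelihood, digits = 6),
      "   log-posterior: ", format(x$log_posterior, digits = 6), "\n",
      sep = "")
  cat("best restart ", x$best_restart, " of ", x$n_restarts_run,
      if (x$converged) " (converged)" else " (not converged)", "\n",
      sep = "")
  invisible(x)
}
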