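#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model object
#'
#' @param x A `stakerl_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.stakerl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = as.numeric(x$estimates))
}

#' One-row fit summary
#'
#' @param x A `stakerl_fit`.
#' @param ... Unused.
#' @return Tibble with the likelihood, posterior and restart provenance.
#' @export
glance.stakerl_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 log_likelihood = x$log_likelihood,
                 log_posterior = x$log_posterior,
                 n_restarts = x$n_restarts_run,
                 best_restart = x$best_restart,
                 converged = x$converged,
                 seed = x$seed)
}

#' @export
tidy.stakerl_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.split_half_result <- function(x, ...) {
  x$correlations
}
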