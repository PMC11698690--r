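#' Genetic-algorithm configuration for the utility-model fit
#'
#' Hyperparameters of the real-valued genetic algorithm: a population of
#' candidate parameter vectors is evolved by tournament selection, uniform
#' crossover and Gaussian mutation under elitism, maximising the session
#' log-likelihood as the fitness.
#'
#' @param pop_size Population size (default 1000).
#' @param n_generations Number of generations (default 100).
#' @param crossover_rate Probability that each offspring gene is taken
#'   from the second parent (uniform crossover; default 0.5).
#' @param mutation_sd Per-parameter mutation standard deviations; default
#'   10% of each bound width. Either a single fraction-of-width number or
#'   a named vector on the parameter scale.
#' @param mutation_rate Per-gene probability of mutation (default 0.2).
#' @param elite_count Number of best individuals copied unchanged into the
#'   next generation (default 5).
#' @param tournament_size Tournament size for parent selection (default 3).
#' @param bounds Named list of `c(min, max)` per parameter; defaults to
#'   `mu` in \[-2, 2\], `beta_u` in \[0, 5\], `eta` in \[0, 1\],
#'   `gamma_disc` in \[0, 1\], `delta_limit` in \[0.1, 10\].
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(pop_size = 1000, n_generations = 100,
                      crossover_rate = 0.5, mutation_sd = 0.1,
                      mutation_rate = 0.2, elite_count = 5,
                      tournament_size = 3,
                      bounds = utility_default_bounds()) {
  cfg <- structure(
    list(pop_size = as.integer(pop_size),
         n_generations = as.integer(n_generations),
         crossover_rate = crossover_rate, mutation_sd = mutation_sd,
         mutation_rate = mutation_rate,
         elite_count = as.integer(elite_count),
         tournament_size = as.integer(tournament_size), bounds = bounds),
    class = "ga_config"
  )
  if (cfg$pop_size < 1 || cfg$n_generations < 1) {
    stop("`pop_size` and `n_generations` must be at least 1.",
         call. = FALSE)
  }
  if (cfg$elite_count < 1 || cfg$elite_count > cfg$pop_size) {
    stop("need `pop_size >= elite_count >= 1`.", call. = FALSE)
  }
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1 ||
      cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    stop("rates must lie in [0, 1].", call. = FALSE)
  }
  for (nm in names(bounds)) {
    if (bounds[[nm]][1] >= bounds[[nm]][2]) {
      stop("degenerate bounds for `", nm, "` (min >= max).", call. = FALSE)
    }
  }
  cfg
}

#' @rdname ga_config
#' @export
utility_default_bounds <- function() {
  list(mu = c(-2, 2), beta_u = c(0, 5), eta = c(0, 1),
       gamma_disc = c(0, 1), delta_limit = c(0.1, 10))
}

#' Read and write GA configurations as JSON
#' @param ga A [ga_config()].
#' @param path File path.
#' @export
write_ga_config <- function(ga, path) {
  jsonlite::write_json(unclass(ga), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ga_config
#' @export
read_ga_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bounds <- lapply(x$bounds, as.numeric)
  do.call(ga_config, x)
}

#' Genetic-algorithm fit of the utility model
#'
#' Maximises [utility_log_likelihood()] over the five utility parameters
#' with a real-valued genetic algorithm: tournament selection, uniform
#' crossover, Gaussian mutation clipped to the bounds, and elitism. The
#' returned individual is the best ever evaluated (which elitism also
#' keeps in the population, so the per-generation best fitness is
#' non-decreasing). Fully deterministic given `seed`.
#'
#' @param session Single-subject session tibble.
#' @param stake_filter `"all"`, `"low"` or `"high"` — which trials enter
#'   the fitness sum (learning always runs over all trials).
#' @param ga A [ga_config()].
#' @param seed Integer seed.
#' @param config A [task_config()].
#' @param reward_signal Passed to [utility_log_likelihood()].
#' @return A `stakerl_fit` object; `$trace` holds the best fitness per
#'   generation.
#' @export
fit_utility_ga <- function(session, stake_filter = c("all", "low", "high"),
                           ga = ga_config(), seed = 1,
                           config = task_config(),
                           reward_signal = c("delivered", "base")) {
  stake_filter <- match.arg(stake_filter)
  reward_signal <- match.arg(reward_signal)
  nms <- names(ga$bounds)
  d <- length(nms)
  lo <- vapply(ga$bounds, `[`, numeric(1), 1)
  hi <- vapply(ga$bounds, `[`, numeric(1), 2)
  width <- hi - lo
  msd <- if (length(ga$mutation_sd) == 1 && is.null(names(ga$mutation_sd))) {
    ga$mutation_sd * width
  } else {
    as.numeric(ga$mutation_sd[nms])
  }

  enc <- list(
    stake = ifelse(session$stake == "high", 2L, 1L),
    state = as.integer(session$start_state),
    action = as_action_index(session$action),
    planet = match(session$planet, planet_labels()),
    reward = if (reward_signal == "delivered") {
      as.numeric(session$delivered_reward)
    } else {
      as.numeric(session$base_reward)
    }
  )
  filt <- switch(stake_filter, all = 0L, low = 1L, high = 2L)
  fitness <- function(th) {
    utility_loglik_cpp(enc$stake, enc$state, enc$action, enc$planet,
                       enc$reward, th[1], th[2], th[3], th[4], th[5], filt)
  }

  withr::with_seed(seed, {
    pop <- matrix(stats::runif(ga$pop_size * d, rep(lo, each = ga$pop_size),
                               rep(hi, each = ga$pop_size)),
                  nrow = ga$pop_size, dimnames = list(NULL, nms))
    fit <- apply(pop, 1, fitness)
    best_ever <- pop[which.max(fit), ]
    best_ever_fit <- max(fit)
    trace <- numeric(ga$n_generations)

    for (g in seq_len(ga$n_generations)) {
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(ga$elite_count)], , drop = FALSE]
      n_children <- ga$pop_size - ga$elite_count
      children <- matrix(0, n_children, d, dimnames = list(NULL, nms))
      for (k in seq_len(n_children)) {
        p1 <- tournament_pick(fit, ga$tournament_size)
        p2 <- tournament_pick(fit, ga$tournament_size)
        child <- pop[p1, ]
        take2 <- stats::runif(d) < ga$crossover_rate
        child[take2] <- pop[p2, take2]
        mut <- stats::runif(d) < ga$mutation_rate
        if (any(mut)) {
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, msd[mut])
          child <- pmin(pmax(child, lo), hi)
        }
        children[k, ] <- child
      }
      pop <- rbind(elites, children)
      fit <- apply(pop, 1, fitness)
      if (max(fit) > best_ever_fit) {
        best_ever_fit <- max(fit)
        best_ever <- pop[which.max(fit), ]
      }
      trace[g] <- max(fit)
    }

    structure(
      list(
        estimates = stats::setNames(as.numeric(best_ever), nms),
        log_likelihood = best_ever_fit,
        log_posterior = best_ever_fit,
        n_restarts_run = ga$n_generations,
        best_restart = NA_integer_,
        converged = TRUE,
        seed = seed,
        model = paste0("utility_", stake_filter),
        trace = trace
      ),
      class = "stakerl_fit"
    )
  })
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), k, replace = TRUE)
  cand[which.max(fit[cand])]
}
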