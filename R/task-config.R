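#' Configuration of the stakes-modulated two-step task
#'
#' Builds the configuration object that every simulation and fitting
#' function consumes. The task has two first-stage states ("spaceship"
#' screens), each offering the same choice between travelling to the red or
#' the purple planet, where a drifting number of points is paid out. A cue
#' at the start of each trial announces the stake: on high-stakes trials the
#' points earned at the planet are multiplied by `stake_multiplier`, on
#' low-stakes trials they are paid out unchanged.
#'
#' @param n_trials Number of trials per session (default 200).
#' @param p_high_stake Probability that a trial is cued as high stakes
#'   (default 0.5).
#' @param stake_multiplier Multiplier applied to second-stage points on
#'   high-stakes trials (default 5).
#' @param payoff_min,payoff_max Bounds of the planet payoffs in points
#'   (defaults 0 and 9).
#' @param drift_sd Standard deviation, in points per trial, of the Gaussian
#'   random-walk step of each planet's payoff (default 2).
#' @param transition_map 2x2 integer matrix; `transition_map[s, a]` is the
#'   planet (1 = red, 2 = purple) reached by taking action `a` in
#'   first-stage state `s`. Each row must cover both planets. The default
#'   sends action A to red and action B to purple from both states, so the
#'   two first-stage states offer an identical choice between planets.
#' @param p_start_state Probability that a trial starts in first-stage
#'   state 1 (default 0.5).
#' @param deterministic_transitions Logical; the task as deployed uses
#'   deterministic spaceship-to-planet transitions. Set to `FALSE` together
#'   with `transition_probs` for a stochastic variant.
#' @param transition_probs Optional 2x2x2 array of
#'   `P(planet | state, action)`; ignored unless
#'   `deterministic_transitions = FALSE`.
#' @param integer_payoffs Logical; round walk payoffs to whole points
#'   (default `TRUE`, the on-screen convention).
#' @param randomize_keys Logical; if `TRUE` the left/right placement of the
#'   two spaceships is shuffled per trial, otherwise action A always sits
#'   on the left key (default `FALSE`).
#' @param learning_reward Which reward signal a learning agent receives:
#'   `"base"` (the unmultiplied points; stake effects then enter only
#'   through the stake-conditional parameters) or `"delivered"` (the points
#'   after the stake multiplier).
#'
#' @return A list of class `"task_config"`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
task_config <- function(n_trials = 200,
                        p_high_stake = 0.5,
                        stake_multiplier = 5,
                        payoff_min = 0,
                        payoff_max = 9,
                        drift_sd = 2,
                        transition_map = default_transition_map(),
                        p_start_state = 0.5,
                        deterministic_transitions = TRUE,
                        transition_probs = NULL,
                        integer_payoffs = TRUE,
                        randomize_keys = FALSE,
                        learning_reward = c("base", "delivered")) {
  learning_reward <- match.arg(learning_reward)
  cfg <- structure(
    list(
      n_trials = as.integer(n_trials),
      p_high_stake = p_high_stake,
      stake_multiplier = stake_multiplier,
      payoff_min = payoff_min,
      payoff_max = payoff_max,
      drift_sd = drift_sd,
      transition_map = transition_map,
      p_start_state = p_start_state,
      deterministic_transitions = isTRUE(deterministic_transitions),
      transition_probs = transition_probs,
      integer_payoffs = isTRUE(integer_payoffs),
      randomize_keys = isTRUE(randomize_keys),
      learning_reward = learning_reward
    ),
    class = "task_config"
  )
  validate_task_config(cfg)
  cfg
}

#' @rdname task_config
#' @export
default_transition_map <- function() {
  m <- matrix(c(1L, 1L, 2L, 2L), nrow = 2,
              dimnames = list(state = c("1", "2"), action = c("A", "B")))
  m
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (is.na(cfg$n_trials) || cfg$n_trials < 0) {
    stop("`n_trials` must be a non-negative integer.", call. = FALSE)
  }
  if (cfg$p_high_stake < 0 || cfg$p_high_stake > 1) {
    stop("`p_high_stake` must lie in [0, 1].", call. = FALSE)
  }
  if (cfg$p_start_state < 0 || cfg$p_start_state > 1) {
    stop("`p_start_state` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(cfg$stake_multiplier) || cfg$stake_multiplier < 1) {
    stop("`stake_multiplier` must be a positive number.", call. = FALSE)
  }
  if (cfg$payoff_min >= cfg$payoff_max) {
    stop("`payoff_min` must be strictly below `payoff_max`.", call. = FALSE)
  }
  if (cfg$drift_sd < 0) {
    stop("`drift_sd` must be non-negative.", call. = FALSE)
  }
  tm <- cfg$transition_map
  if (!is.matrix(tm) || !identical(dim(tm), c(2L, 2L)) ||
      !all(tm %in% c(1L, 2L))) {
    stop("`transition_map` must be a 2x2 matrix of planet indices 1/2.",
         call. = FALSE)
  }
  if (any(apply(tm, 1, function(r) length(unique(r))) != 2)) {
    stop("Each first-stage state must map its two actions onto the two ",
         "distinct planets.", call. = FALSE)
  }
  if (!cfg$deterministic_transitions) {
    tp <- cfg$transition_probs
    if (is.null(tp) || !identical(dim(tp), c(2L, 2L, 2L)) ||
        any(tp < 0) || any(abs(apply(tp, c(1, 2), sum) - 1) > 1e-8)) {
      stop("Stochastic transitions need `transition_probs`, a 2x2x2 array ",
           "of P(planet | state, action) with rows summing to 1.",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# P(planet | state, action) as a 2x2x2 array regardless of representation
transition_prob_array <- function(cfg) {
  if (cfg$deterministic_transitions || is.null(cfg$transition_probs)) {
    tp <- array(0, dim = c(2, 2, 2))
    for (s in 1:2) for (a in 1:2) tp[s, a, cfg$transition_map[s, a]] <- 1
    tp
  } else {
    cfg$transition_probs
  }
}

#' Read and write task configurations as JSON
#'
#' The on-disk form is a flat JSON object with the `task_config()` argument
#' names as keys. Unknown keys are rejected so that typos in hand-edited
#' configuration files fail loudly.
#'
#' @param cfg A `task_config` object.
#' @param path File path.
#' @return `read_task_config()` returns a `task_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
write_task_config <- function(cfg, path) {
  validate_task_config(cfg)
  x <- unclass(cfg)
  x$transition_map <- as.vector(cfg$transition_map)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(task_config))
  extra <- setdiff(names(x), c(known, "deterministic_transitions"))
  if (length(extra)) {
    stop("Unknown task configuration key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$transition_map)) {
    x$transition_map <- matrix(as.integer(x$transition_map), nrow = 2,
                               dimnames = list(state = c("1", "2"),
                                               action = c("A", "B")))
  }
  do.call(task_config, x)
}
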