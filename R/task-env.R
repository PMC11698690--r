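#' Drifting planet payoffs
#'
#' Each planet pays a number of points that evolves across trials as a
#' Gaussian random walk with reflecting boundaries at
#' `[payoff_min, payoff_max]`. The two planets drift independently, so
#' their relative worth keeps changing and agents must keep learning.
#' Initial payoffs are drawn uniformly within the bounds.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the same walks.
#' @return A tibble with columns `trial` (0-based), `red`, `purple`.
#' @export
#' @examples
#' walks <- generate_reward_walks(task_config(), seed = 1)
#' head(walks)
generate_reward_walks <- function(config = task_config(), seed) {
  validate_task_config(config)
  n <- config$n_trials
  lo <- config$payoff_min
  hi <- config$payoff_max
  out <- withr::with_seed(seed, {
    lapply(1:2, function(p) {
      x <- numeric(n)
      if (n == 0) return(x)
      cur <- stats::runif(1, lo, hi)
      steps <- stats::rnorm(n, 0, config$drift_sd)
      for (t in seq_len(n)) {
        if (t > 1) cur <- reflect_into(cur + steps[t], lo, hi)
        x[t] <- cur
      }
      x
    })
  })
  red <- out[[1]]
  purple <- out[[2]]
  if (config$integer_payoffs) {
    red <- round(red)
    purple <- round(purple)
  }
  tibble::tibble(trial = seq_len(n) - 1L, red = red, purple = purple)
}

# reflect a value into [lo, hi] (repeatedly, for steps wider than the range)
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- lo + (lo - x)
    if (x > hi) x <- hi - (x - hi)
  }
  x
}

#' Sample the per-trial stake cues
#'
#' Each trial is independently cued as high stakes with probability
#' `p_high_stake` (a fair coin in the deployed task, so neither stake
#' condition is systematically more frequent).
#'
#' @inheritParams generate_reward_walks
#' @return Character vector of length `n_trials` with values
#'   `"low"`/`"high"`.
#' @export
sample_stake_sequence <- function(config = task_config(), seed) {
  validate_task_config(config)
  withr::with_seed(seed, {
    ifelse(stats::runif(config$n_trials) < config$p_high_stake,
           "high", "low")
  })
}

#' Spaceship-to-planet transition
#'
#' Looks up which planet a first-stage action leads to. Transitions in this
#' task are deterministic: each spaceship always flies to one fixed planet,
#' and both first-stage states offer the same choice between the two
#' planets.
#'
#' @param start_state First-stage state, 1 or 2.
#' @param action `"A"` or `"B"` (or 1/2).
#' @inheritParams generate_reward_walks
#' @return `"red"` or `"purple"`.
#' @export
#' @examples
#' transition(1, "A")
transition <- function(start_state, action, config = task_config()) {
  s <- as_state_index(start_state)
  a <- as_action_index(action)
  planet_labels()[config$transition_map[cbind(s, a)]]
}

#' Apply the stake multiplier to a planet payoff
#'
#' @param base_reward Points shown on the planet.
#' @param stake `"low"` or `"high"`.
#' @inheritParams generate_reward_walks
#' @return Delivered points: `base_reward * stake_multiplier` on
#'   high-stakes trials, `base_reward` otherwise.
#' @export
#' @examples
#' deliver_reward(3, "high")  # 15 under the default x5 multiplier
deliver_reward <- function(base_reward, stake, config = task_config()) {
  stopifnot(all(stake %in% c("low", "high")))
  ifelse(stake == "high", base_reward * config$stake_multiplier, base_reward)
}

planet_labels <- function() c("red", "purple")
action_labels <- function() c("A", "B")
key_labels <- function() c("left", "right")

as_state_index <- function(x) {
  s <- as.integer(x)
  if (any(is.na(s) | !(s %in% 1:2))) {
    stop("first-stage state must be 1 or 2", call. = FALSE)
  }
  s
}

as_action_index <- function(x) {
  if (is.character(x) || is.factor(x)) {
    a <- match(as.character(x), action_labels())
  } else {
    a <- as.integer(x)
  }
  if (any(is.na(a) | !(a %in% 1:2))) {
    stop("action must be \"A\" or \"B\"", call. = FALSE)
  }
  a
}

# left/right key layout for a trial: key_of[a] in 1:2 (1=left)
trial_key_layout <- function(randomize, u = NULL) {
  if (randomize && !is.null(u) && u < 0.5) c(2L, 1L) else c(1L, 2L)
}

#' Play a choice policy through the task
#'
#' Runs an arbitrary first-stage choice rule through the generative
#' environment: stake cues, start states and planet payoffs are sampled
#' from `config`, the policy is shown the trial context (including the
#' stake cue, which is displayed before the choice) and returns the action,
#' and the trial outcome is recorded.
#'
#' @inheritParams generate_reward_walks
#' @param policy Function of `(trial_context)` returning `"A"` or `"B"`.
#'   The context is a list with elements `trial` (0-based index), `stake`,
#'   `start_state`, `key_of` (named vector mapping action to `"left"` or
#'   `"right"`), and `runif` (a function drawing uniforms from the
#'   session's random stream, for stochastic policies). A learning agent is
#'   passed as a list with elements `choose` (as above) and `observe`,
#'   called with the completed trial record so the agent can update its
#'   values.
#' @param subject_id,group Session labels stored on every trial row.
#' @return A session tibble, one row per trial, with columns `subject_id`,
#'   `group`, `trial`, `stake`, `start_state`, `action`, `response_key`,
#'   `planet`, `base_reward`, `delivered_reward`.
#' @export
#' @examples
#' uniform <- function(ctx) if (ctx$runif() < 0.5) "A" else "B"
#' s <- build_session(task_config(n_trials = 5), uniform, seed = 1)
#' s
build_session <- function(config = task_config(), policy, seed,
                          subject_id = "sim", group = "unknown") {
  validate_task_config(config)
  n <- config$n_trials
  walks <- generate_reward_walks(config, seed = seed + 1L)
  stakes <- sample_stake_sequence(config, seed = seed + 2L)
  tparr <- transition_prob_array(config)
  choose <- if (is.list(policy)) policy$choose else policy
  observe <- if (is.list(policy)) policy$observe else NULL

  withr::with_seed(seed, {
    start_state <- ifelse(stats::runif(n) < config$p_start_state, 1L, 2L)
    layout_u <- stats::runif(n)
    trans_u <- stats::runif(n)
    rows <- vector("list", n)
    for (t in seq_len(n)) {
      key_of <- trial_key_layout(config$randomize_keys, layout_u[t])
      ctx <- list(
        trial = t - 1L,
        stake = stakes[t],
        start_state = start_state[t],
        key_of = stats::setNames(key_labels()[key_of], action_labels()),
        runif = function() stats::runif(1)
      )
      act <- choose(ctx)
      a <- tryCatch(as_action_index(act), error = function(e) NA_integer_)
      if (is.na(a)) {
        stop("policy returned an invalid action at trial ", t - 1L,
             call. = FALSE)
      }
      p_red <- tparr[start_state[t], a, 1]
      planet <- if (trans_u[t] < p_red) 1L else 2L
      base <- walks[[planet_labels()[planet]]][t]
      rows[[t]] <- list(
        trial = t - 1L, stake = stakes[t], start_state = start_state[t],
        action = action_labels()[a],
        response_key = key_labels()[key_of[a]],
        planet = planet_labels()[planet],
        base_reward = base,
        delivered_reward = deliver_reward(base, stakes[t], config)
      )
      if (!is.null(observe)) observe(rows[[t]])
    }
    out <- dplyr::bind_rows(rows)
    if (n == 0) {
      out <- tibble::tibble(
        trial = integer(), stake = character(), start_state = integer(),
        action = character(), response_key = character(),
        planet = character(), base_reward = numeric(),
        delivered_reward = numeric()
      )
    }
    tibble::tibble(subject_id = rep(subject_id, n),
                   group = rep(group, n)) |>
      dplyr::bind_cols(out)
  })
}

#' Validate a session table
#'
#' Checks every structural invariant of a session: required columns,
#' consecutive 0-based trial indices per subject, legal factor levels,
#' planet consistent with the transition map, and the delivered reward
#' equal to the base reward times the stake multiplier on high-stakes
#' trials.
#'
#' @param sessions A session tibble (one or several subjects).
#' @inheritParams generate_reward_walks
#' @return `sessions`, invisibly; errors describe the first violation.
#' @export
validate_sessions <- function(sessions, config = task_config()) {
  required <- c("subject_id", "group", "trial", "stake", "start_state",
                "action", "response_key", "planet", "base_reward",
                "delivered_reward")
  missing <- setdiff(required, names(sessions))
  if (length(missing)) {
    stop("session table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(sessions) == 0) return(invisible(sessions))
  bad_stake <- which(!sessions$stake %in% c("low", "high"))
  if (length(bad_stake)) {
    stop("invalid stake label at row ", bad_stake[1], call. = FALSE)
  }
  bad <- which(!sessions$action %in% action_labels() |
                 !sessions$planet %in% planet_labels() |
                 !sessions$response_key %in% key_labels() |
                 !sessions$start_state %in% 1:2)
  if (length(bad)) {
    stop("invalid categorical value at row ", bad[1], call. = FALSE)
  }
  by_subj <- split(sessions$trial, sessions$subject_id)
  for (id in names(by_subj)) {
    tr <- by_subj[[id]]
    if (!identical(as.integer(tr), seq_along(tr) - 1L)) {
      stop("trial indices for subject ", id,
           " are not consecutive from 0", call. = FALSE)
    }
  }
  if (config$deterministic_transitions) {
    expected <- transition(sessions$start_state, sessions$action, config)
    bad <- which(expected != sessions$planet)
    if (length(bad)) {
      stop("planet inconsistent with the transition map at row ", bad[1],
           call. = FALSE)
    }
  }
  expected_del <- deliver_reward(sessions$base_reward, sessions$stake, config)
  bad <- which(abs(expected_del - sessions$delivered_reward) > 1e-9)
  if (length(bad)) {
    stop("delivered_reward inconsistent with stake at row ", bad[1],
         call. = FALSE)
  }
  invisible(sessions)
}
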