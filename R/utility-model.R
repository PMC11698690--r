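#' Risk-sensitive utility model parameters
#'
#' The five parameters of the mean-variance utility model: risk
#' sensitivity `mu` (positive values penalise variance — risk aversion —
#' and negative values reward it), softmax inverse temperature `beta_u`,
#' learning rate `eta`, discount factor `gamma_disc` applied to the planet
#' value when backing it up to the first stage, and `delta_limit`, the
#' maximum magnitude a temporal-difference error may take before being
#' clipped.
#'
#' @param mu Risk sensitivity (default bounds \[-2, 2\] in the fitter).
#' @param beta_u Inverse temperature, non-negative.
#' @param eta Learning rate in \[0, 1\].
#' @param gamma_disc Discount factor in \[0, 1\].
#' @param delta_limit Positive clipping bound for TD errors, in points.
#' @return Named numeric vector of class `"utility_params"`.
#' @export
utility_params <- function(mu, beta_u, eta, gamma_disc, delta_limit) {
  p <- c(mu = mu, beta_u = beta_u, eta = eta, gamma_disc = gamma_disc,
         delta_limit = delta_limit)
  if (!all(is.finite(p))) stop("parameters must be finite.", call. = FALSE)
  if (beta_u < 0) stop("`beta_u` must be non-negative.", call. = FALSE)
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1].", call. = FALSE)
  if (gamma_disc < 0 || gamma_disc > 1) {
    stop("`gamma_disc` must lie in [0, 1].", call. = FALSE)
  }
  if (delta_limit <= 0) {
    stop("`delta_limit` must be positive.", call. = FALSE)
  }
  structure(p, class = "utility_params")
}

#' Mean-variance utility
#'
#' `U = R - mu * sign(R) * sqrt(h)`: the expected return penalised (or
#' boosted, for `mu < 0`) by the running risk estimate. The `sign(R)`
#' factor makes a positive `mu` shrink the utility of positive-return
#' options and inflate the cost of negative-return ones, so risk-seeking
#' for gains and risk-aversion for losses fall out of a single
#' coefficient. `sign(0)` is taken as 0, so a zero expected return has
#' utility 0 whatever the risk.
#'
#' @param r_value Expected return (points).
#' @param h_value Risk (return variance, points squared); must be
#'   non-negative.
#' @param mu Risk sensitivity.
#' @return Utility value(s).
#' @export
#' @examples
#' utility(4, 4, 0.5)   # 3
#' utility(-4, 4, 0.5)  # -3
utility <- function(r_value, h_value, mu) {
  if (any(h_value < 0)) {
    stop("risk `h_value` must be non-negative.", call. = FALSE)
  }
  r_value - mu * sign(r_value) * sqrt(h_value)
}

#' Fresh utility-model state
#'
#' Expected-return estimates for the four first-stage state-action pairs
#' and the two planets, and a risk (return-variance) table for the
#' first-stage pairs only — the second-stage action is forced and carries
#' no risk trade-off.
#'
#' @return List with `r1` (2x2), `r2` (length 2), `h` (2x2).
#' @export
utility_state_new <- function() {
  list(r1 = matrix(0, 2, 2, dimnames = list(state = c("1", "2"),
                                            action = c("A", "B"))),
       r2 = c(red = 0, purple = 0),
       h = matrix(0, 2, 2))
}

#' One utility-model trial update
#'
#' Two temporal-difference passes with error clipping: the first-stage
#' error `delta1 = gamma_disc * R(planet) - R(s1, a1)` and the planet
#' error `delta2 = r - R(planet)` are each clipped to
#' `[-delta_limit, delta_limit]` and applied with learning rate `eta` to
#' their pair's expected return. The first-stage pair's risk then moves
#' toward the squared clipped first-stage error through the risk
#' prediction error `xi = delta1^2 - h`: `h <- h + eta * xi`, a convex
#' combination that keeps `h` non-negative.
#'
#' @param state A [utility_state_new()] state.
#' @param trial One-row list/tibble with `start_state`, `action`, `planet`.
#' @param params A [utility_params()].
#' @param reward The reward signal for this trial (points).
#' @return Updated state.
#' @export
utility_update <- function(state, trial, params, reward) {
  s <- as_state_index(trial$start_state)
  a <- as_action_index(trial$action)
  p <- match(trial$planet, planet_labels())
  dl <- params[["delta_limit"]]
  eta <- params[["eta"]]

  d1 <- clip(params[["gamma_disc"]] * state$r2[[p]] - state$r1[s, a], dl)
  d2 <- clip(reward - state$r2[[p]], dl)
  state$r1[s, a] <- state$r1[s, a] + eta * d1
  state$r2[p] <- state$r2[p] + eta * d2
  state$h[s, a] <- state$h[s, a] + eta * (d1^2 - state$h[s, a])
  state
}

clip <- function(x, limit) pmin(pmax(x, -limit), limit)

#' Softmax choice under the utility model
#'
#' `p(a) proportional to exp(beta_u * U(s, a))` over the two first-stage
#' actions, evaluated stably.
#'
#' @inheritParams utility_update
#' @param start_state First-stage state (1 or 2).
#' @return Length-2 probabilities summing to 1.
#' @export
utility_choice_probabilities <- function(state, start_state, params) {
  s <- as_state_index(start_state)
  u <- utility(state$r1[s, ], state$h[s, ], params[["mu"]])
  if (!all(is.finite(u))) stop("non-finite utilities.", call. = FALSE)
  x <- params[["beta_u"]] * u
  p <- exp(x - max(x))
  p / sum(p)
}

#' Session log-likelihood of the utility model
#'
#' Sum of log probabilities of the observed first-stage choices over the
#' trials passing the stake filter. The learning dynamics always run over
#' every trial in order — risk and return estimates accumulate
#' continuously — and only the likelihood sum is restricted, so the low-
#' and high-stake log-likelihoods add up to the unfiltered one.
#'
#' @param params A [utility_params()].
#' @param session Single-subject session tibble.
#' @param stake_filter `"all"`, `"low"` or `"high"`.
#' @param config A [task_config()]; `utility_reward` in the fit functions
#'   defaults to delivered points (the payout the stake cue announces).
#' @param reward_signal `"delivered"` (default) or `"base"`.
#' @return Log-likelihood (0 when no trial passes the filter).
#' @export
utility_log_likelihood <- function(params, session,
                                   stake_filter = c("all", "low", "high"),
                                   config = task_config(),
                                   reward_signal = c("delivered", "base")) {
  stake_filter <- match.arg(stake_filter)
  reward_signal <- match.arg(reward_signal)
  if (nrow(session) == 0) return(0)
  stake <- ifelse(session$stake == "high", 2L, 1L)
  reward <- if (reward_signal == "delivered") {
    as.numeric(session$delivered_reward)
  } else {
    as.numeric(session$base_reward)
  }
  utility_loglik_cpp(
    stake, as.integer(session$start_state),
    as_action_index(session$action),
    match(session$planet, planet_labels()), reward,
    params[["mu"]], params[["beta_u"]], params[["eta"]],
    params[["gamma_disc"]], params[["delta_limit"]],
    switch(stake_filter, all = 0L, low = 1L, high = 2L)
  )
}

#' Simulate a utility-model agent on the task
#'
#' Plays an agent that chooses by [utility_choice_probabilities()] and
#' learns by [utility_update()] through the generative environment. True
#' parameters are attached as the `"true_params"` attribute.
#'
#' @inheritParams utility_log_likelihood
#' @param seed Integer seed.
#' @param subject_id,group Session labels.
#' @return A session tibble.
#' @export
simulate_utility <- function(params, config = task_config(), seed,
                             subject_id = "sim", group = "unknown",
                             reward_signal = c("delivered", "base")) {
  reward_signal <- match.arg(reward_signal)
  state <- utility_state_new()

  choose <- function(tc) {
    pr <- utility_choice_probabilities(state, tc$start_state, params)
    action_labels()[if (tc$runif() < pr[1]) 1L else 2L]
  }
  observe <- function(trial) {
    r <- if (reward_signal == "delivered") {
      trial$delivered_reward
    } else {
      trial$base_reward
    }
    state <<- utility_update(state, trial, params, r)
  }

  out <- build_session(config, list(choose = choose, observe = observe),
                       seed = seed, subject_id = subject_id, group = group)
  attr(out, "true_params") <- params
  out
}
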