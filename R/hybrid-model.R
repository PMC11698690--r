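#' Dual-system model parameters
#'
#' The seven free parameters of the hybrid model: model-free learning rate
#' `alpha`, softmax inverse temperature `beta`, eligibility-trace decay
#' `lam`, stake-conditional mixing weights `w_low` and `w_high` between the
#' model-based and model-free action values, choice stickiness `pi`
#' (tendency to revisit the previously chosen planet) and response
#' stickiness `rho` (tendency to repeat the previous key press).
#'
#' `exhaustive_params()` builds the twelve-parameter variant in which every
#' parameter may take different values on low- and high-stakes trials.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @param lam Eligibility decay in \[0, 1\].
#' @param w_low,w_high Mixing weights in \[0, 1\] (0 = purely model-free,
#'   1 = purely model-based).
#' @param pi,rho Stickiness parameters (any finite real).
#' @return A named numeric vector of class `"hybrid_params"`.
#' @export
#' @examples
#' hybrid_params(alpha = 0.4, beta = 1, lam = 0.6,
#'               w_low = 0.3, w_high = 0.7, pi = 0.1, rho = 0)
hybrid_params <- function(alpha, beta, lam, w_low, w_high, pi = 0, rho = 0) {
  p <- c(alpha = alpha, beta = beta, lam = lam, w_low = w_low,
         w_high = w_high, pi = pi, rho = rho)
  check_unit <- function(nm) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1].", call. = FALSE)
    }
  }
  for (nm in c("alpha", "lam", "w_low", "w_high")) check_unit(nm)
  if (p[["beta"]] < 0 || !is.finite(p[["beta"]])) {
    stop("`beta` must be finite and non-negative.", call. = FALSE)
  }
  if (!all(is.finite(p))) stop("parameters must be finite.", call. = FALSE)
  structure(p, class = "hybrid_params")
}

#' @rdname hybrid_params
#' @param low,high Named vectors with elements `alpha`, `beta`, `lam`, `w`,
#'   `pi`, `rho` giving the parameter values used on low- and high-stakes
#'   trials.
#' @export
exhaustive_params <- function(low, high) {
  need <- c("alpha", "beta", "lam", "w", "pi", "rho")
  stopifnot(all(need %in% names(low)), all(need %in% names(high)))
  p <- c(stats::setNames(as.numeric(low[need]), paste0(need, "_low")),
         stats::setNames(as.numeric(high[need]), paste0(need, "_high")))
  for (nm in c("alpha", "lam", "w")) {
    for (sfx in c("_low", "_high")) {
      v <- p[[paste0(nm, sfx)]]
      if (v < 0 || v > 1) {
        stop("`", nm, sfx, "` must lie in [0, 1].", call. = FALSE)
      }
    }
  }
  structure(p, class = "exhaustive_params")
}

# (alpha, beta, lam, w, pi, rho) vectors for the low/high conditions
par_by_stake <- function(params) {
  if (inherits(params, "exhaustive_params") ||
      all(c("alpha_low", "alpha_high") %in% names(params))) {
    list(
      low = as.numeric(params[c("alpha_low", "beta_low", "lam_low",
                                "w_low", "pi_low", "rho_low")]),
      high = as.numeric(params[c("alpha_high", "beta_high", "lam_high",
                                 "w_high", "pi_high", "rho_high")])
    )
  } else {
    shared <- as.numeric(params[c("alpha", "beta", "lam")])
    list(
      low = c(shared, params[["w_low"]], params[["pi"]], params[["rho"]]),
      high = c(shared, params[["w_high"]], params[["pi"]], params[["rho"]])
    )
  }
}

#' Fresh model-free value state
#'
#' The model-free learner tracks `Q` values for the four first-stage
#' state-action pairs and the two planet states (one forced action each),
#' plus an eligibility trace per pair. Values start at 0 and traces are
#' reset at the start of every trial.
#'
#' @return A list with `q1` (2x2 first-stage values), `q2` (length-2 planet
#'   values), `e1`, `e2` (matching eligibility traces).
#' @export
value_state_new <- function() {
  list(q1 = matrix(0, 2, 2, dimnames = list(state = c("1", "2"),
                                            action = c("A", "B"))),
       q2 = c(red = 0, purple = 0),
       e1 = matrix(0, 2, 2),
       e2 = c(0, 0))
}

#' One SARSA(lambda) trial update
#'
#' Applies the model-free temporal-difference update for a completed trial,
#' in order: eligibility traces are zeroed at trial start; the trace of the
#' chosen first-stage pair is incremented, the first-stage prediction error
#' `delta1 = Q(planet) - Q(s1, a1)` (driven only by the second-stage value,
#' as no reward is delivered at stage 1) updates all pairs through their
#' traces, and traces decay by `lam`; then the planet trace is incremented,
#' the second-stage prediction error `delta2 = r - Q(planet)` (driven only
#' by the reward, as the task ends there) updates all pairs through their
#' traces — so the first-stage pair receives it down-weighted by `lam` —
#' and traces decay by `lam` again.
#'
#' @param state A value state from [value_state_new()].
#' @param trial One-row list or tibble with `start_state`, `action`,
#'   `planet`.
#' @param params A [hybrid_params()] (only `alpha` and `lam` are used).
#' @param learning_reward The reward signal the learner receives on this
#'   trial (points).
#' @return The updated value state.
#' @export
mf_update <- function(state, trial, params, learning_reward) {
  s <- as_state_index(trial$start_state)
  a <- as_action_index(trial$action)
  p <- match(trial$planet, planet_labels())
  alpha <- params[["alpha"]]
  lam <- params[["lam"]]

  state$e1[] <- 0
  state$e2[] <- 0

  state$e1[s, a] <- state$e1[s, a] + 1
  d1 <- state$q2[[p]] - state$q1[s, a]
  state$q1 <- state$q1 + alpha * d1 * state$e1
  state$q2 <- state$q2 + alpha * d1 * state$e2
  state$e1 <- state$e1 * lam
  state$e2 <- state$e2 * lam

  state$e2[p] <- state$e2[p] + 1
  d2 <- learning_reward - state$q2[[p]]
  state$q1 <- state$q1 + alpha * d2 * state$e1
  state$q2 <- state$q2 + alpha * d2 * state$e2
  state$e1 <- state$e1 * lam
  state$e2 <- state$e2 * lam

  state
}

#' Model-based first-stage action values
#'
#' The model-based planner evaluates each first-stage action by propagating
#' the current planet values through the task's transition structure:
#' `Q_MB(s, a) = sum_planet P(planet | s, a) * Q(planet)`. With the task's
#' deterministic transitions this is a lookup of the reached planet's
#' value, so both first-stage states share the same model-based values —
#' the structural equivalence a model-based agent exploits. At the second
#' stage the model-based and model-free values coincide.
#'
#' @inheritParams mf_update
#' @param config A [task_config()] supplying the transition structure.
#' @return A 2x2 matrix of `Q_MB` over (state, action).
#' @export
mb_values <- function(state, config = task_config()) {
  tp <- transition_prob_array(config)
  out <- matrix(0, 2, 2, dimnames = dimnames(state$q1))
  for (s in 1:2) for (a in 1:2) {
    out[s, a] <- sum(tp[s, a, ] * state$q2)
  }
  out
}

#' Mix model-based and model-free values
#'
#' `Q_net = omega * Q_MB + (1 - omega) * Q_MF`, with `omega` chosen per
#' trial according to the stake cue (`w_low` on low-stakes, `w_high` on
#' high-stakes trials).
#'
#' @param q_mb,q_mf Numeric values of matching shape.
#' @param omega Mixing weight in \[0, 1\].
#' @return The element-wise convex combination.
#' @export
mix_values <- function(q_mb, q_mf, omega) {
  if (omega < 0 || omega > 1) {
    stop("`omega` must lie in [0, 1].", call. = FALSE)
  }
  omega * q_mb + (1 - omega) * q_mf
}

#' Softmax choice probabilities with perseveration
#'
#' Probability of each first-stage action under
#' `p(a) proportional to exp(beta * (Q_net(a) + pi * rep(a) + rho *
#' resp(a)))`, evaluated with a numerically stable log-sum-exp. `rep(a)`
#' is 1 when action `a` leads to the planet chosen on the previous trial
#' (choice identity is carried by the destination planet, since the two
#' start states offer equivalent choices); `resp(a)` is 1 when `a` sits on
#' the key pressed on the previous trial.
#'
#' @param q_net Length-2 numeric, net action values.
#' @param ctx List with `prev_planet` and `prev_key` (labels, or `NULL` on
#'   the first trial).
#' @param planet_of Length-2 character, the planet each action leads to.
#' @param key_of Length-2 character, the key each action sits on.
#' @param params A [hybrid_params()] (uses `beta`, `pi`, `rho`).
#' @return Length-2 numeric probabilities summing to 1.
#' @export
#' @examples
#' choice_probabilities(
#'   c(1, 0), ctx = list(prev_planet = NULL, prev_key = NULL),
#'   planet_of = c("red", "purple"), key_of = c("left", "right"),
#'   params = hybrid_params(0.5, 1, 0.5, 0.5, 0.5))
choice_probabilities <- function(q_net, ctx, planet_of, key_of, params) {
  if (!all(is.finite(q_net))) {
    stop("non-finite action values.", call. = FALSE)
  }
  rep_a <- if (is.null(ctx$prev_planet)) c(0, 0) else {
    as.numeric(planet_of == ctx$prev_planet)
  }
  resp_a <- if (is.null(ctx$prev_key)) c(0, 0) else {
    as.numeric(key_of == ctx$prev_key)
  }
  x <- params[["beta"]] *
    (q_net + params[["pi"]] * rep_a + params[["rho"]] * resp_a)
  m <- max(x)
  p <- exp(x - m)
  p / sum(p)
}

# encode a single-subject session tibble into the integer vectors the C++
# core consumes
encode_session <- function(session, config) {
  list(
    stake = ifelse(session$stake == "high", 2L, 1L),
    state = as.integer(session$start_state),
    action = as_action_index(session$action),
    planet = match(session$planet, planet_labels()),
    keyidx = match(session$response_key, key_labels()),
    reward = if (config$learning_reward == "delivered") {
      as.numeric(session$delivered_reward)
    } else {
      as.numeric(session$base_reward)
    }
  )
}

#' Session log-likelihood of the dual-system model
#'
#' Sum over trials of the log probability of the observed first-stage
#' action under the hybrid (or exhaustive) model, with the model-free
#' values evolved by the SARSA(lambda) update on the observed events. The
#' planet stage offers a single forced action and contributes nothing. For
#' exhaustive parameters, each trial uses the parameter values of its stake
#' condition over one shared value table.
#'
#' @param params A [hybrid_params()] or [exhaustive_params()].
#' @param session Single-subject session tibble (see [build_session()]).
#' @param config A [task_config()]; `learning_reward` selects whether the
#'   learner sees base or delivered points.
#' @return The log-likelihood (0 for an empty session).
#' @export
session_log_likelihood <- function(params, session,
                                   config = task_config()) {
  if (nrow(session) == 0) return(0)
  enc <- encode_session(session, config)
  ps <- par_by_stake(params)
  tp <- transition_prob_array(config)
  hybrid_loglik_cpp(enc$stake, enc$state, enc$action, enc$planet,
                    enc$keyidx, enc$reward, ps$low, ps$high,
                    as.numeric(aperm(tp, c(3, 2, 1))))
}

#' Log posterior of the dual-system model
#'
#' `session_log_likelihood()` plus the summed log prior densities of the
#' parameters. Returns `-Inf` when any prior density is zero (for example
#' a Beta(2, 2) parameter at its boundary) rather than raising an error.
#'
#' @inheritParams session_log_likelihood
#' @param priors A `prior_spec`; see [hybrid_priors()].
#' @return The log posterior (up to the model-evidence constant).
#' @export
log_posterior <- function(params, session, priors,
                          config = task_config()) {
  lp <- hybrid_log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + session_log_likelihood(params, session, config)
}

# prior term for hybrid or exhaustive parameter vectors; exhaustive
# parameters reuse the base-name prior for both stake conditions
hybrid_log_prior <- function(params, priors) {
  nms <- names(params)
  total <- 0
  for (nm in nms) {
    base <- if (nm %in% names(priors)) {
      nm
    } else if (sub("_(low|high)$", "", nm) %in% names(priors)) {
      sub("_(low|high)$", "", nm)
    } else if (sub("_(low|high)$", "", nm) == "w") {
      # exhaustive w_low/w_high match the hybrid names directly
      nm
    } else {
      stop("no prior found for parameter ", nm, call. = FALSE)
    }
    total <- total + prior_log_density_1(priors[[base]], params[[nm]])
  }
  total
}
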