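#' Simulate a dual-system agent on the task
#'
#' Plays a hybrid agent with known parameters through the generative
#' environment: on each trial the agent mixes its model-based and
#' model-free values with the stake-appropriate weight, samples an action
#' from [choice_probabilities()], and learns from the outcome via
#' [mf_update()]. The true parameters are attached to the returned session
#' as the `"true_params"` attribute.
#'
#' @param params A [hybrid_params()].
#' @param config A [task_config()]; `config$learning_reward` selects
#'   whether the agent learns from base or delivered points.
#' @param seed Integer seed (fully determines the session).
#' @param subject_id,group Labels stored on the session rows.
#' @return A session tibble (see [build_session()]).
#' @export
#' @examples
#' s <- simulate_hybrid(
#'   hybrid_params(0.5, 1, 0.6, 0.3, 0.7), task_config(n_trials = 20),
#'   seed = 1)
#' nrow(s)
simulate_hybrid <- function(params, config = task_config(), seed,
                            subject_id = "sim", group = "unknown") {
  state <- value_state_new()
  ctx <- list(prev_planet = NULL, prev_key = NULL)
  tm <- config$transition_map

  choose <- function(tc) {
    s <- tc$start_state
    omega <- if (tc$stake == "high") params[["w_high"]] else params[["w_low"]]
    qmb <- mb_values(state, config)
    qnet <- mix_values(qmb[s, ], state$q1[s, ], omega)
    planet_of <- planet_labels()[tm[s, ]]
    pr <- choice_probabilities(qnet, ctx, planet_of, tc$key_of, params)
    action_labels()[if (tc$runif() < pr[1]) 1L else 2L]
  }
  observe <- function(trial) {
    r <- if (config$learning_reward == "delivered") {
      trial$delivered_reward
    } else {
      trial$base_reward
    }
    state <<- mf_update(state, trial, params, r)
    ctx$prev_planet <<- trial$planet
    ctx$prev_key <<- trial$response_key
  }

  out <- build_session(config, list(choose = choose, observe = observe),
                       seed = seed, subject_id = subject_id, group = group)
  attr(out, "true_params") <- params
  out
}
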