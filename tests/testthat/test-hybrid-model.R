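trial_row <- function(start_state = 1, action = "A") {
  list(start_state = start_state, action = action,
       planet = if (action == "A") "red" else "purple")
}

test_that("SARSA(lambda) updates propagate reward by the trace decay", {
  p <- function(lam) hybrid_params(0.5, 1, lam, 0.5, 0.5)

  # lambda = 0: only the planet value moves
  st <- mf_update(value_state_new(), trial_row(), p(0), 8)
  expect_equal(st$q2[["red"]], 4)
  expect_equal(unname(st$q1[1, 1]), 0)

  # lambda = 1: first-stage pair updated by the same amount
  st <- mf_update(value_state_new(), trial_row(), p(1), 8)
  expect_equal(st$q2[["red"]], 4)
  expect_equal(unname(st$q1[1, 1]), 4)

  # lambda = 0.5: half the planet update reaches stage 1
  st <- mf_update(value_state_new(), trial_row(), p(0.5), 8)
  expect_equal(st$q2[["red"]], 4)
  expect_equal(unname(st$q1[1, 1]), 2)

  # alpha = 0: nothing changes
  st <- mf_update(value_state_new(), trial_row(),
                  hybrid_params(0, 1, 0.5, 0.5, 0.5), 8)
  expect_equal(st$q1, value_state_new()$q1)
  expect_equal(st$q2, value_state_new()$q2)
})

test_that("non-zero first-stage values feed the bootstrapped RPE", {
  # two trials to the same planet: second stage-1 RPE uses learned value
  p <- hybrid_params(0.5, 1, 0, 0.5, 0.5)
  st <- mf_update(value_state_new(), trial_row(), p, 8)  # q2 red = 4
  st <- mf_update(st, trial_row(), p, 0)
  # stage 1: d1 = 4 - 0 -> q1[1,A] = 2; stage 2: d2 = -4 -> q2 red = 2
  expect_equal(unname(st$q1[1, 1]), 2)
  expect_equal(st$q2[["red"]], 2)
})

test_that("eligibility traces end each trial decayed exactly twice", {
  for (lam in c(0, 0.3, 1)) {
    st <- mf_update(value_state_new(), trial_row(2, "B"),
                    hybrid_params(0.2, 1, lam, 0.5, 0.5), 5)
    expect_equal(unname(st$e1[2, 2]), lam^2)   # incremented then decayed twice
    expect_equal(st$e2[[2]], lam)              # incremented between decays
    expect_true(all(st$e1 >= 0) && all(st$e2 >= 0))
  }
})

test_that("model-based values plan through the transition structure", {
  st <- value_state_new()
  st$q2 <- c(red = 6, purple = 2)
  qmb <- mb_values(st)
  # both first-stage states offer the identical red/purple choice
  expect_equal(unname(qmb[1, ]), c(6, 2))
  expect_equal(unname(qmb[2, ]), c(6, 2))
  expect_equal(mb_values(value_state_new()), matrix(0, 2, 2),
               ignore_attr = TRUE)

  # stochastic transitions take the expectation
  cfg <- task_config(deterministic_transitions = FALSE,
                     transition_probs = array(c(0.7, 0.3, 0.3, 0.7,
                                                0.3, 0.7, 0.7, 0.3),
                                              dim = c(2, 2, 2)))
  qmb2 <- mb_values(st, cfg)
  expect_equal(unname(qmb2[1, 1]), 0.7 * 6 + 0.3 * 2)
})

test_that("value mixing is the convex combination with stake-specific omega", {
  expect_equal(mix_values(4, 2, 1), 4)
  expect_equal(mix_values(4, 2, 0), 2)
  expect_equal(mix_values(4, 2, 0.5), 3)
  expect_error(mix_values(4, 2, 1.5), "omega")
})

test_that("softmax choice probabilities follow the stickiness-augmented rule", {
  no_hist <- list(prev_planet = NULL, prev_key = NULL)
  planets <- c("red", "purple")
  keys <- c("left", "right")

  p0 <- choice_probabilities(c(3, -1), no_hist, planets, keys,
                             hybrid_params(0.5, 0, 0.5, 0.5, 0.5))
  expect_equal(p0, c(0.5, 0.5))

  p1 <- choice_probabilities(c(1, 0), no_hist, planets, keys,
                             hybrid_params(0.5, 1, 0.5, 0.5, 0.5))
  expect_equal(p1, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  # perseveration: previous planet matching action A tilts choice toward A
  hist <- list(prev_planet = "red", prev_key = NULL)
  p2 <- choice_probabilities(c(0, 0), hist, planets, keys,
                             hybrid_params(0.5, 1, 0.5, 0.5, 0.5, pi = 0.7))
  expect_gt(p2[1], 0.5)

  # response stickiness works on the key layout
  hist_k <- list(prev_planet = NULL, prev_key = "right")
  p3 <- choice_probabilities(c(0, 0), hist_k, planets, keys,
                             hybrid_params(0.5, 1, 0.5, 0.5, 0.5, rho = 0.7))
  expect_gt(p3[2], 0.5)

  expect_error(
    choice_probabilities(c(NaN, 0), no_hist, planets, keys,
                         hybrid_params(0.5, 1, 0.5, 0.5, 0.5)),
    "finite")
})

test_that("choice probabilities are invariant to constant value shifts", {
  params <- hybrid_params(0.5, 1.3, 0.5, 0.5, 0.5, 0.2, -0.1)
  no_hist <- list(prev_planet = "red", prev_key = "left")
  for (i in 1:20) {
    q <- withr::with_seed(i, rnorm(2, sd = 3))
    c0 <- choice_probabilities(q, no_hist, c("red", "purple"),
                               c("left", "right"), params)
    c1 <- choice_probabilities(q + 57.3, no_hist, c("red", "purple"),
                               c("left", "right"), params)
    expect_equal(sum(c0), 1, tolerance = 1e-12)
    expect_equal(c0, c1, tolerance = 1e-9)
  }
})

test_that("session likelihood matches elementary hand cases", {
  params <- hybrid_params(0.5, 0, 0.5, 0.5, 0.5)
  expect_equal(session_log_likelihood(params, one_trial_session()),
               log(0.5), tolerance = 1e-12)
  empty <- one_trial_session()[0, ]
  expect_equal(session_log_likelihood(params, empty), 0)
})

test_that("session likelihood matches the hand-stepped oracle", {
  pr <- hybrid_priors()
  for (i in 1:25) {
    sess <- random_session(10, seed = 1000 + i)
    params <- withr::with_seed(2000 + i, {
      p <- sample_from_priors(pr)
      hybrid_params(p[["alpha"]], p[["beta"]], p[["lam"]], p[["w_low"]],
                    p[["w_high"]], p[["pi"]], p[["rho"]])
    })
    expect_equal(
      session_log_likelihood(params, sess),
      oracle_hybrid_loglik7(params, sess, sess$base_reward),
      tolerance = 1e-9)
  }
})

test_that("the learning-reward switch feeds delivered points to the learner", {
  sess <- random_session(10, seed = 77)
  params <- hybrid_params(0.4, 0.8, 0.5, 0.3, 0.7, 0.1, 0)
  cfg_del <- task_config(learning_reward = "delivered")
  expect_equal(session_log_likelihood(params, sess, cfg_del),
               oracle_hybrid_loglik7(params, sess, sess$delivered_reward),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(
    session_log_likelihood(params, sess, cfg_del),
    session_log_likelihood(params, sess))))
})

test_that("the exhaustive model nests the hybrid model bit-for-bit", {
  sess <- random_session(30, seed = 5)
  hp <- hybrid_params(0.55, 1.2, 0.4, 0.25, 0.8, 0.3, -0.2)
  ep <- exhaustive_params(
    low = c(alpha = 0.55, beta = 1.2, lam = 0.4, w = 0.25, pi = 0.3,
            rho = -0.2),
    high = c(alpha = 0.55, beta = 1.2, lam = 0.4, w = 0.8, pi = 0.3,
             rho = -0.2))
  expect_identical(session_log_likelihood(ep, sess),
                   session_log_likelihood(hp, sess))
})

test_that("exhaustive likelihood switches parameters by stake over one table", {
  sess <- random_session(12, seed = 9)
  low <- c(alpha = 0.3, beta = 0.7, lam = 0.2, w = 0.1, pi = 0.05,
           rho = 0.02)
  high <- c(alpha = 0.8, beta = 1.5, lam = 0.9, w = 0.9, pi = -0.2,
            rho = 0.1)
  ep <- exhaustive_params(low, high)
  expect_equal(session_log_likelihood(ep, sess),
               oracle_hybrid_loglik(low, high, sess, sess$base_reward),
               tolerance = 1e-9)
})

test_that("log posterior adds the prior term and flags zero-density points", {
  pr <- hybrid_priors()
  params <- hybrid_params(0.4, 0.8, 0.5, 0.3, 0.7, 0.1, 0)
  empty <- one_trial_session()[0, ]
  expect_equal(log_posterior(params, empty, pr),
               log_prior_density(pr, unclass(params)))

  boundary <- hybrid_params(0.4, 0.8, 0.5, 0, 0.7, 0.1, 0)
  expect_identical(log_posterior(boundary, empty, pr), -Inf)

  # the posterior-likelihood gap depends only on the parameters
  s1 <- random_session(8, seed = 1)
  s2 <- random_session(8, seed = 2)
  gap1 <- log_posterior(params, s1, pr) -
    session_log_likelihood(params, s1)
  gap2 <- log_posterior(params, s2, pr) -
    session_log_likelihood(params, s2)
  expect_equal(gap1, gap2, tolerance = 1e-10)
})

test_that("simulated hybrid agents are reproducible and model-based control
          pays off in this task", {
  params <- hybrid_params(0.5, 3, 0.6, 0.5, 0.5)
  cfg <- task_config(n_trials = 200)
  expect_identical(simulate_hybrid(params, cfg, seed = 21),
                   simulate_hybrid(params, cfg, seed = 21))

  mean_reward <- function(w, seeds) {
    p <- hybrid_params(0.7, 5, 0.6, w, w)
    mean(vapply(seeds, function(s) {
      mean(simulate_hybrid(p, cfg, seed = s)$base_reward)
    }, numeric(1)))
  }
  seeds <- 1:30
  expect_gt(mean_reward(1, seeds), mean_reward(0, seeds))
})
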