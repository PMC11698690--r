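# Independent hand-stepped oracles, written directly from the model
# equations with scalar arithmetic and explicit bookkeeping. They share no
# code with the package implementation and deliberately use a different
# data layout (one named numeric vector over explicit state-action labels).

# default deterministic transition structure: action A -> red, B -> purple
# from both first-stage states
oracle_planet_of <- function(action) if (action == "A") "red" else "purple"

# Dual-system session log-likelihood, hand-stepped trial by trial.
# par_low / par_high: named vectors with alpha, beta, lam, w, pi, rho.
# session: data frame with stake, start_state, action, planet,
# response_key; reward: the learning signal per trial.
oracle_hybrid_loglik <- function(par_low, par_high, session, reward) {
  pairs1 <- c("1.A", "1.B", "2.A", "2.B")
  q <- c("1.A" = 0, "1.B" = 0, "2.A" = 0, "2.B" = 0, red = 0, purple = 0)
  prev_planet <- NA_character_
  prev_key <- NA_character_
  ll <- 0
  for (t in seq_len(nrow(session))) {
    par <- if (session$stake[t] == "high") par_high else par_low
    s <- session$start_state[t]
    a <- session$action[t]
    chosen <- paste0(s, ".", a)
    key_chosen <- session$response_key[t]

    # softmax over the two first-stage actions
    logits <- numeric(2)
    for (j in 1:2) {
      act <- c("A", "B")[j]
      qmb <- q[[oracle_planet_of(act)]]
      qnet <- par[["w"]] * qmb + (1 - par[["w"]]) * q[[paste0(s, ".", act)]]
      rep_a <- if (!is.na(prev_planet) && oracle_planet_of(act) == prev_planet) 1 else 0
      key_a <- if (act == a) key_chosen else setdiff(c("left", "right"), key_chosen)
      resp_a <- if (!is.na(prev_key) && key_a == prev_key) 1 else 0
      logits[j] <- par[["beta"]] *
        (qnet + par[["pi"]] * rep_a + par[["rho"]] * resp_a)
    }
    pchosen <- exp(logits[match(a, c("A", "B"))]) / sum(exp(logits))
    ll <- ll + log(pchosen)

    # SARSA(lambda) pass: traces reset, two updates, two decays
    e <- c("1.A" = 0, "1.B" = 0, "2.A" = 0, "2.B" = 0, red = 0, purple = 0)
    e[chosen] <- e[chosen] + 1
    d1 <- q[[session$planet[t]]] - q[[chosen]]
    for (nm in names(q)) q[nm] <- q[nm] + par[["alpha"]] * d1 * e[nm]
    e <- e * par[["lam"]]
    e[session$planet[t]] <- e[session$planet[t]] + 1
    d2 <- reward[t] - q[[session$planet[t]]]
    for (nm in names(q)) q[nm] <- q[nm] + par[["alpha"]] * d2 * e[nm]
    e <- e * par[["lam"]]

    prev_planet <- session$planet[t]
    prev_key <- key_chosen
  }
  ll
}

# convenience wrapper for the 7-parameter hybrid model
oracle_hybrid_loglik7 <- function(params, session, reward) {
  base <- c(alpha = params[["alpha"]], beta = params[["beta"]],
            lam = params[["lam"]], pi = params[["pi"]],
            rho = params[["rho"]])
  oracle_hybrid_loglik(c(base, w = params[["w_low"]]),
                       c(base, w = params[["w_high"]]),
                       session, reward)
}

# Risk-sensitive utility model log-likelihood, hand-stepped.
oracle_utility_loglik <- function(mu, beta_u, eta, gam, dlim, session,
                                  reward, filter = "all") {
  r <- c("1.A" = 0, "1.B" = 0, "2.A" = 0, "2.B" = 0, red = 0, purple = 0)
  h <- c("1.A" = 0, "1.B" = 0, "2.A" = 0, "2.B" = 0)
  ll <- 0
  for (t in seq_len(nrow(session))) {
    s <- session$start_state[t]
    a <- session$action[t]
    chosen <- paste0(s, ".", a)

    if (filter == "all" || session$stake[t] == filter) {
      u <- numeric(2)
      for (j in 1:2) {
        key <- paste0(s, ".", c("A", "B")[j])
        u[j] <- r[[key]] - mu * sign(r[[key]]) * sqrt(h[[key]])
      }
      x <- beta_u * u
      ll <- ll + x[match(a, c("A", "B"))] - log(sum(exp(x)))
    }

    d1 <- gam * r[[session$planet[t]]] - r[[chosen]]
    d1 <- max(min(d1, dlim), -dlim)
    d2 <- reward[t] - r[[session$planet[t]]]
    d2 <- max(min(d2, dlim), -dlim)
    r[chosen] <- r[chosen] + eta * d1
    r[session$planet[t]] <- r[session$planet[t]] + eta * d2
    h[chosen] <- h[chosen] + eta * (d1^2 - h[chosen])
  }
  ll
}

# random session generator for oracle comparisons (default transition map,
# fixed A = left layout, integer payoffs 0..9)
random_session <- function(n, seed, subject_id = "t") {
  withr::with_seed(seed, {
    stake <- sample(c("low", "high"), n, replace = TRUE)
    start_state <- sample(1:2, n, replace = TRUE)
    action <- sample(c("A", "B"), n, replace = TRUE)
    planet <- ifelse(action == "A", "red", "purple")
    base <- sample(0:9, n, replace = TRUE)
    tibble::tibble(
      subject_id = subject_id, group = "unknown",
      trial = seq_len(n) - 1L, stake = stake, start_state = start_state,
      action = action,
      response_key = ifelse(action == "A", "left", "right"),
      planet = planet, base_reward = as.numeric(base),
      delivered_reward = ifelse(stake == "high", base * 5, base))
  })
}

# one-trial session builder for hand checks
one_trial_session <- function(stake = "low", start_state = 1,
                              action = "A", base_reward = 3) {
  planet <- if (action == "A") "red" else "purple"
  tibble::tibble(
    subject_id = "t", group = "unknown", trial = 0L, stake = stake,
    start_state = as.integer(start_state), action = action,
    response_key = if (action == "A") "left" else "right",
    planet = planet, base_reward = as.numeric(base_reward),
    delivered_reward = if (stake == "high") base_reward * 5 else
      as.numeric(base_reward))
}
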