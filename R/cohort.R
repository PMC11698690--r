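#' Specification of one synthetic subject group
#'
#' Describes how one group's subjects are generated: each parameter of the
#' generating agent is drawn independently from a truncated Gaussian with
#' the given location, scale and truncation interval.
#'
#' @param label Group label, e.g. `"user"` or `"nonuser"`.
#' @param n_subjects Number of subjects (at least 1).
#' @param dist Named list; each element is a list with `loc`, `scale`,
#'   `lower`, `upper`.
#' @param seed Integer seed for the group; each subject's draw and session
#'   are derived from `(seed, subject_index)` so subjects are individually
#'   reproducible.
#' @return A list of class `"group_spec"`.
#' @export
group_spec <- function(label, n_subjects, dist, seed) {
  stopifnot(n_subjects >= 1)
  for (nm in names(dist)) {
    d <- dist[[nm]]
    if (d$lower >= d$upper) {
      stop("empty truncation interval for `", nm, "`.", call. = FALSE)
    }
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 dist = dist, seed = as.integer(seed)),
            class = "group_spec")
}

#' Built-in study-emulating cohort presets
#'
#' Loads the version-controlled preset file shipped with the package. The
#' hybrid preset gives the non-user group a positive high-minus-low
#' mixing-weight difference (mean 0.35 vs 0.55) and the user group a flat
#' profile (0.45 vs 0.45); the utility preset gives both groups a higher
#' high-stakes risk sensitivity, smaller in the user group.
#'
#' @param agent_kind `"hybrid"` or `"utility"`.
#' @param n_nonuser,n_user Group sizes (defaults 34 and 47).
#' @param seed Master seed; group seeds are derived from it.
#' @return List of two [group_spec()]s (nonuser, user).
#' @export
default_group_specs <- function(agent_kind = c("hybrid", "utility"),
                                n_nonuser = 34, n_user = 47, seed = 1) {
  agent_kind <- match.arg(agent_kind)
  presets <- cohort_presets()
  list(
    group_spec("nonuser", n_nonuser, presets[[agent_kind]]$nonuser,
               seed = seed * 1000L + 1L),
    group_spec("user", n_user, presets[[agent_kind]]$user,
               seed = seed * 1000L + 2L)
  )
}

cohort_presets <- function() {
  path <- system.file("extdata", "cohort_presets.json", package = "stakerl")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

rtruncnorm1 <- function(loc, scale, lower, upper) {
  if (scale == 0) return(min(max(loc, lower), upper))
  # inverse-CDF sampling; exact for one draw and never rejects
  plo <- stats::pnorm(lower, loc, scale)
  phi <- stats::pnorm(upper, loc, scale)
  stats::qnorm(stats::runif(1, plo, phi), loc, scale)
}

subject_seed <- function(group_seed, subject_index, stream = 0L) {
  # fixed splitting rule keeping derived seeds within 32-bit range
  (group_seed * 577L + subject_index * 7919L + stream * 263L) %% 2000000011L
}

#' Draw one subject's true parameters
#'
#' Independent truncated-Gaussian draws per parameter, reproducible from
#' the group seed and the subject index alone.
#'
#' @param spec A [group_spec()].
#' @param subject_index 1-based subject index within the group.
#' @return Named numeric vector of parameter values.
#' @export
draw_subject_params <- function(spec, subject_index) {
  withr::with_seed(subject_seed(spec$seed, subject_index, 1L), {
    vapply(spec$dist, function(d) {
      rtruncnorm1(d$loc, d$scale, d$lower, d$upper)
    }, numeric(1))
  })
}

#' Generate a synthetic two-group cohort
#'
#' For each subject, draws true generating parameters from the group's
#' distributions and simulates a complete task session with the chosen
#' agent. Utility-preset parameters named `mu_low`/`mu_high` produce an
#' agent whose risk sensitivity follows the trial's stake cue.
#'
#' @param specs List of [group_spec()]s (see [default_group_specs()]).
#' @param config A [task_config()].
#' @param agent_kind `"hybrid"` or `"utility"`.
#' @param include_severity If `TRUE`, adds a synthetic alcohol-severity
#'   covariate (group-dependent truncated Gaussian) to the truth table,
#'   for exercising the correlation stage.
#' @return A list of class `"cohort_dataset"` with `sessions` (all trials,
#'   one tibble), `truth` (one row per subject: group, true parameters)
#'   and `provenance` (specs and config).
#' @export
#' @examples
#' specs <- default_group_specs("hybrid", n_nonuser = 2, n_user = 2)
#' cohort <- generate_cohort(specs, task_config(n_trials = 10), "hybrid")
#' cohort$truth
generate_cohort <- function(specs, config = task_config(),
                            agent_kind = c("hybrid", "utility"),
                            include_severity = FALSE) {
  agent_kind <- match.arg(agent_kind)
  sev_presets <- if (include_severity) cohort_presets()$severity else NULL
  sessions <- list()
  truth <- list()
  for (spec in specs) {
    for (i in seq_len(spec$n_subjects)) {
      pars <- draw_subject_params(spec, i)
      sid <- sprintf("%s_%03d", spec$label, i)
      sim_seed <- subject_seed(spec$seed, i, 2L)
      sess <- if (agent_kind == "hybrid") {
        simulate_hybrid(
          hybrid_params(pars[["alpha"]], pars[["beta"]], pars[["lam"]],
                        pars[["w_low"]], pars[["w_high"]],
                        pars[["pi"]], pars[["rho"]]),
          config, seed = sim_seed, subject_id = sid, group = spec$label)
      } else {
        simulate_utility_stakewise(pars, config, sim_seed, sid, spec$label)
      }
      row <- tibble::as_tibble(as.list(pars)) |>
        dplyr::mutate(subject_id = sid, group = spec$label,
                      .before = 1)
      if (include_severity) {
        d <- sev_presets[[spec$label]]
        row$severity <- withr::with_seed(
          subject_seed(spec$seed, i, 3L),
          rtruncnorm1(d$loc, d$scale, d$lower, d$upper))
      }
      attr(sess, "true_params") <- NULL  # truth lives in the truth table
      sessions[[sid]] <- sess
      truth[[sid]] <- row
    }
  }
  structure(
    list(sessions = dplyr::bind_rows(sessions),
         truth = dplyr::bind_rows(truth),
         provenance = list(specs = specs, config = config,
                           agent_kind = agent_kind)),
    class = "cohort_dataset"
  )
}

# utility agent whose risk sensitivity can differ by stake cue
simulate_utility_stakewise <- function(pars, config, seed, subject_id,
                                       group) {
  has_split_mu <- all(c("mu_low", "mu_high") %in% names(pars))
  base <- utility_params(
    mu = if (has_split_mu) pars[["mu_low"]] else pars[["mu"]],
    beta_u = pars[["beta_u"]], eta = pars[["eta"]],
    gamma_disc = pars[["gamma_disc"]], delta_limit = pars[["delta_limit"]])
  if (!has_split_mu) {
    return(simulate_utility(base, config, seed, subject_id, group))
  }
  state <- utility_state_new()
  choose <- function(tc) {
    p <- base
    p[["mu"]] <- if (tc$stake == "high") pars[["mu_high"]] else
      pars[["mu_low"]]
    pr <- utility_choice_probabilities(state, tc$start_state, p)
    action_labels()[if (tc$runif() < pr[1]) 1L else 2L]
  }
  observe <- function(trial) {
    state <<- utility_update(state, trial, base, trial$delivered_reward)
  }
  out <- build_session(config, list(choose = choose, observe = observe),
                       seed = seed, subject_id = subject_id, group = group)
  attr(out, "true_params") <- pars
  out
}

#' Write a cohort to disk
#'
#' Writes the standard session CSV plus a truth CSV (one row per subject,
#' one column per true parameter).
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sessions(cohort$sessions, file.path(dir, "sessions.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
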