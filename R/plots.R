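#' Diagnostic plots
#'
#' `plot_reward_walks()` shows the drifting payoffs of the two planets.
#' `plot_recovery()` shows recovered against true parameter values for a
#' fitted synthetic cohort. `plot_stake_weights()` shows the per-group
#' low/high mixing-weight (or risk-sensitivity) profiles behind the
#' stakes-by-group interaction.
#'
#' @param walks Tibble from [generate_reward_walks()].
#' @return A ggplot object.
#' @export
plot_reward_walks <- function(walks) {
  long <- tidyr::pivot_longer(walks, c("red", "purple"),
                              names_to = "planet", values_to = "payoff")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$trial, y = .data$payoff,
                               colour = .data$planet)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(red = "#c0392b",
                                            purple = "#8e44ad")) +
    ggplot2::labs(x = "trial", y = "payoff (points)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_reward_walks
#' @param cohort A `cohort_dataset`.
#' @param fits Subject parameter table with columns matching the truth.
#' @param parameters Which parameters to facet over; defaults to all
#'   shared columns.
#' @export
plot_recovery <- function(cohort, fits, parameters = NULL) {
  truth <- cohort$truth
  params <- parameters %||%
    intersect(setdiff(names(truth), c("subject_id", "group")), names(fits))
  merged <- dplyr::inner_join(
    tidyr::pivot_longer(truth[, c("subject_id", params)],
                        dplyr::all_of(params),
                        names_to = "parameter", values_to = "true"),
    tidyr::pivot_longer(fits[, c("subject_id", params)],
                        dplyr::all_of(params),
                        names_to = "parameter", values_to = "recovered"),
    by = c("subject_id", "parameter"))
  ggplot2::ggplot(merged,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true value", y = "recovered value") +
    ggplot2::theme_minimal()
}

#' @rdname plot_reward_walks
#' @param table Subject parameter table.
#' @param parameter `"omega"` or `"mu"`.
#' @export
plot_stake_weights <- function(table, parameter = c("omega", "mu")) {
  cols <- parameter_columns(table, parameter)
  long <- tidyr::pivot_longer(table[, c("subject_id", "group", cols)],
                              dplyr::all_of(cols),
                              names_to = "stake", values_to = "value")
  long$stake <- factor(ifelse(long$stake == cols[1], "low", "high"),
                       levels = c("low", "high"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stake, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.2) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$group),
                          fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "stake condition", y = "estimate", colour = NULL) +
    ggplot2::theme_minimal()
}
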