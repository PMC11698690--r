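#' Mixed stakes-by-group ANOVA on a subject parameter table
#'
#' A 2 x 2 analysis of variance with the stake condition (low vs high) as
#' the within-subject factor and group as the between-subject factor —
#' every subject contributes one low-stakes and one high-stakes estimate,
#' so with `n` subjects each effect is tested on (1, n - 2) degrees of
#' freedom. Reports F, p and partial eta-squared per effect.
#'
#' @param table Tibble with one row per subject: `subject_id`, `group`,
#'   and a low/high column pair for the requested parameter (`w_low` /
#'   `w_high` for `"omega"`, `mu_low` / `mu_high` for `"mu"`).
#' @param parameter `"omega"` (mixing weight) or `"mu"` (risk
#'   sensitivity), or a custom `c(low_col, high_col)` pair.
#' @return Tibble of class `"stakerl_anova"`: columns `effect`, `df1`,
#'   `df2`, `statistic`, `p.value`, `partial_eta_sq`.
#' @export
mixed_anova_2x2 <- function(table, parameter = c("omega", "mu")) {
  cols <- parameter_columns(table, parameter)
  if (length(unique(table$group)) < 2) {
    stop("both groups must be present.", call. = FALSE)
  }
  if (any(tabulate(factor(table$group)) < 2)) {
    stop("each group needs at least 2 subjects.", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    table[, c("subject_id", "group", cols)],
    cols = dplyr::all_of(cols), names_to = "stake", values_to = "value")
  long$stake <- factor(ifelse(long$stake == cols[1], "low", "high"),
                       levels = c("low", "high"))
  long$group <- factor(long$group)
  long$subject_id <- factor(long$subject_id)
  if (anyNA(long$value)) {
    stop("low and high values must be present for every subject.",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ group * stake + Error(subject_id), data = long)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject_id"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  pull_effect <- function(stratum, row_name, label) {
    rows <- trimws(rownames(stratum))
    i <- match(row_name, rows)
    res <- match("Residuals", rows)
    ss <- stratum$`Sum Sq`
    tibble::tibble(
      effect = label,
      df1 = stratum$Df[i], df2 = stratum$Df[res],
      statistic = stratum$`F value`[i],
      p.value = stratum$`Pr(>F)`[i],
      partial_eta_sq = ss[i] / (ss[i] + ss[res])
    )
  }
  out <- dplyr::bind_rows(
    pull_effect(wth, "stake", "stakes"),
    pull_effect(btw, "group", "group"),
    pull_effect(wth, "group:stake", "interaction")
  )
  class(out) <- c("stakerl_anova", class(out))
  out
}

parameter_columns <- function(table, parameter) {
  if (length(parameter) == 2 && all(parameter %in% names(table))) {
    return(parameter)
  }
  parameter <- match.arg(parameter[1], c("omega", "mu"))
  cols <- switch(parameter,
                 omega = c("w_low", "w_high"),
                 mu = c("mu_low", "mu_high"))
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols
}

# tie-corrected normal-approximation z for the Mann-Whitney U statistic
# (U counts pairs where a group-1 value exceeds a group-2 value)
mann_whitney_z <- function(x, y, correct = TRUE) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    return(list(U = U, z = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  center <- U - n1 * n2 / 2
  cc <- if (correct) sign(center) * 0.5 else 0
  z <- (center - cc) / sqrt(v)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

# tie-corrected normal-approximation z for the Wilcoxon signed-rank
# statistic (zero differences dropped)
wilcoxon_signed_z <- function(x, y, correct = TRUE) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(V = NA_real_, z = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) {
    return(list(V = V, z = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  center <- V - n * (n + 1) / 4
  cc <- if (correct) sign(center) * 0.5 else 0
  z <- (center - cc) / sqrt(v)
  list(V = V, z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Rank-test battery on a subject parameter table
#'
#' The non-parametric follow-ups to the mixed ANOVA: between-group
#' Mann-Whitney U tests at each stake level and on the high-minus-low
#' difference, and within-group Wilcoxon signed-rank tests of high versus
#' low. All tests are two-sided and use the tie-corrected normal
#' approximation with continuity correction; all-tied data yield a
#' degenerate flag rather than an error.
#'
#' @inheritParams mixed_anova_2x2
#' @return Tibble with columns `test`, `comparison`, `statistic`, `z`,
#'   `p.value`, `n1`, `n2`, `degenerate`.
#' @export
rank_tests <- function(table, parameter = c("omega", "mu")) {
  cols <- parameter_columns(table, parameter)
  groups <- sort(unique(table$group))
  if (length(groups) != 2) {
    stop("exactly two groups are required.", call. = FALSE)
  }
  g1 <- table[table$group == groups[1], ]
  g2 <- table[table$group == groups[2], ]
  rows <- list()
  vals <- list(low = cols[1], high = cols[2])
  for (lvl in names(vals)) {
    mw <- mann_whitney_z(g1[[vals[[lvl]]]], g2[[vals[[lvl]]]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "mann_whitney",
      comparison = paste0(groups[1], " vs ", groups[2], " (", lvl, ")"),
      statistic = mw$U, z = mw$z, p.value = mw$p,
      n1 = nrow(g1), n2 = nrow(g2), degenerate = mw$degenerate)
  }
  mw <- mann_whitney_z(g1[[cols[2]]] - g1[[cols[1]]],
                       g2[[cols[2]]] - g2[[cols[1]]])
  rows[[length(rows) + 1]] <- tibble::tibble(
    test = "mann_whitney",
    comparison = paste0(groups[1], " vs ", groups[2], " (high - low)"),
    statistic = mw$U, z = mw$z, p.value = mw$p,
    n1 = nrow(g1), n2 = nrow(g2), degenerate = mw$degenerate)
  for (g in groups) {
    sub <- table[table$group == g, ]
    wx <- wilcoxon_signed_z(sub[[cols[2]]], sub[[cols[1]]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "wilcoxon_signed_rank",
      comparison = paste0(g, ": high vs low"),
      statistic = wx$V, z = wx$z, p.value = wx$p,
      n1 = nrow(sub), n2 = nrow(sub), degenerate = wx$degenerate)
  }
  dplyr::bind_rows(rows)
}

#' Spearman correlations with Bonferroni correction
#'
#' Rank correlation for each requested variable pair, with family-wise
#' Bonferroni adjustment over the requested family (the family size is
#' always reported next to the adjusted p so the correction is auditable).
#'
#' @param table Tibble holding the variables.
#' @param pairs List of length-2 character vectors naming variable pairs.
#' @return Tibble: `var1`, `var2`, `rho`, `n`, `p.value`, `p.adjusted`
#'   (`min(1, p * family_size)`), `family_size`, `degenerate`.
#' @export
spearman_with_bonferroni <- function(table, pairs) {
  family <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4) {
      stop("need at least 4 complete pairs for ", pr[1], " ~ ", pr[2],
           call. = FALSE)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], rho = NA_real_,
                            n = length(x), p.value = NA_real_,
                            p.adjusted = NA_real_, family_size = family,
                            degenerate = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(var1 = pr[1], var2 = pr[2],
                   rho = unname(ct$estimate), n = length(x),
                   p.value = ct$p.value,
                   p.adjusted = min(1, ct$p.value * family),
                   family_size = family, degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Fisher z comparison of two independent correlations
#'
#' Tests whether two correlations from independent samples differ, via the
#' variance-stabilising transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each above 3.
#' @return Tibble with `z` and `p.value`.
#' @export
#' @examples
#' fisher_z_compare(-0.349, 47, -0.229, 34)
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must lie strictly inside (-1, 1).", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) {
    stop("both sample sizes must exceed 3.", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Split-half reliability of refitted parameters
#'
#' Splits every subject's session into two halves — either the first and
#' second hundred trials (`"first_second"`, preserving temporal order;
#' with an odd trial count the first half receives the extra trial) or the
#' odd- versus even-numbered trials (`"odd_even"`) — refits the model on
#' each half independently, and correlates the half-estimates across
#' subjects for each parameter.
#'
#' @param sessions Session tibble for several subjects.
#' @param scheme `"first_second"` or `"odd_even"`.
#' @param model `"hybrid"` currently.
#' @param n_restarts,seed,config Passed to the fitter.
#' @param priors A `prior_spec`.
#' @param method Correlation method (default `"spearman"`).
#' @return List of class `"split_half_result"` with `correlations` (tibble
#'   parameter/correlation/n) and `half_fits` (per-subject estimates for
#'   both halves).
#' @export
split_half_refit <- function(sessions,
                             scheme = c("first_second", "odd_even"),
                             model = "hybrid", priors = hybrid_priors(),
                             n_restarts = 10, seed = 1,
                             config = task_config(),
                             method = "spearman") {
  scheme <- match.arg(scheme)
  ids <- unique(sessions$subject_id)
  fits <- lapply(ids, function(id) {
    sess <- sessions[sessions$subject_id == id, ]
    halves <- split_session_halves(sess, scheme)
    est <- lapply(seq_along(halves), function(k) {
      h <- halves[[k]]
      f <- fit_hybrid_map(h, priors = priors, n_restarts = n_restarts,
                          seed = seed + 13L * k, config = config)
      f$estimates
    })
    tibble::tibble(subject_id = id,
                   parameter = names(est[[1]]),
                   half1 = as.numeric(est[[1]]),
                   half2 = as.numeric(est[[2]]))
  })
  half_fits <- dplyr::bind_rows(fits)
  correlations <- half_fits |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = suppressWarnings(
        stats::cor(.data$half1, .data$half2, method = method)),
      n = dplyr::n(), .groups = "drop")
  structure(list(scheme = scheme, correlations = correlations,
                 half_fits = half_fits),
            class = "split_half_result")
}

#' Partition one session into two half-sessions
#'
#' `"first_second"` keeps temporal order (the first half receives the
#' extra trial when the count is odd); `"odd_even"` alternates trials by
#' their 1-based trial number. The partition is disjoint and exhaustive,
#' and each half is re-indexed from trial 0 so it is a valid session.
#'
#' @param session Single-subject session tibble.
#' @param scheme `"first_second"` or `"odd_even"`.
#' @return List of two session tibbles.
#' @export
split_session_halves <- function(session,
                                 scheme = c("first_second", "odd_even")) {
  scheme <- match.arg(scheme)
  pos <- seq_len(nrow(session))  # 1-based trial number
  in_first <- if (scheme == "first_second") {
    pos <= ceiling(nrow(session) / 2)
  } else {
    pos %% 2 == 1
  }
  lapply(list(session[in_first, ], session[!in_first, ]), function(h) {
    h$trial <- seq_len(nrow(h)) - 1L
    h
  })
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Refits the generating model to every simulated session and compares the
#' recovered estimates with the stored ground truth: Spearman correlation
#' and mean bias per parameter. A constant true parameter makes the
#' correlation undefined; it is flagged, not an error.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param fits Optional precomputed subject parameter table (one row per
#'   subject, columns named like the truth columns); when `NULL` the
#'   hybrid model is refit with the options below.
#' @param priors,n_restarts,seed,config Fitting options used when `fits`
#'   is `NULL`.
#' @return Tibble: `parameter`, `rho`, `bias`, `n`, `degenerate`.
#' @export
parameter_recovery_report <- function(cohort, fits = NULL,
                                      priors = hybrid_priors(),
                                      n_restarts = 10, seed = 1,
                                      config = task_config()) {
  if (is.null(cohort$truth)) {
    stop("cohort carries no truth records.", call. = FALSE)
  }
  if (is.null(fits)) {
    fits <- fit_cohort(cohort$sessions, priors = priors,
                       n_restarts = n_restarts, seed = seed,
                       config = config)
  }
  truth <- cohort$truth
  params <- intersect(setdiff(names(truth), c("subject_id", "group")),
                      names(fits))
  merged <- dplyr::inner_join(
    truth[, c("subject_id", params)],
    fits[, c("subject_id", params)],
    by = "subject_id", suffix = c("_true", "_hat"))
  rows <- lapply(params, function(p) {
    tr <- merged[[paste0(p, "_true")]]
    hat <- merged[[paste0(p, "_hat")]]
    degenerate <- stats::sd(tr) == 0 || stats::sd(hat) == 0
    tibble::tibble(
      parameter = p,
      rho = if (degenerate) NA_real_ else {
        suppressWarnings(stats::cor(tr, hat, method = "spearman"))
      },
      bias = mean(hat - tr),
      n = length(tr),
      degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}
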