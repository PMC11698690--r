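make_table <- function(w_low, w_high, group) {
  tibble::tibble(subject_id = sprintf("s%02d", seq_along(w_low)),
                 group = group, w_low = w_low, w_high = w_high)
}

# textbook split-plot sums of squares for a balanced 2 x 2 mixed design
hand_mixed_anova <- function(table) {
  y <- rbind(table$w_low, table$w_high)  # stake x subject
  groups <- table$group
  N <- ncol(y)
  grand <- mean(y)
  subj_means <- colMeans(y)
  stake_means <- rowMeans(y)
  group_levels <- unique(groups)
  group_means <- vapply(group_levels,
                        function(g) mean(y[, groups == g]), numeric(1))
  cell_means <- sapply(group_levels, function(g) rowMeans(y[, groups == g]))

  n_per <- vapply(group_levels, function(g) sum(groups == g), numeric(1))
  ss_between_subj <- 2 * sum((subj_means - grand)^2)
  ss_group <- 2 * sum(n_per * (group_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_stake <- N * sum((stake_means - grand)^2)
  ss_int <- sum(rep(n_per, each = 2) *
                  (sweep(sweep(cell_means, 2, group_means), 1,
                         stake_means) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_stake - ss_int
  a <- length(group_levels)
  list(
    F_group = (ss_group / (a - 1)) / (ss_subj_within / (N - a)),
    F_stake = ss_stake / (ss_err / (N - a)),
    F_int = (ss_int / (a - 1)) / (ss_err / (N - a)),
    df2 = N - a
  )
}

test_that("a constructed null yields vanishing group and interaction F", {
  # identical groups, constant stake shift, subject noise repeated across
  # groups so the group and interaction sums of squares are exactly zero
  # while the within error stays positive
  w_low <- c(0.2, 0.4, 0.6, 0.8, 0.2, 0.4, 0.6, 0.8)
  noise <- rep(c(0.01, -0.02, 0.03, -0.01), times = 2)
  tbl <- make_table(w_low, w_low + 0.1 + noise,
                    rep(c("nonuser", "user"), each = 4))
  res <- mixed_anova_2x2(tbl, "omega")
  expect_equal(res$statistic[res$effect == "interaction"], 0,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "group"], 0, tolerance = 1e-10)
  expect_gt(res$statistic[res$effect == "stakes"], 1)  # the +0.1 shift
})

test_that("mixed ANOVA reproduces hand-computed sums of squares", {
  tbl <- make_table(c(0.31, 0.52, 0.44, 0.65),
                    c(0.58, 0.49, 0.77, 0.60),
                    c("nonuser", "nonuser", "user", "user"))
  res <- mixed_anova_2x2(tbl, "omega")
  hand <- hand_mixed_anova(tbl)
  expect_equal(res$statistic[res$effect == "group"], hand$F_group,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "stakes"], hand$F_stake,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "interaction"], hand$F_int,
               tolerance = 1e-8)
  expect_true(all(res$df1 == 1))
  expect_true(all(res$df2 == hand$df2))
})

test_that("with 81 subjects every effect is tested on (1, 79) df", {
  w_low <- withr::with_seed(1, runif(81))
  w_high <- withr::with_seed(2, runif(81))
  tbl <- make_table(w_low, w_high,
                    rep(c("nonuser", "user"), times = c(34, 47)))
  res <- mixed_anova_2x2(tbl, "omega")
  expect_true(all(res$df1 == 1))
  expect_true(all(res$df2 == 79))
})

test_that("ANOVA F values are invariant to group relabeling", {
  tbl <- make_table(withr::with_seed(3, runif(20)),
                    withr::with_seed(4, runif(20)),
                    rep(c("nonuser", "user"), each = 10))
  tbl_swapped <- tbl
  tbl_swapped$group <- ifelse(tbl$group == "user", "nonuser", "user")
  expect_equal(mixed_anova_2x2(tbl, "omega")$statistic,
               mixed_anova_2x2(tbl_swapped, "omega")$statistic,
               tolerance = 1e-10)
})

test_that("completely separated samples give U = 0 and strong z", {
  tbl <- make_table(c(1, 2, 3, 10, 11, 12), c(1, 2, 3, 10, 11, 12) + 1,
                    rep(c("a", "b"), each = 3))
  res <- rank_tests(tbl, c("w_low", "w_high"))
  mw_low <- res[res$comparison == "a vs b (low)", ]
  expect_equal(mw_low$statistic, 0)
  expect_lt(mw_low$z, 0)
})

test_that("rank-test p-values agree with wilcox.test and the exact
          enumeration at small n", {
  x <- c(1.2, 3.4, 0.5, 2.2, 4.1, 2.9)
  y <- c(2.0, 5.1, 4.4, 3.3, 6.2)
  ours <- stakerl:::mann_whitney_z(x, y, correct = TRUE)
  ref <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  exact <- wilcox.test(x, y, exact = TRUE)
  expect_lt(abs(ours$p - exact$p.value), 0.05)

  d1 <- c(0.4, -1.1, 2.0, 0.8, -0.6, 1.4, 0.9)
  d2 <- rep(0, 7)
  ours_w <- stakerl:::wilcoxon_signed_z(d1, d2, correct = TRUE)
  ref_w <- suppressWarnings(
    wilcox.test(d1, d2, paired = TRUE, exact = FALSE, correct = TRUE))
  expect_equal(ours_w$V, unname(ref_w$statistic))
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)
})

test_that("identical samples make the signed-rank test degenerate, not an
          error", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  tbl <- make_table(x, x, rep(c("a", "b"), each = 2))
  res <- rank_tests(tbl, c("w_low", "w_high"))
  wil <- res[res$test == "wilcoxon_signed_rank", ]
  expect_true(all(wil$degenerate))
  expect_true(all(is.na(wil$p.value)))
})

test_that("the Mann-Whitney normal approximation is calibrated under the
          null", {
  n_sim <- 1000
  rejections <- withr::with_seed(42, {
    vapply(seq_len(n_sim), function(i) {
      x <- rnorm(15)
      y <- rnorm(15)
      stakerl:::mann_whitney_z(x, y)$p < 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("Spearman correlations honour monotone transforms and the hand
          formula", {
  x <- c(2, 5, 1, 4, 3, 7)
  tbl <- tibble::tibble(a = x, b = exp(x), c = -x,
                        d = c(2.1, 0.4, 3.3, 1.9, 4.4, 0.2),
                        const = 1)
  res <- spearman_with_bonferroni(tbl, list(c("a", "b"), c("a", "c"),
                                            c("a", "d")))
  expect_equal(res$rho[1], 1)
  expect_equal(res$rho[2], -1)
  # classic 1 - 6 sum(d^2) / (n (n^2 - 1)) with no ties
  dsq <- sum((rank(x) - rank(tbl$d))^2)
  expect_equal(res$rho[3], 1 - 6 * dsq / (6 * 35), tolerance = 1e-10)
  expect_equal(res$family_size, rep(3, 3))
  expect_true(all(res$p.adjusted >= res$p.value, na.rm = TRUE))

  res1 <- spearman_with_bonferroni(tbl, list(c("a", "d")))
  expect_equal(res1$p.adjusted, res1$p.value)

  res_const <- spearman_with_bonferroni(tbl, list(c("a", "const")))
  expect_true(res_const$degenerate)

  expect_error(spearman_with_bonferroni(tbl[1:3, ], list(c("a", "b"))),
               "at least 4")
})

test_that("Fisher z comparison is antisymmetric and null at equality", {
  expect_equal(fisher_z_compare(0.4, 30, 0.4, 50)$z, 0)
  z12 <- fisher_z_compare(0.6, 40, 0.2, 35)$z
  z21 <- fisher_z_compare(0.2, 35, 0.6, 40)$z
  expect_equal(z12, -z21)
  expect_error(fisher_z_compare(1, 30, 0.2, 30), "strictly inside")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 30), "exceed 3")
})

test_that("session halves partition trials disjointly and exhaustively", {
  sess <- random_session(200, seed = 1)
  fs <- split_session_halves(sess, "first_second")
  expect_equal(nrow(fs[[1]]), 100)
  expect_equal(nrow(fs[[2]]), 100)
  expect_equal(fs[[1]]$base_reward, sess$base_reward[1:100])

  odd5 <- split_session_halves(random_session(5, seed = 2),
                               "first_second")
  expect_equal(nrow(odd5[[1]]), 3)  # first half takes the extra trial

  oe <- split_session_halves(sess, "odd_even")
  expect_equal(nrow(oe[[1]]) + nrow(oe[[2]]), 200)
  expect_equal(oe[[1]]$base_reward, sess$base_reward[seq(1, 199, 2)])
  expect_equal(oe[[2]]$base_reward, sess$base_reward[seq(2, 200, 2)])
  # both halves are valid re-indexed sessions
  expect_equal(oe[[1]]$trial, 0:99)
})

test_that("the recovery report compares truth with refits and flags
          degenerate parameters", {
  specs <- list(group_spec("nonuser", 4, list(
    alpha = list(loc = 0.5, scale = 0.15, lower = 0.05, upper = 0.95),
    beta = list(loc = 1, scale = 0.3, lower = 0.3, upper = 2.5),
    lam = list(loc = 0.5, scale = 0, lower = 0.05, upper = 0.95),
    w_low = list(loc = 0.3, scale = 0.15, lower = 0.02, upper = 0.98),
    w_high = list(loc = 0.6, scale = 0.15, lower = 0.02, upper = 0.98),
    pi = list(loc = 0, scale = 0.1, lower = -1, upper = 1),
    rho = list(loc = 0, scale = 0.1, lower = -1, upper = 1)),
    seed = 3))
  cfg <- task_config(n_trials = 15)
  cohort <- generate_cohort(specs, cfg, "hybrid")
  rep <- parameter_recovery_report(cohort, n_restarts = 2, seed = 1,
                                   config = cfg)
  expect_equal(nrow(rep), 7)  # one row per free parameter
  expect_true(rep$degenerate[rep$parameter == "lam"])  # constant truth
  expect_true(all(is.finite(rep$bias)))
  expect_error(
    parameter_recovery_report(list(truth = NULL, sessions = NULL)),
    "truth")
})
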