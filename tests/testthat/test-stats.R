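mini_log <- function() {
  tibble::tibble(
    mouse_id = rep(c("m1", "m2"), each = 4),
    genotype = rep(c("WT", "KO"), each = 4),
    session = rep(c(1L, 1L, 7L, 7L), 2),
    trial_index = rep(1:4, 2),
    distance_cm = rep(c(3.0, 3.0, 3.0, 5.0), 2),
    outcome = c("success", "failure", "success", "success",
                "failure", "failure", "success", "failure"),
    reward = NA, event_sequence = "1>2>3>4", event_times = "0;1;2;3")
}

test_that("success tables partition trial counts exactly", {
  tab <- build_success_table(mini_log())
  expect_s3_class(tab, "success_table")
  cell <- tab[tab$mouse_id == "m1" & tab$session == 1 &
                tab$distance_cm == 3.0, ]
  expect_identical(cell$n_trials, 2L)
  expect_identical(cell$n_success, 1L)
  expect_identical(sum(tab$n_trials), nrow(mini_log()))
  expect_identical(sum(tab$n_success),
                   sum(mini_log()$outcome == "success"))
  dup <- mini_log(); dup$trial_index[2] <- 1L
  expect_error(build_success_table(dup), "duplicate")
  expect_error(build_success_table(mini_log()[0, ]), "empty")
  expect_error(build_success_table(mini_log()[, -5]), "missing columns")
})

test_that("per-mouse totals are conserved on a simulated cohort", {
  logs <- simulate_cohort(n_wt = 0, n_ko = 3, seed = 3)
  tab <- build_success_table(logs)
  raw <- table(logs$mouse_id)
  agg <- tapply(tab$n_trials, tab$mouse_id, sum)
  expect_equal(as.numeric(agg[names(raw)]), as.numeric(raw))
})

test_that("block rates pool counts and improvements subtract blocks", {
  # m1 at 3.0 cm: block1 1/2 = 50%, block2 1/1 = 100%; whisker cell only in
  # block2 -> missing in block1, excluded from the class average
  expect_warning(bs <- block_rates(build_success_table(mini_log())),
                 "no trials")
  r <- bs$rates
  m1 <- r[r$mouse_id == "m1" & r$distance_cm == 3.0, ]
  expect_equal(sort(m1$rate), c(50, 100))
  imp <- bs$improvement
  expect_equal(imp$improvement[imp$mouse_id == "m1" & imp$class == "nose"], 50)
  # whisker class has no complete distance for either mouse
  expect_false(any(imp$class == "whisker"))
})

test_that("hand-built two-mouse table reproduces hand-computed rates", {
  tab <- tibble::tibble(
    mouse_id = rep(c("a", "b"), each = 4),
    genotype = "WT",
    session = rep(c(2L, 5L, 8L, 11L), 2),
    distance_cm = 3.5,
    n_trials = c(4L, 6L, 5L, 5L, 10L, 10L, 8L, 2L),
    n_success = c(2L, 3L, 5L, 4L, 1L, 3L, 4L, 2L))
  tab <- structure(tab, class = c("success_table", class(tab)))
  bs <- suppressWarnings(block_rates(tab))
  r <- bs$rates
  # a: block1 pooled 5/10 = 50, block2 9/10 = 90
  expect_equal(r$rate[r$mouse_id == "a" & r$block == "block1" &
                        r$distance_cm == 3.5], 50)
  expect_equal(r$rate[r$mouse_id == "a" & r$block == "block2" &
                        r$distance_cm == 3.5], 90)
  # b: block1 4/20 = 20, block2 6/10 = 60
  imp <- bs$improvement
  expect_equal(imp$improvement[imp$mouse_id == "b"], 40)
  # per-session averaging differs when session sizes differ
  bs2 <- suppressWarnings(block_rates(tab, pool = "per_session"))
  r2 <- bs2$rates
  expect_equal(r2$rate[r2$mouse_id == "b" & r2$block == "block1" &
                         r2$distance_cm == 3.5], mean(c(10, 30)))
})

test_that("improvement is invariant to session order within blocks", {
  logs <- simulate_cohort(n_wt = 2, n_ko = 0, seed = 29)
  tab <- build_success_table(logs)
  bs1 <- suppressWarnings(block_rates(tab))
  # permute session labels within each block
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L, 9L, 7L, 8L, 12L, 10L, 11L)
  tab2 <- tab
  tab2$session <- perm[tab2$session]
  bs2 <- suppressWarnings(block_rates(
    structure(tab2, class = class(tab))))
  expect_equal(dplyr::arrange(bs1$improvement, mouse_id, class),
               dplyr::arrange(bs2$improvement, mouse_id, class))
})

test_that("RM-ANOVA block effect matches a from-scratch sums-of-squares oracle", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(4:8, 1); k <- sample(2:4, 1)
    # integer percentages so counts-of-100 reproduce the rates exactly
    y <- array(sample(20:90, n * k * 2, replace = TRUE), c(n, k, 2))
    tab <- table_from_rates(y, distances = c(5.0, 5.5, 6.0, 6.5)[1:k])
    bs <- block_rates(tab, classes = list(whisker = c(5.0, 5.5, 6.0, 6.5)[1:k]))
    got <- rm_anova_block_by_distance(bs, "WT", "whisker")
    ref <- brute_rm_anova_block(y)
    expect_equal(got$F, ref$F, tolerance = 1e-8)
    expect_equal(got$p, ref$p, tolerance = 1e-8)
    expect_equal(c(got$df1, got$df2), c(ref$df1, ref$df2))
  }
})

test_that("RM-ANOVA degrees of freedom follow the mouse-by-distance convention", {
  set.seed(41)
  y <- array(sample(20:90, 6 * 3 * 2, replace = TRUE), c(6, 3, 2))
  tab <- table_from_rates(y, distances = c(5.0, 5.5, 6.0))
  bs <- suppressWarnings(block_rates(tab))
  got <- rm_anova_block_by_distance(bs, "WT", "whisker")
  expect_equal(c(got$df1, got$df2), c(1, 15))  # 3 * (6 - 1)
  expect_identical(c(got$n_mice, got$n_distances), c(6L, 3L))
})

test_that("a block-invariant table gives F = 0, p = 1", {
  y <- array(rep(runif(12, 30, 80), 2), c(4, 3, 2))  # identical blocks
  tab <- table_from_rates(y, distances = c(5.0, 5.5, 6.0))
  bs <- suppressWarnings(block_rates(tab))
  got <- rm_anova_block_by_distance(bs, "WT", "whisker")
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)
})

test_that("subjects missing a block are dropped with a diagnostic", {
  y <- array(runif(4 * 2 * 2, 20, 90), c(4, 2, 2))
  tab <- table_from_rates(y, distances = c(5.0, 5.5))
  # remove one mouse's 5.0 cm cell in block 2
  tab <- tab[!(tab$mouse_id == "WT01" & tab$distance_cm == 5.0 &
                 tab$session == 7L), ]
  tab <- structure(tab, class = c("success_table", class(tab)))
  expect_warning(bs <- block_rates(tab), "no trials")
  expect_warning(got <- rm_anova_block_by_distance(bs, "WT", "whisker"),
                 "WT01@5.0")
  # 7 remaining subjects, 14 observations: within stratum 7 df, minus
  # block (1) and block:distance (1) leaves 5 residual df
  expect_equal(got$df2, 5)
  expect_error(rm_anova_block_by_distance(bs, "KO", "whisker"), "no data")
})

test_that("improvement comparison behaves at the null and separation limits", {
  mk_summary <- function(wt, ko) {
    imp <- tibble::tibble(
      mouse_id = c(sprintf("w%d", seq_along(wt)), sprintf("k%d", seq_along(ko))),
      genotype = rep(c("WT", "KO"), c(length(wt), length(ko))),
      class = "whisker", improvement = c(wt, ko),
      n_distances = 3L)
    structure(list(rates = NULL, improvement = imp,
                   blocks = default_blocks(), classes = default_classes(),
                   pool = "pooled"),
              class = "block_summary")
  }
  v <- c(5, 10, 15, 20)
  same <- compare_improvement(mk_summary(v, v), "whisker")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  # WT all +15, KO all 0 with shrinking jitter: p decreases towards 0
  set.seed(43)
  jit1 <- rnorm(4); jit2 <- rnorm(4)
  p_wide <- compare_improvement(
    mk_summary(15 + 8 * jit1, 0 + 8 * jit2), "whisker")$p
  p_tight <- compare_improvement(
    mk_summary(15 + 0.5 * jit1, 0 + 0.5 * jit2), "whisker")$p
  expect_lt(p_tight, p_wide)
  expect_lt(p_tight, 1e-6)
  expect_error(compare_improvement(mk_summary(v, 3), "whisker"), ">= 2 mice")
})

test_that("cohort totals and SEMs follow the accounting identities", {
  tab <- build_success_table(tibble::tibble(
    mouse_id = rep(c("m1", "m2"), c(10, 10)),
    genotype = "KO", session = 1L, trial_index = rep(1:10, 2),
    distance_cm = 3.0,
    outcome = c(rep("success", 7), rep("failure", 3), rep("success", 10)),
    reward = NA, event_sequence = "1>2>3>4", event_times = "0"))
  tot <- cohort_totals(tab)
  expect_identical(tot$total_trials, 20L)
  expect_identical(tot$total_success, 17L)
  expect_equal(tot$mean_success, 8.5)
  expect_equal(tot$sem_success, sd(c(7, 10)) / sqrt(2))
  # single mouse: SEM not available
  one <- build_success_table(tibble::tibble(
    mouse_id = "m1", genotype = "WT", session = 1L, trial_index = 1:10,
    distance_cm = 3.0, outcome = rep(c("success", "failure"), c(7, 3)),
    reward = NA, event_sequence = "1>2>3>4", event_times = "0"))
  t1 <- cohort_totals(one)
  expect_identical(t1$total_trials, 10L)
  expect_identical(t1$total_success, 7L)
  expect_true(is.na(t1$sem_success))
  # simulated cohort: totals equal raw row counts
  logs <- simulate_cohort(n_wt = 2, n_ko = 2, seed = 47)
  tt <- cohort_totals(build_success_table(logs))
  expect_identical(sum(tt$total_trials), nrow(logs))
})

test_that("serialise -> rebuild leaves block summaries identical", {
  logs <- simulate_cohort(n_wt = 2, n_ko = 2, seed = 53)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(logs, path)
  back <- read_trial_log(path)
  expect_true(validate_trial_log(back))
  bs1 <- suppressWarnings(block_rates(build_success_table(logs)))
  bs2 <- suppressWarnings(block_rates(build_success_table(back)))
  expect_equal(bs1$rates, bs2$rates)
  expect_equal(bs1$improvement, bs2$improvement)
})

test_that("the summary plot builds from a block summary", {
  logs <- simulate_cohort(n_wt = 2, n_ko = 2, seed = 59)
  bs <- suppressWarnings(block_rates(build_success_table(logs)))
  p <- plot_block_rates(bs)
  expect_s3_class(p, "ggplot")
  expect_gte(length(p$layers), 2)
})
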