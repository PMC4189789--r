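# Session-block success statistics: success tables, block rates and
# improvements, repeated-measures ANOVA and the genotype improvement test.

#' Aggregate a trial log into a success table
#'
#' Counts trials and successes per (mouse, session, distance). Totals per
#' mouse equal the raw log row counts by construction; duplicated
#' (mouse, session, trial_index) rows indicate a corrupt log and are
#' rejected.
#'
#' @param trials tidy trial log: columns `mouse_id`, `genotype`, `session`,
#'   `trial_index`, `distance_cm`, `outcome` (see [experiment_to_trials()]
#'   / [read_trial_log()]).
#' @return a `success_table` tibble: `mouse_id`, `genotype`, `session`,
#'   `distance_cm`, `n_trials`, `n_success`.
#' @export
build_success_table <- function(trials) {
  need <- c("mouse_id", "genotype", "session", "trial_index",
            "distance_cm", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial log missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(trials) == 0L) stop("empty trial log")
  dup <- duplicated(trials[c("mouse_id", "session", "trial_index")])
  if (any(dup)) {
    stop("duplicate (mouse, session, trial_index) rows in log, e.g. ",
         with(trials[dup, ][1, ],
              sprintf("%s session %d trial %d", mouse_id, session,
                      trial_index)))
  }
  if (!all(trials$outcome %in% c("success", "failure"))) {
    stop("outcome must be 'success' or 'failure'")
  }
  tab <- trials |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$session,
                    .data$distance_cm) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_success = sum(.data$outcome == "success"),
                     .groups = "drop")
  structure(tab, class = c("success_table", class(tab)))
}

#' Default session blocks and distance classes
#'
#' The learning contrast compares the first six sessions with the
#' subsequent six; distances analysed are restricted to 3.0-6.0 cm, split
#' into the nose class (target reachable by nose, up to and including
#' 4.5 cm by default) and the whisker class (5.0, 5.5, 6.0 cm).
#'
#' @param nose_includes_4.5 if `FALSE`, 4.5 cm is dropped from the nose
#'   class (the strict reading of "nose < 4.5 cm").
#' @name block_defaults
#' @export
default_blocks <- function() list(block1 = 1:6, block2 = 7:12)

#' @rdname block_defaults
#' @export
default_classes <- function(nose_includes_4.5 = TRUE) {
  nose <- c(3.0, 3.5, 4.0, if (nose_includes_4.5) 4.5)
  list(nose = nose, whisker = c(5.0, 5.5, 6.0))
}

#' Block success rates and per-class improvements
#'
#' Computes, for each mouse, distance and session block, the percent of
#' successful crossings, and from those the per-mouse improvement (late
#' block minus early block, percentage points) averaged over each distance
#' class. By default trials are pooled across the block's sessions before
#' forming the rate, which is robust to sessions where the adaptive
#' algorithm offered a distance only a handful of times;
#' `pool = "per_session"` averages per-session rates instead. A
#' (mouse, distance, block) cell with no trials is marked missing, warned
#' about, and excluded from that mouse's class average.
#'
#' @param table a [build_success_table()] result.
#' @param blocks named list of session-index vectors partitioning the
#'   sessions.
#' @param classes named list of distance vectors (cm); distances outside
#'   their union are not analysed.
#' @param pool `"pooled"` or `"per_session"`.
#' @return a `block_summary`: list with `rates` (tibble: `mouse_id`,
#'   `genotype`, `distance_cm`, `class`, `block`, `rate`, `n_trials`) and
#'   `improvement` (tibble: `mouse_id`, `genotype`, `class`,
#'   `improvement`, `n_distances`).
#' @export
block_rates <- function(table,
                        blocks = default_blocks(),
                        classes = default_classes(),
                        pool = c("pooled", "per_session")) {
  stopifnot(inherits(table, "success_table"))
  pool <- match.arg(pool)
  if (length(blocks) < 2L) stop("need at least two session blocks")
  if (anyDuplicated(unlist(blocks))) stop("blocks must not overlap")
  if (anyDuplicated(unlist(classes))) stop("classes must not overlap")

  block_of <- function(s) {
    idx <- vapply(blocks, function(b) s %in% b, logical(1))
    if (!any(idx)) NA_character_ else names(blocks)[which(idx)[1]]
  }
  class_of <- function(d) {
    idx <- vapply(classes, function(v) any(abs(v - d) < 1e-9), logical(1))
    if (!any(idx)) NA_character_ else names(classes)[which(idx)[1]]
  }

  dat <- table |>
    dplyr::mutate(
      block = vapply(.data$session, block_of, character(1)),
      class = vapply(.data$distance_cm, class_of, character(1))) |>
    dplyr::filter(!is.na(.data$block), !is.na(.data$class))
  if (nrow(dat) == 0L) stop("no analysable trials in table")

  rates <- if (pool == "pooled") {
    dat |>
      dplyr::group_by(.data$mouse_id, .data$genotype, .data$distance_cm,
                      .data$class, .data$block) |>
      dplyr::summarise(rate = 100 * sum(.data$n_success) / sum(.data$n_trials),
                       n_trials = sum(.data$n_trials), .groups = "drop")
  } else {
    dat |>
      dplyr::group_by(.data$mouse_id, .data$genotype, .data$distance_cm,
                      .data$class, .data$block, .data$session) |>
      dplyr::summarise(srate = 100 * sum(.data$n_success) / sum(.data$n_trials),
                       n = sum(.data$n_trials), .groups = "drop_last") |>
      dplyr::summarise(rate = mean(.data$srate), n_trials = sum(.data$n),
                       .groups = "drop")
  }

  # complete the (mouse, analysed distance, block) lattice; absent cells
  # are missing, not zero
  full <- rates |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("mouse_id"), !!rlang::sym("genotype")),
      distance_cm = sort(unlist(classes, use.names = FALSE)),
      block = names(blocks),
      fill = list(n_trials = 0L)) |>
    dplyr::mutate(class = vapply(.data$distance_cm, class_of, character(1)))
  n_missing <- sum(is.na(full$rate))
  if (n_missing > 0) {
    warning(sprintf(
      "%d (mouse, distance, block) cells have no trials; excluded from class averages",
      n_missing), call. = FALSE)
  }

  bn <- names(blocks)
  improvement <- full |>
    dplyr::select(-"n_trials") |>
    tidyr::pivot_wider(names_from = "block", values_from = "rate") |>
    dplyr::filter(!is.na(.data[[bn[1]]]), !is.na(.data[[bn[2]]])) |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$class) |>
    dplyr::summarise(
      improvement = mean(.data[[bn[2]]] - .data[[bn[1]]]),
      n_distances = dplyr::n(), .groups = "drop")

  structure(list(rates = full, improvement = improvement,
                 blocks = blocks, classes = classes, pool = pool),
            class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat(sprintf("<block_summary> %d mice, %s pooling; classes: %s\n",
              dplyr::n_distinct(x$rates$mouse_id), x$pool,
              paste(names(x$classes), collapse = ", ")))
  print(x$improvement)
  invisible(x)
}

#' Repeated-measures ANOVA of block by distance within a genotype
#'
#' Tests whether success rates differ between session blocks across the
#' distances of one class, within one genotype. Each mouse-by-distance
#' cell is treated as a matched subject measured in both blocks, so the
#' block main effect is tested on `F(1, k*(n-1))` for `n` mice and `k`
#' distances -- e.g. `F(1, 15)` for 6 mice over 3 distances. With only two
#' block levels the within-subject factor has one degree of freedom and
#' needs no sphericity correction. Mouse-by-distance subjects missing a
#' block (after the exclusion rules of [block_rates()]) are dropped with a
#' diagnostic.
#'
#' @param summary a [block_rates()] result.
#' @param genotype `"WT"` or `"KO"`.
#' @param class distance-class name present in the summary.
#' @return one-row tibble: `genotype`, `class`, `effect = "block"`,
#'   `F`, `df1`, `df2`, `p`, `n_mice`, `n_distances`.
#' @export
rm_anova_block_by_distance <- function(summary, genotype, class) {
  stopifnot(inherits(summary, "block_summary"))
  bn <- names(summary$blocks)
  d <- summary$rates |>
    dplyr::filter(.data$genotype == !!genotype, .data$class == !!class,
                  .data$block %in% bn)
  if (nrow(d) == 0L) stop("no data for ", genotype, " / ", class)

  # drop subjects (mouse x distance) without both blocks
  wide <- d |>
    dplyr::select("mouse_id", "distance_cm", "block", "rate") |>
    tidyr::pivot_wider(names_from = "block", values_from = "rate")
  bad <- !complete.cases(wide[bn])
  if (any(bad)) {
    warning(sprintf(
      "dropping %d mouse x distance subjects missing a block: %s",
      sum(bad),
      paste(sprintf("%s@%.1f", wide$mouse_id[bad],
                    wide$distance_cm[bad]), collapse = ", ")),
      call. = FALSE)
    keep <- wide[!bad, c("mouse_id", "distance_cm")]
    d <- dplyr::semi_join(d, keep, by = c("mouse_id", "distance_cm"))
  }
  n_mice <- dplyr::n_distinct(d$mouse_id)
  n_dist <- dplyr::n_distinct(d$distance_cm)
  if (n_mice < 2L) stop("need >= 2 mice with complete data")
  if (n_dist < 2L) stop("need >= 2 distances in class ", class)

  d$block_f <- factor(d$block, levels = bn)
  d$dist_f <- factor(d$distance_cm)
  d$subj <- interaction(d$mouse_id, d$dist_f, drop = TRUE)
  fit <- aov(rate ~ block_f * dist_f + Error(subj), data = d)
  strata <- summary(fit)
  within <- strata[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  i <- match("block_f", rn)
  if (is.na(i)) stop("block effect not estimable (no within-subject variance)")
  f <- within[i, "F value"]; p <- within[i, "Pr(>F)"]
  # a block-invariant table has zero block SS up to floating-point dust;
  # report F = 0, p = 1 rather than a ratio of rounding errors
  ss_scale <- sum((d$rate - mean(d$rate))^2)
  if (!is.finite(f) || within[i, "Sum Sq"] <= 1e-10 * ss_scale) {
    f <- 0; p <- 1
  }
  tibble::tibble(genotype = genotype, class = class, effect = "block",
                 F = f, df1 = within[i, "Df"],
                 df2 = within[match("Residuals", rn), "Df"],
                 p = p, n_mice = n_mice, n_distances = n_dist)
}

#' Between-genotype comparison of learning improvement
#'
#' Two-sample, two-tailed Student t-test on the per-mouse class
#' improvements (WT versus KO) from [block_rates()].
#'
#' @param summary a [block_rates()] result.
#' @param class distance-class name.
#' @param var_equal pooled-variance t-test (default), as in classical
#'   two-tailed t comparisons; `FALSE` gives Welch.
#' @return one-row tibble: `class`, `t`, `df`, `p`, `mean_wt`, `mean_ko`,
#'   `mean_diff` (WT minus KO).
#' @export
compare_improvement <- function(summary, class, var_equal = TRUE) {
  stopifnot(inherits(summary, "block_summary"))
  d <- summary$improvement |>
    dplyr::filter(.data$class == !!class)
  wt <- d$improvement[d$genotype == "WT"]
  ko <- d$improvement[d$genotype == "KO"]
  if (length(wt) < 2L || length(ko) < 2L) {
    stop("need >= 2 mice per genotype (WT: ", length(wt),
         ", KO: ", length(ko), ")")
  }
  tt <- t.test(wt, ko, var.equal = var_equal)
  tibble::tibble(class = class, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_wt = mean(wt), mean_ko = mean(ko),
                 mean_diff = mean(wt) - mean(ko))
}

#' Per-genotype trial and success totals
#'
#' Total trials and successful crossings per genotype with the per-mouse
#' mean and standard error, the mobility/motivation control comparison.
#'
#' @param table a [build_success_table()] result.
#' @return tibble: `genotype`, `n_mice`, `total_trials`, `total_success`,
#'   `mean_trials`, `sem_trials`, `mean_success`, `sem_success` (SEMs are
#'   `NA` for a single mouse).
#' @export
cohort_totals <- function(table) {
  stopifnot(inherits(table, "success_table"))
  per_mouse <- table |>
    dplyr::group_by(.data$genotype, .data$mouse_id) |>
    dplyr::summarise(trials = sum(.data$n_trials),
                     success = sum(.data$n_success), .groups = "drop")
  sem <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  per_mouse |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n_mice = dplyr::n(),
                     total_trials = sum(.data$trials),
                     total_success = sum(.data$success),
                     mean_trials = mean(.data$trials),
                     sem_trials = sem(.data$trials),
                     mean_success = mean(.data$success),
                     sem_success = sem(.data$success), .groups = "drop")
}
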