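# Closed-loop gap-cross session logic: adaptive distance selection,
# sensor-event classification and the exploration/adjustment loop.

#' Gap-cross assay configuration
#'
#' Geometry and schedule of the closed-loop assay: the 0.5 cm distance
#' grid from 3.0 to 7.0 cm, the adaptive window (1.0 cm below to 1.5 cm
#' above the session's maximum successful crossing), the 20-success /
#' 20-minute session rule, and the 12-session experiment (2 per day). The
#' nose/whisker boundary (`nose_max`) classifies distances for the
#' learning model and statistics.
#'
#' @param d_min,d_max grid limits, cm.
#' @param step grid increment, cm.
#' @param lower_offset,upper_offset adaptive-window half-widths below/above
#'   the running maximum, cm; must be multiples of `step`.
#' @param first_trial_distance every session opens here, cm.
#' @param success_quota successes that end a session.
#' @param session_time_limit s; session ends when the simulated clock
#'   reaches it.
#' @param sessions_total sessions per experiment.
#' @param sessions_per_day schedule metadata.
#' @param nose_max largest nose-class distance, cm.
#' @param whisker_min smallest whisker-class distance, cm.
#' @return object of class `gapcross_config`.
#' @export
gapcross_config <- function(d_min = 3.0, d_max = 7.0, step = 0.5,
                            lower_offset = 1.0, upper_offset = 1.5,
                            first_trial_distance = 3.0,
                            success_quota = 20L,
                            session_time_limit = 1200,
                            sessions_total = 12L,
                            sessions_per_day = 2L,
                            nose_max = 4.5, whisker_min = 5.0) {
  cfg <- list(d_min = d_min, d_max = d_max, step = step,
              lower_offset = lower_offset, upper_offset = upper_offset,
              first_trial_distance = first_trial_distance,
              success_quota = as.integer(success_quota),
              session_time_limit = session_time_limit,
              sessions_total = as.integer(sessions_total),
              sessions_per_day = as.integer(sessions_per_day),
              nose_max = nose_max, whisker_min = whisker_min)
  su <- cm_to_units(step)
  if (su <= 0L) stop("step must be > 0")
  for (nm in c("lower_offset", "upper_offset")) {
    if (cm_to_units(cfg[[nm]]) %% su != 0L) {
      stop(nm, " must be a multiple of step")
    }
  }
  if (cfg$success_quota < 1L) stop("success_quota must be >= 1")
  if (cfg$sessions_total < 1L) stop("sessions_total must be >= 1")
  if (cfg$session_time_limit <= 0) stop("session_time_limit must be > 0")
  if ((cm_to_units(d_max) - cm_to_units(d_min)) %% su != 0L) {
    stop("d_max - d_min must be a multiple of step")
  }
  cfg <- structure(cfg, class = "gapcross_config")
  if (!is_on_grid(first_trial_distance, cfg)) {
    stop("first_trial_distance must lie on the distance grid")
  }
  cfg
}

#' Candidate distances of the adaptive algorithm
#'
#' The next gap distance is drawn from the 0.5 cm grid spanning 1.0 cm
#' below to 1.5 cm above the maximum distance successfully crossed so far
#' in the session, clamped to the 3.0-7.0 cm track limits. Before the
#' first success of a session the maximum is undefined and the opening
#' distance (3.0 cm) is used in its place.
#'
#' @param max_crossed maximum distance (cm) successfully crossed this
#'   session, or `NULL`/`NA` if there has been no success yet.
#' @param config a [gapcross_config()].
#' @return ascending numeric vector of candidate distances, cm.
#' @export
candidate_distances <- function(max_crossed = NULL,
                                config = gapcross_config()) {
  if (is.null(max_crossed) || length(max_crossed) == 0L ||
      is.na(max_crossed)) {
    max_crossed <- config$first_trial_distance
  }
  if (!is_on_grid(max_crossed, config)) {
    stop(sprintf("max_crossed %.2f cm is off the %.1f cm grid [%.1f, %.1f]",
                 max_crossed, config$step, config$d_min, config$d_max))
  }
  m <- cm_to_units(max_crossed)
  lo <- max(cm_to_units(config$d_min), m - cm_to_units(config$lower_offset))
  hi <- min(cm_to_units(config$d_max), m + cm_to_units(config$upper_offset))
  units_to_cm(seq.int(lo, hi, by = cm_to_units(config$step)))
}

#' Draw the next gap distance
#'
#' Uniform draw over [candidate_distances()]. Uses the current RNG stream.
#'
#' @inheritParams candidate_distances
#' @param n number of draws.
#' @return numeric vector of length `n`, cm.
#' @export
next_gap_distance <- function(max_crossed = NULL,
                              config = gapcross_config(), n = 1L) {
  cand <- candidate_distances(max_crossed, config)
  cand[sample.int(length(cand), n, replace = TRUE)]
}

#' Classify a sensor-event sequence into a trial outcome
#'
#' Sensors: 1 = home-platform rear, 2 = home edge, 3 = target edge,
#' 4 = target rear. A trial is a success if sensor 4 is reached (the mouse
#' crossed and triggered the rear of the target platform); a failure if
#' the mouse reached the home edge (optionally touching the target edge)
#' and then returned to the home rear without reaching sensor 4; anything
#' else is `"incomplete"` -- the sequence does not yet constitute a trial.
#'
#' @param events a data frame with columns `sensor_id` and `timestamp`, or
#'   a bare integer vector of sensor ids (timestamps then taken as their
#'   order of arrival).
#' @return `"success"`, `"failure"` or `"incomplete"`.
#' @export
classify_trial <- function(events) {
  if (is.data.frame(events)) {
    ids <- events$sensor_id
    ts <- events$timestamp
  } else {
    ids <- events
    ts <- seq_along(events)
  }
  if (length(ids) == 0L) stop("empty event sequence")
  if (!all(ids %in% 1:4)) {
    stop("unknown sensor id: ", paste(setdiff(ids, 1:4), collapse = ", "))
  }
  if (is.unsorted(ts)) stop("event timestamps must be non-decreasing")
  if (!(ids[1] %in% c(1L, 2L))) {
    stop("trial must begin on the home platform (sensor 1 or 2)")
  }
  if (4L %in% ids) return("success")
  if (2L %in% ids && ids[length(ids)] == 1L) return("failure")
  "incomplete"
}

#' Run one closed-loop session
#'
#' Alternates the two machine states: exploration (one trial is collected
#' at the current gap distance) and adjustment (the next distance is drawn
#' by the adaptive algorithm from the running maximum successful
#' crossing). The session opens at `first_trial_distance`, ends after
#' `success_quota` successes (`termination = "quota"`) or when the
#' simulated clock reaches `session_time_limit` (`"timeout"`); a trial in
#' progress at the limit completes and is kept. Each trial charges the
#' clock its sensor-event span plus a drawn inter-trial interval. Draws
#' come from the current RNG stream.
#'
#' @param agent an [agent_config()].
#' @param session_index 1-based session number (drives agent learning).
#' @param config a [gapcross_config()].
#' @return object of class `gapcross_session`: list with `trials` (tibble:
#'   `trial_index`, `distance_cm`, `outcome`, `reward`, `t_start`,
#'   `events` list-column), `termination`, `max_distance_crossed`
#'   (`NA` if no success), `n_success`, `session_index`.
#' @export
run_session <- function(agent, session_index = 1L,
                        config = gapcross_config()) {
  stopifnot(inherits(agent, "agent_config"))
  quota <- config$success_quota
  limit <- config$session_time_limit

  # Hot loop: the agent's success probability depends only on (distance,
  # session) and the candidate window only on the running maximum, so both
  # are tabulated over the grid up front. The per-trial draws consume the
  # RNG stream exactly as simulate_agent_response() would (one uniform for
  # the outcome, a second one on failures for the retreat shape), which a
  # regression test pins down.
  su <- cm_to_units(config$step)
  grid_u <- seq.int(cm_to_units(config$d_min), cm_to_units(config$d_max),
                    by = su)
  grid_cm <- units_to_cm(grid_u)
  p_by_u <- agent_success_prob(agent, grid_cm, session_index, config)
  cand_by_u <- lapply(grid_cm, function(m)
    cm_to_units(candidate_distances(m, config)))
  uidx <- function(u) (u - grid_u[1]) %/% su + 1L

  ct <- agent$crossing_time
  tmpl <- list(
    success = new_sensor_events(c(1L, 2L, 3L, 4L), c(0, 0.3, 0.7, 1) * ct),
    retreat = new_sensor_events(c(1L, 2L, 1L), c(0, 0.4, 1) * ct),
    touch = new_sensor_events(c(1L, 2L, 3L, 2L, 1L),
                              c(0, 0.25, 0.5, 0.75, 1) * ct))
  stopifnot(classify_trial(tmpl$success) == "success",
            classify_trial(tmpl$retreat) == "failure",
            classify_trial(tmpl$touch) == "failure")

  dist_u <- integer(0); success <- logical(0)
  t_start <- numeric(0); events <- list()
  clock <- 0; n_succ <- 0L; max_u <- NA_integer_
  cur_u <- cm_to_units(config$first_trial_distance)
  termination <- "timeout"

  repeat {
    succ <- runif(1) < p_by_u[uidx(cur_u)]
    ev <- if (succ) tmpl$success
          else if (runif(1) < 0.5) tmpl$retreat else tmpl$touch
    dist_u <- c(dist_u, cur_u)
    success <- c(success, succ)
    t_start <- c(t_start, clock)
    events[[length(events) + 1L]] <- ev
    clock <- clock + ct + draw_iti(agent)
    if (succ) {
      n_succ <- n_succ + 1L
      if (is.na(max_u) || cur_u > max_u) max_u <- cur_u
    }
    if (n_succ >= quota) { termination <- "quota"; break }
    if (clock >= limit) { termination <- "timeout"; break }
    key_u <- if (is.na(max_u)) cm_to_units(config$first_trial_distance)
             else max_u
    cand <- cand_by_u[[uidx(key_u)]]
    cur_u <- cand[sample.int(length(cand), 1L)]
  }

  outcome <- ifelse(success, "success", "failure")
  trials <- tibble::new_tibble(list(
    trial_index = seq_along(dist_u),
    distance_cm = units_to_cm(dist_u),
    outcome = outcome,
    reward = success,
    t_start = t_start,
    events = events), nrow = length(dist_u))
  structure(list(trials = trials, termination = termination,
                 max_distance_crossed =
                   if (is.na(max_u)) NA_real_ else units_to_cm(max_u),
                 n_success = n_succ, session_index = session_index),
            class = "gapcross_session")
}

#' @export
print.gapcross_session <- function(x, ...) {
  cat(sprintf(
    "<gapcross_session> %d trials, %d successes, termination: %s, max crossed: %s cm\n",
    nrow(x$trials), x$n_success, x$termination,
    format(x$max_distance_crossed)))
  invisible(x)
}

#' Run a full gap-cross experiment for one mouse
#'
#' Runs `sessions_total` consecutive sessions; the session index is passed
#' to the agent so session-linear learning accrues across the experiment,
#' and the adaptive algorithm's maximum crossed distance resets at each
#' session boundary.
#'
#' @param agent an [agent_config()].
#' @param mouse_id label recorded in the output.
#' @param config a [gapcross_config()].
#' @param seed optional integer; seeds a private RNG stream so identical
#'   seeds give bit-identical records.
#' @return object of class `experiment_record`: list with `mouse_id`,
#'   `genotype`, `sessions` (list of [gapcross_session][run_session]).
#' @export
run_experiment <- function(agent, mouse_id = "m1",
                           config = gapcross_config(), seed = NULL) {
  sessions <- with_local_seed(seed, lapply(
    seq_len(config$sessions_total),
    function(i) run_session(agent, i, config)))
  structure(list(mouse_id = mouse_id, genotype = agent$genotype,
                 sessions = sessions, config = config),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  ns <- vapply(x$sessions, function(s) s$n_success, integer(1))
  nt <- vapply(x$sessions, function(s) nrow(s$trials), integer(1))
  cat(sprintf("<experiment_record> mouse %s (%s): %d sessions, %d trials, %d successes\n",
              x$mouse_id, x$genotype, length(x$sessions), sum(nt), sum(ns)))
  invisible(x)
}

#' Flatten an experiment record to a tidy trial log
#'
#' One row per trial with the event sequence serialised as
#' `"1>2>3>4"` and timestamps as a `;`-separated string, the on-disk
#' format of [write_trial_log()].
#'
#' @param record an [experiment_record][run_experiment], or a list of them.
#' @return tibble with columns `mouse_id`, `genotype`, `session`,
#'   `trial_index`, `distance_cm`, `outcome`, `reward`,
#'   `event_sequence`, `event_times`.
#' @export
experiment_to_trials <- function(record) {
  if (inherits(record, "experiment_record")) record <- list(record)
  rows <- lapply(record, function(rec) {
    per_session <- lapply(rec$sessions, function(s) {
      tr <- s$trials
      n <- nrow(tr)
      tibble::new_tibble(list(
        mouse_id = rep(rec$mouse_id, n), genotype = rep(rec$genotype, n),
        session = rep(s$session_index, n),
        trial_index = tr$trial_index,
        distance_cm = tr$distance_cm,
        outcome = tr$outcome, reward = tr$reward,
        event_sequence = vapply(tr$events, function(e)
          paste(e$sensor_id, collapse = ">"), character(1)),
        event_times = vapply(tr$events, function(e)
          paste(signif(e$timestamp, 6), collapse = ";"), character(1))),
        nrow = n)
    })
    dplyr::bind_rows(per_session)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a two-genotype cohort
#'
#' Runs full experiments for `n_wt` wild-type and `n_ko` knockout mice and
#' returns the pooled tidy trial log. Default agents encode the pattern
#' the assay was designed to detect: both genotypes learn at nose
#' distances, only WT learns at whisker distances.
#'
#' @param n_wt,n_ko cohort sizes.
#' @param wt_agent,ko_agent [agent_config()]s.
#' @param config a [gapcross_config()].
#' @param seed optional integer seed for the whole cohort.
#' @return tidy trial tibble (see [experiment_to_trials()]).
#' @export
simulate_cohort <- function(n_wt = 6, n_ko = 9,
                            wt_agent = agent_config("WT"),
                            ko_agent = agent_config("KO"),
                            config = gapcross_config(), seed = NULL) {
  with_local_seed(seed, {
    recs <- c(
      lapply(seq_len(n_wt), function(i)
        run_experiment(wt_agent, sprintf("WT%02d", i), config)),
      lapply(seq_len(n_ko), function(i)
        run_experiment(ko_agent, sprintf("KO%02d", i), config)))
    experiment_to_trials(recs)
  })
}
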