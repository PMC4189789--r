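# On-disk formats: multi-frame TIFF stacks with a JSON sidecar, CSV trial
# logs, YAML configurations.

#' Write / read an image stack as multi-frame TIFF
#'
#' Frames are stored as 32-bit samples scaled to the stack's value range;
#' the scaling, frame rate and dimensions go into a JSON sidecar at
#' `<path>.json` so the round trip restores camera units (to ~1e-9 of the
#' value range).
#'
#' @param stack an [image_stack].
#' @param path output `.tif` path.
#' @return `write_stack_tiff`: the path, invisibly. `read_stack_tiff`: an
#'   [image_stack].
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(d[1]), function(i) {
    (stack$data[i, , , drop = TRUE] - lo) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(frame_rate = stack$frame_rate, n_frames = d[1],
         rows = d[2], cols = d[3], offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) != meta$n_frames) {
    stop("frame count disagrees with sidecar")
  }
  dat <- array(0, c(meta$n_frames, meta$rows, meta$cols))
  for (i in seq_along(frames)) {
    dat[i, , ] <- frames[[i]] * meta$scale + meta$offset
  }
  image_stack(dat, meta$frame_rate)
}

#' Write a response map (magnitude + phase) with a JSON summary
#'
#' Magnitude and phase go to 32-bit TIFFs (`<stem>_magnitude.tif`,
#' `<stem>_phase.tif`, each with a scaling sidecar); the JSON summary
#' holds the stimulus frequency and, if supplied, a threshold curve.
#'
#' @param map a [response_map][compute_response_map].
#' @param stem output path stem (no extension).
#' @param curve optional [threshold_curve()] to embed in the summary.
#' @return the summary JSON path, invisibly.
#' @export
write_response_map <- function(map, stem, curve = NULL) {
  stopifnot(inherits(map, "response_map"))
  write_plane <- function(m, path) {
    m[!is.finite(m)] <- 0
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32)
    list(path = basename(path), offset = lo, scale = scale)
  }
  mag <- write_plane(map$magnitude, paste0(stem, "_magnitude.tif"))
  ph <- write_plane(map$phase, paste0(stem, "_phase.tif"))
  summary_path <- paste0(stem, "_summary.json")
  jsonlite::write_json(
    list(stim_frequency = map$stim_frequency, bin_factor = map$bin_factor,
         magnitude = mag, phase = ph,
         threshold_curve = if (!is.null(curve))
           list(threshold = curve$threshold,
                pixel_count = curve$pixel_count)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary_path)
}

#' Write / read a tidy trial log as CSV
#'
#' One row per trial; event sequences are serialised as `"1>2>3>4"` with
#' `;`-separated timestamps, so a log round-trips to an identical success
#' table.
#'
#' @param trials tidy trial tibble (see [experiment_to_trials()]).
#' @param path CSV path.
#' @return `write_trial_log`: the path, invisibly; `read_trial_log`: the
#'   trial tibble.
#' @export
write_trial_log <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    mouse_id = readr::col_character(),
    genotype = readr::col_character(),
    session = readr::col_integer(),
    trial_index = readr::col_integer(),
    distance_cm = readr::col_double(),
    outcome = readr::col_character(),
    reward = readr::col_logical(),
    event_sequence = readr::col_character(),
    event_times = readr::col_character()))
}

#' Replay-validate a trial log
#'
#' Re-classifies every recorded sensor-event sequence and checks the
#' accounting invariants: the stored outcome matches the classification,
#' rewards coincide with successes, every distance lies on the assay grid,
#' and each session's first trial is at the opening distance.
#'
#' @param trials a trial tibble (e.g. from [read_trial_log()]).
#' @param config the [gapcross_config()] the log claims to follow.
#' @return `TRUE` invisibly; errors with a diagnostic on any violation.
#' @export
validate_trial_log <- function(trials, config = gapcross_config()) {
  fail <- function(...) stop("trial log invalid: ", sprintf(...), call. = FALSE)
  if (!all(is_on_grid(trials$distance_cm, config))) {
    fail("off-grid distances present")
  }
  reclass <- vapply(strsplit(trials$event_sequence, ">", fixed = TRUE),
                    function(s) classify_trial(as.integer(s)), character(1))
  bad <- which(reclass != trials$outcome)
  if (length(bad)) {
    fail("outcome/event mismatch at row %d (%s vs %s)",
         bad[1], trials$outcome[bad[1]], reclass[bad[1]])
  }
  if (!identical(trials$reward, trials$outcome == "success")) {
    fail("rewards do not coincide with successes")
  }
  firsts <- trials |>
    dplyr::group_by(.data$mouse_id, .data$session) |>
    dplyr::slice_min(.data$trial_index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (!all(abs(firsts$distance_cm - config$first_trial_distance) < 1e-9)) {
    fail("a session does not open at %.1f cm", config$first_trial_distance)
  }
  invisible(TRUE)
}

#' Read configurations from YAML
#'
#' Each reader passes the YAML mapping to the corresponding constructor,
#' so invariants are enforced on load. `write_yaml_config` writes any of
#' the package's configuration objects.
#'
#' @param x a configuration object.
#' @param path YAML file path.
#' @name yaml_config
#' @export
write_yaml_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname yaml_config
#' @export
read_phantom_config <- function(path) {
  do.call(ois_phantom_config, yaml::read_yaml(path))
}

#' @rdname yaml_config
#' @export
read_protocol <- function(path) {
  args <- yaml::read_yaml(path)
  args$stim_frequency <- NULL  # derived field
  do.call(stimulus_protocol, args)
}

#' @rdname yaml_config
#' @export
read_gapcross_config <- function(path) {
  do.call(gapcross_config, yaml::read_yaml(path))
}

#' @rdname yaml_config
#' @export
read_agent_config <- function(path) {
  do.call(agent_config, yaml::read_yaml(path))
}
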