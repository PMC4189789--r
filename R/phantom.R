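# Phantom reflectance stacks with a known stimulus-locked response.

#' Image stack container
#'
#' A minimal container for a reflectance time series: a numeric array of
#' dimension frames x rows x cols plus the acquisition frame rate. All
#' downstream analysis consumes this type.
#'
#' @param data numeric array, frames x rows x cols (camera units).
#' @param frame_rate acquisition rate in Hz.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, frame_rate) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (frames x rows x cols)")
  }
  if (!all(is.finite(data))) stop("stack contains non-finite values")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number")
  }
  structure(list(data = data, frame_rate = frame_rate), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %d x %d px at %g Hz (%.1f s)\n",
              d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate))
  invisible(x)
}

#' Phantom configuration for intrinsic-signal imaging
#'
#' Describes a synthetic reflectance stack containing a compact Gaussian
#' response blob modulated at the stimulus-repetition frequency, over
#' baseline reflectance, white sensor noise, a slow drift and optional
#' confound sinusoids (respiration/heartbeat surrogates). The defaults give
#' 35 stimulus cycles of a 20 s repetition period on a compressed time base
#' (700 frames at 1 Hz, stimulus at 0.05 Hz): the Fourier readout depends
#' only on frequency ratios, not absolute durations.
#'
#' The stack duration must be a whole number of stimulus periods so that the
#' stimulus frequency falls exactly on a discrete Fourier bin; off-bin
#' configurations are rejected because spectral leakage would bias the
#' amplitude estimate.
#'
#' @param n_frames number of frames.
#' @param frame_rate frames per second (Hz).
#' @param stim_frequency stimulus repetition frequency (Hz).
#' @param image_shape integer (rows, cols) in pixels.
#' @param blob_center (row, col) of the response centre, 1-based pixels.
#' @param blob_sigma Gaussian width of the response region (pixels).
#' @param peak_drr peak fractional reflectance change dR/R at the blob
#'   centre (dimensionless; ~1e-3 is typical of intrinsic signals).
#' @param baseline_reflectance mean reflectance (camera units).
#' @param white_noise_sd per-frame, per-pixel Gaussian noise (camera units).
#' @param drift_amplitude amplitude of a slow sinusoidal drift at one cycle
#'   per acquisition (camera units).
#' @param confound_frequencies frequencies (Hz) of additive global
#'   sinusoids away from the stimulus frequency; defaults to 7x and 9x the
#'   stimulus frequency (both below Nyquist at the default geometry).
#' @param confound_amplitude amplitude of each confound (camera units).
#' @param waveform `"sine"` (default; ground truth exact at the stimulus
#'   bin) or `"boxcar"` (on for `duty` of each period; more like an
#'   episodic hemodynamic response, ground truth at the fundamental is then
#'   only approximate).
#' @param duty on-fraction of each period for the boxcar waveform.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   stacks.
#' @return an object of class `ois_phantom_config` (a validated list).
#' @export
ois_phantom_config <- function(n_frames = 700L,
                               frame_rate = 1,
                               stim_frequency = 0.05,
                               image_shape = c(64L, 64L),
                               blob_center = c(32, 32),
                               blob_sigma = 5,
                               peak_drr = 1e-3,
                               baseline_reflectance = 2000,
                               white_noise_sd = 2,
                               drift_amplitude = 5,
                               confound_frequencies = stim_frequency * c(7, 9),
                               confound_amplitude = 2,
                               waveform = c("sine", "boxcar"),
                               duty = 0.15,
                               seed = NULL) {
  waveform <- match.arg(waveform)
  cfg <- list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
              stim_frequency = stim_frequency,
              image_shape = as.integer(image_shape),
              blob_center = blob_center, blob_sigma = blob_sigma,
              peak_drr = peak_drr,
              baseline_reflectance = baseline_reflectance,
              white_noise_sd = white_noise_sd,
              drift_amplitude = drift_amplitude,
              confound_frequencies = confound_frequencies,
              confound_amplitude = confound_amplitude,
              waveform = waveform, duty = duty, seed = seed)
  validate_phantom_config(cfg)
  structure(cfg, class = "ois_phantom_config")
}

validate_phantom_config <- function(cfg) {
  n_cycles <- cfg$n_frames / cfg$frame_rate * cfg$stim_frequency
  if (abs(n_cycles - round(n_cycles)) > 1e-9 || round(n_cycles) < 2) {
    stop("stack duration must span a whole number (>= 2) of stimulus ",
         "periods so the stimulus frequency falls on an FFT bin; got ",
         signif(n_cycles, 6), " cycles")
  }
  if (cfg$stim_frequency <= 0 || cfg$stim_frequency > cfg$frame_rate / 2) {
    stop("stimulus frequency must lie in (0, Nyquist]")
  }
  if (cfg$peak_drr < 0) stop("peak_drr must be >= 0")
  if (cfg$blob_sigma <= 0) stop("blob_sigma must be > 0")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 1L)) {
    stop("image_shape must be (rows, cols)")
  }
  lo <- cfg$blob_center - 3 * cfg$blob_sigma
  hi <- cfg$blob_center + 3 * cfg$blob_sigma
  if (any(lo < 1) || any(hi > cfg$image_shape)) {
    stop("response blob must lie fully inside the image at 3 sigma")
  }
  stim_bin <- cfg$stim_frequency * cfg$n_frames / cfg$frame_rate
  conf_bins <- cfg$confound_frequencies * cfg$n_frames / cfg$frame_rate
  if (any(abs(conf_bins - round(stim_bin)) < 0.5)) {
    stop("confound frequencies must not coincide with the stimulus bin")
  }
  if (any(cfg$confound_frequencies > cfg$frame_rate / 2)) {
    stop("confound frequencies must be below Nyquist")
  }
  if (cfg$white_noise_sd < 0 || cfg$drift_amplitude < 0 ||
      cfg$confound_amplitude < 0) {
    stop("noise, drift and confound amplitudes must be >= 0")
  }
  if (cfg$duty <= 0 || cfg$duty >= 1) stop("duty must be in (0, 1)")
  invisible(cfg)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# stream is untouched. A NULL seed uses (and advances) the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Ground-truth amplitude map of a phantom configuration
#'
#' The fractional response amplitude at pixel (r, c) is
#' `peak_drr * exp(-d^2 / (2 * blob_sigma^2))` with `d` the Euclidean
#' distance to the blob centre.
#'
#' @param config an [ois_phantom_config()].
#' @return rows x cols numeric matrix of dR/R amplitudes.
#' @export
phantom_truth_map <- function(config) {
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  dr <- (seq_len(rows) - config$blob_center[1])
  dc <- (seq_len(cols) - config$blob_center[2])
  d2 <- outer(dr^2, dc^2, `+`)
  config$peak_drr * exp(-d2 / (2 * config$blob_sigma^2))
}

#' Generate a phantom reflectance stack
#'
#' Builds a frames x rows x cols reflectance series in which each pixel has
#' temporal mean ~ `baseline_reflectance` and a stimulus-locked component
#' whose fractional amplitude follows the Gaussian ground-truth map, plus
#' white noise, a one-cycle-per-acquisition drift and the configured
#' confound sinusoids. With the `"sine"` waveform and no noise the
#' stimulus-bin Fourier amplitude of every pixel equals the ground truth
#' exactly (to numerical precision).
#'
#' @param config an [ois_phantom_config()].
#' @return a list of class `ois_phantom` with elements `stack`
#'   ([image_stack]), `truth` (rows x cols dR/R amplitude matrix) and
#'   `config`.
#' @export
generate_ois_stack <- function(config) {
  stopifnot(inherits(config, "ois_phantom_config"))
  validate_phantom_config(config)
  n <- config$n_frames
  t <- (seq_len(n) - 1) / config$frame_rate
  truth <- phantom_truth_map(config)

  s <- switch(config$waveform,
    sine = cos(2 * pi * config$stim_frequency * t),
    boxcar = {
      phase <- (t * config$stim_frequency) %% 1
      as.numeric(phase < config$duty)
    })

  # global additive terms (camera units), shared by all pixels
  duration <- n / config$frame_rate
  g <- config$drift_amplitude * sin(2 * pi * t / duration)
  for (fc in config$confound_frequencies) {
    g <- g + config$confound_amplitude * cos(2 * pi * fc * t)
  }

  flat <- config$baseline_reflectance *
    (1 + outer(s, as.vector(truth))) + g
  dat <- with_local_seed(config$seed, {
    if (config$white_noise_sd > 0) {
      flat <- flat + rnorm(length(flat), sd = config$white_noise_sd)
    }
    flat
  })
  dim(dat) <- c(n, config$image_shape)
  structure(list(stack = image_stack(dat, config$frame_rate),
                 truth = truth, config = config),
            class = "ois_phantom")
}

#' @export
print.ois_phantom <- function(x, ...) {
  cat(sprintf(
    "<ois_phantom> %s waveform, peak dR/R %.2g, stimulus %.3g Hz\n",
    x$config$waveform, x$config$peak_drr, x$config$stim_frequency))
  print(x$stack)
  invisible(x)
}
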