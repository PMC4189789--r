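# Per-pixel Fourier extraction of the stimulus-locked dR/R and
# threshold-curve quantification of the responsive region.

#' Periodic whisker-stimulation protocol
#'
#' Metadata for a temporally-encoded stimulation run: a brief deflection
#' train delivered once per repetition period, repeated many times while
#' imaging continuously. The analysis consumes only the repetition
#' frequency `1 / repetition_period`; the train parameters and deflection
#' angle are carried as provenance.
#'
#' @param repetition_period s between train onsets (default 20).
#' @param train_frequency deflection frequency within a train, Hz.
#' @param train_duration train length, s.
#' @param n_repeats number of repetitions per acquisition.
#' @param deflection_degrees approximate deflection amplitude (metadata).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(repetition_period = 20,
                              train_frequency = 3,
                              train_duration = 3,
                              n_repeats = 35,
                              deflection_degrees = 15) {
  if (repetition_period <= train_duration) {
    stop("repetition_period must exceed train_duration")
  }
  structure(list(repetition_period = repetition_period,
                 train_frequency = train_frequency,
                 train_duration = train_duration,
                 n_repeats = n_repeats,
                 deflection_degrees = deflection_degrees,
                 stim_frequency = 1 / repetition_period),
            class = "stimulus_protocol")
}

#' Spatially bin an image stack
#'
#' Replaces each `bin_factor` x `bin_factor` block of pixels by its mean,
#' frame by frame. The frame count and frame rate are unchanged.
#'
#' @param stack an [image_stack].
#' @param bin_factor integer; must divide both image dimensions.
#' @return a binned [image_stack].
#' @export
spatial_bin <- function(stack, bin_factor) {
  stopifnot(inherits(stack, "image_stack"))
  bin_factor <- as.integer(bin_factor)
  if (length(bin_factor) != 1L || is.na(bin_factor) || bin_factor < 1L) {
    stop("`bin_factor` must be a positive integer")
  }
  d <- dim(stack$data)
  if (d[2] %% bin_factor != 0L || d[3] %% bin_factor != 0L) {
    stop(sprintf(
      "bin_factor %d does not divide image dimensions %d x %d",
      bin_factor, d[2], d[3]))
  }
  if (bin_factor == 1L) return(stack)
  nr <- d[2] %/% bin_factor; nc <- d[3] %/% bin_factor
  # fold each spatial axis into (bin, coarse) and average the bin axes
  x <- stack$data
  dim(x) <- c(d[1], bin_factor, nr, bin_factor, nc)
  out <- apply(x, c(1, 3, 5), mean)
  image_stack(out, stack$frame_rate)
}

stim_bin_index <- function(n_frames, frame_rate, f_stim) {
  k <- f_stim * n_frames / frame_rate
  if (abs(k - round(k)) > 1e-6) {
    stop(sprintf(
      paste0("stimulus frequency %.6g Hz does not fall on an FFT bin for ",
             "%d frames at %.6g Hz (bin index %.4f); refusing to estimate ",
             "with spectral leakage"), f_stim, n_frames, frame_rate, k))
  }
  k <- as.integer(round(k))
  if (k < 2L) stop("stack must span at least 2 full stimulus cycles")
  if (k > n_frames %/% 2L) stop("stimulus frequency is above Nyquist")
  k
}

#' Per-pixel response magnitude and phase at the stimulus frequency
#'
#' For each pixel the mean-subtracted time series is Fourier transformed
#' and the coefficient at the stimulus frequency read out. The reported
#' magnitude is the fractional amplitude of the stimulus-locked sinusoid,
#' `2 * |X(f_stim)| / (n_frames * mean(pixel))` -- i.e. dR/R normalised by
#' that pixel's own temporal mean -- and the phase is `Arg(X(f_stim))`.
#' The acquisition must span a whole number of repetition periods so that
#' the stimulus frequency falls exactly on a Fourier bin.
#'
#' Pixels with (numerically) zero temporal mean cannot be normalised; their
#' magnitude and phase are set to `NaN` and excluded by downstream
#' threshold counting.
#'
#' @param stack an [image_stack].
#' @param protocol a [stimulus_protocol()] (or any list with a
#'   `stim_frequency` element in Hz).
#' @param detrend `"mean"` (default) subtracts each pixel's temporal mean
#'   only; `"linear"` additionally removes a least-squares line, for stacks
#'   with strong monotone drift.
#' @return object of class `response_map`: list with `magnitude` and
#'   `phase` (rows x cols matrices), `stim_frequency`, `bin_factor`.
#' @export
compute_response_map <- function(stack, protocol, detrend = c("mean", "linear")) {
  stopifnot(inherits(stack, "image_stack"))
  detrend <- match.arg(detrend)
  f_stim <- protocol$stim_frequency
  if (is.null(f_stim) || f_stim <= 0) stop("protocol must give stim_frequency > 0")
  d <- dim(stack$data)
  n <- d[1]
  k <- stim_bin_index(n, stack$frame_rate, f_stim)

  x <- stack$data
  dim(x) <- c(n, d[2] * d[3])
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, `-`)
  if (detrend == "linear") {
    tt <- seq_len(n) - (n + 1) / 2
    slope <- colSums(xc * tt) / sum(tt^2)
    xc <- xc - outer(tt, slope)
  }
  coef <- mvfft(xc)[k + 1L, ]
  bad <- abs(mu) < .Machine$double.eps * 1e3
  amp <- 2 * Mod(coef) / (n * mu)
  amp[bad] <- NaN
  ph <- Arg(coef)
  ph[bad] <- NaN
  magnitude <- matrix(amp, d[2], d[3])
  phase <- matrix(ph, d[2], d[3])
  structure(list(magnitude = magnitude, phase = phase,
                 stim_frequency = f_stim, bin_factor = 1L),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "<response_map> %d x %d px at %.3g Hz; dR/R range [%.3g, %.3g]\n",
    nrow(x$magnitude), ncol(x$magnitude), x$stim_frequency,
    min(x$magnitude, na.rm = TRUE), max(x$magnitude, na.rm = TRUE)))
  invisible(x)
}

#' Default threshold grid for a response map
#'
#' Ten evenly spaced dR/R values between the 50th and 99.5th percentiles of
#' the (finite, optionally ROI-masked) magnitude map.
#'
#' @param map a [response_map][compute_response_map].
#' @param roi optional logical matrix selecting pixels.
#' @param n number of thresholds.
#' @return ascending numeric vector of thresholds.
#' @export
default_thresholds <- function(map, roi = NULL, n = 10) {
  v <- mask_values(map, roi)
  q <- stats::quantile(v, c(0.5, 0.995), names = FALSE)
  if (q[2] <= q[1]) stop("degenerate magnitude distribution; supply thresholds")
  seq(q[1], q[2], length.out = n)
}

mask_values <- function(map, roi) {
  m <- map$magnitude
  if (!is.null(roi)) {
    if (!is.logical(roi) || !identical(dim(roi), dim(m))) {
      stop("`roi` must be a logical matrix matching the map dimensions")
    }
    if (!any(roi)) stop("empty ROI")
    m <- m[roi]
  }
  v <- m[is.finite(m)]
  if (length(v) == 0L) stop("no finite magnitudes in ROI")
  v
}

#' Pixel counts above a grid of dR/R thresholds
#'
#' For each threshold, counts the (ROI) pixels whose response magnitude is
#' strictly greater than the threshold. The counts are non-increasing along
#' an ascending grid; non-finite magnitudes are excluded.
#'
#' @param map a [response_map][compute_response_map].
#' @param thresholds strictly ascending dR/R values; defaults to
#'   [default_thresholds()].
#' @param roi optional logical matrix selecting pixels.
#' @return object of class `threshold_curve`: tibble with columns
#'   `threshold` and `pixel_count`.
#' @export
threshold_curve <- function(map, thresholds = NULL, roi = NULL) {
  v <- mask_values(map, roi)
  if (is.null(thresholds)) thresholds <- default_thresholds(map, roi)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly ascending")
  }
  counts <- vapply(thresholds, function(tau) sum(v > tau), integer(1))
  structure(tibble::tibble(threshold = thresholds, pixel_count = counts),
            class = c("threshold_curve", "tbl_df", "tbl", "data.frame"))
}

#' Compare threshold curves between two groups
#'
#' Two-way fixed-effects ANOVA of pixel counts on group and threshold (both
#' as factors), the comparison used to ask whether one genotype's
#' responsive region is systematically larger across the threshold grid.
#' All curves must share the same threshold grid.
#'
#' @param group_a,group_b lists of [threshold_curve()] objects (one per
#'   animal), at least two per group.
#' @param labels character(2) group names used in the output.
#' @return a tibble with one row per effect (`group`, `threshold`,
#'   `group:threshold`): columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
compare_threshold_curves <- function(group_a, group_b,
                                     labels = c("A", "B")) {
  check_curves <- function(g, nm) {
    if (!is.list(g) || length(g) < 2L) {
      stop("each group needs at least 2 threshold curves (", nm, ")")
    }
    lapply(g, function(x) stopifnot(inherits(x, "threshold_curve")))
    grids <- lapply(g, function(x) x$threshold)
    if (!all(vapply(grids[-1], function(z)
      isTRUE(all.equal(z, grids[[1]])), logical(1)))) {
      stop("threshold grids differ within group ", nm)
    }
    grids[[1]]
  }
  ga <- check_curves(group_a, labels[1])
  gb <- check_curves(group_b, labels[2])
  if (!isTRUE(all.equal(ga, gb))) stop("threshold grids differ between groups")

  long <- dplyr::bind_rows(
    dplyr::bind_rows(group_a, .id = "curve") |>
      dplyr::mutate(group = labels[1]),
    dplyr::bind_rows(group_b, .id = "curve") |>
      dplyr::mutate(group = labels[2]))
  long$group <- factor(long$group, levels = labels)
  long$threshold_f <- factor(long$threshold)

  fit <- aov(pixel_count ~ group * threshold_f, data = long)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  idx <- match(c("group", "threshold_f", "group:threshold_f"), rn)
  df_res <- tab[match("Residuals", rn), "Df"]
  tibble::tibble(
    effect = c("group", "threshold", "group:threshold"),
    df1 = tab[idx, "Df"],
    df2 = df_res,
    F = tab[idx, "F value"],
    p = tab[idx, "Pr(>F)"])
}
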