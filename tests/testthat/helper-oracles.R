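# Independent oracles, kept deliberately naive: each recomputes a quantity
# by direct enumeration or textbook sums so that the package path is
# checked against something that shares none of its code.

# Brute-force DFT coefficient of one series at bin k (0-based):
# X(k) = sum_t x_t * exp(-2*pi*i*k*t/n)
brute_dft_bin <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  sum(x * exp(-2i * pi * k * t / n))
}

# Fractional amplitude and phase at the stimulus bin, from first principles
brute_pixel_response <- function(x, k) {
  mu <- mean(x)
  X <- brute_dft_bin(x - mu, k)
  list(magnitude = 2 * Mod(X) / (length(x) * mu), phase = Arg(X))
}

# Pixel counts above thresholds by explicit scan
brute_threshold_counts <- function(mag, thresholds) {
  v <- mag[is.finite(mag)]
  vapply(thresholds, function(tau) sum(v > tau), integer(1))
}

# Adaptive candidate set by scanning every grid point
brute_candidates <- function(max_crossed, d_min = 3, d_max = 7, step = 0.5,
                             lower = 1.0, upper = 1.5) {
  grid <- seq(d_min, d_max, by = step)
  grid[grid >= max_crossed - lower - 1e-9 &
       grid <= max_crossed + upper + 1e-9]
}

# Two-way repeated-measures ANOVA block effect by hand, for a balanced
# table y[mouse, distance, block] with mouse-by-distance cells as matched
# subjects: within-subject SS decomposition, F = MS_block / MS_resid with
# df (1, k*(n-1)).
brute_rm_anova_block <- function(y) {
  stopifnot(length(dim(y)) == 3L, dim(y)[3] == 2L)
  n <- dim(y)[1]; k <- dim(y)[2]
  g <- mean(y)
  m_b <- apply(y, 3, mean)             # block means
  m_d <- apply(y, 2, mean)             # distance means
  m_db <- apply(y, c(2, 3), mean)      # distance x block means
  m_subj <- apply(y, c(1, 2), mean)    # subject (mouse x distance) means
  ss_block <- n * k * sum((m_b - g)^2)
  resid <- y
  for (b in 1:2) {
    resid[, , b] <- y[, , b] - m_subj -
      matrix(m_db[, b] - m_d, n, k, byrow = TRUE)
  }
  ss_resid <- sum(resid^2)
  df2 <- k * (n - 1)
  f <- (ss_block / 1) / (ss_resid / df2)
  list(F = f, df1 = 1, df2 = df2, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

# Build a block_summary-compatible rates array as a success_table, from a
# rates array y[mouse, distance, block] with a fixed trial count per cell:
# each block is realised as a single session so pooled rates reproduce y.
table_from_rates <- function(y, distances, genotype = "WT",
                             n_per_cell = 100L) {
  n <- dim(y)[1]; k <- dim(y)[2]
  rows <- expand.grid(m = seq_len(n), d = seq_len(k), b = 1:2)
  tab <- tibble::tibble(
    mouse_id = sprintf("%s%02d", genotype, rows$m),
    genotype = genotype,
    session = ifelse(rows$b == 1L, 1L, 7L),
    distance_cm = distances[rows$d],
    n_trials = n_per_cell,
    n_success = round(y[cbind(rows$m, rows$d, rows$b)] / 100 * n_per_cell))
  structure(tab, class = c("success_table", class(tab)))
}

# Minimal always/never-succeeding agents
sure_agent <- function(genotype = "WT", crossing_time = 5,
                       inter_trial_time = c(30, 10)) {
  agent_config(genotype, intercept = 50, slope = 0, nose_learning_rate = 0,
               whisker_learning_rate = 0, lapse_rate = 0,
               inter_trial_time = inter_trial_time,
               crossing_time = crossing_time)
}
never_agent <- function(inter_trial_time = c(60, 0), crossing_time = 0) {
  agent_config("WT", intercept = -50, slope = 0, nose_learning_rate = 0,
               whisker_learning_rate = 0, lapse_rate = 0,
               inter_trial_time = inter_trial_time,
               crossing_time = crossing_time)
}

# Small noiseless phantom whose dimmest pixel stays well above the
# double-precision floor of the Fourier readout
exact_phantom_config <- function(peak_drr = 0.01, white_noise_sd = 0,
                                 drift_amplitude = 0,
                                 confound_amplitude = 0, ...) {
  ois_phantom_config(
    n_frames = 200L, frame_rate = 1, stim_frequency = 0.05,
    image_shape = c(16L, 16L), blob_center = c(8.5, 8.5),
    blob_sigma = 2.5, peak_drr = peak_drr,
    white_noise_sd = white_noise_sd, drift_amplitude = drift_amplitude,
    confound_amplitude = confound_amplitude, ...)
}
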