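#' Block-average downsampling to 1 kHz
#'
#' Each output sample is the arithmetic mean of the `fs/1000` consecutive raw
#' samples in its 1 ms block; a trailing partial block is dropped.
#'
#' @param raw Numeric series sampled at `fs` Hz.
#' @param fs Sampling rate in Hz; must be a positive multiple of 1000.
#' @return Numeric series at 1 kHz.
#' @export
downsample <- function(raw, fs) {
  if (fs <= 0 || fs %% 1000 != 0) stop("fs must be a positive multiple of 1000 Hz")
  k <- fs / 1000
  n_out <- floor(length(raw) / k)
  if (n_out == 0) return(numeric(0))
  colMeans(matrix(raw[seq_len(n_out * k)], nrow = k))
}

#' Median-filter spike removal
#'
#' Centered sliding median with a 5 ms (5 sample) window at 1 kHz; the
#' windows are truncated at the edges. Removes action-potential transients
#' from membrane-potential series while preserving the synaptic envelope.
#'
#' @param series 1 kHz numeric series, length `>= 5`.
#' @param window Window length in samples (odd, default 5).
#' @return Filtered series, same length.
#' @details Near the edges the window is truncated symmetrically (radius
#'   `min(h, i - 1, n - i)`), which keeps the filter centered so monotone
#'   series pass through unchanged.
#' @export
remove_spikes <- function(series, window = 5L) {
  n <- length(series)
  if (n < window) stop("series shorter than the median-filter window")
  h <- (window - 1L) %/% 2L
  out <- as.numeric(stats::runmed(series, window, endrule = "keep"))
  edge <- c(seq_len(h), (n - h + 1L):n)
  out[edge] <- vapply(edge, function(i) {
    r <- min(h, i - 1L, n - i)
    stats::median(series[(i - r):(i + r)])
  }, numeric(1))
  out
}

#' Stimulus-response epoch windows
#'
#' Given the estimated stimulus-on and stimulus-off times, returns the three
#' response epochs: on response `[t_on, t_on + 250]`, full response
#' `[t_on, t_off + 250]`, and off response `[t_off - 70, t_off + 250]` (ms).
#' For short stimuli the off window may overlap the on window.
#'
#' @param t_on,t_off Stimulus on/off time in ms, `t_on < t_off`.
#' @return Tibble with columns `name`, `start_ms`, `end_ms`.
#' @export
epoch_windows <- function(t_on, t_off) {
  stopifnot(t_on < t_off)
  tibble::tibble(name = c("on", "full", "off"),
                 start_ms = c(t_on, t_on, t_off - 70),
                 end_ms = c(t_on + 250, t_off + 250, t_off + 250))
}

#' Estimate the stimulus-onset time from all trials of one cell
#'
#' Implements a conservative onset estimate: average all trials, smooth with
#' a 50 ms running average, find the largest extremum (relative to the mean
#' of the smoothed trace's first 100 ms) in the first half, bin the mean
#' trace into 50 ms bins and difference them, take the largest-magnitude
#' derivative immediately prior to the extremum as the response-start bin,
#' subtract a 100 ms retina-to-cortex propagation allowance, and round to
#' the nearest half bin width (25 ms).
#'
#' @param trials List of 1 kHz numeric series (all trials of one cell and
#'   signal kind), each `>= 200` ms long; at least 2 trials.
#' @return Onset estimate in ms (a multiple of 25).
#' @export
detect_onset <- function(trials) {
  stopifnot(length(trials) >= 2)
  n <- min(lengths(trials))
  if (n < 200) stop("series shorter than 200 ms")
  m <- rowMeans(vapply(trials, function(x) x[seq_len(n)], numeric(n)))
  sm <- running_mean(m, 50L)
  ref <- mean(sm[1:100])
  half <- seq_len(floor(n / 2))
  dev <- abs(sm[half] - ref)
  if (max(dev) < 1e-12 * max(abs(sm), 1)) stop("no response detected")
  ext <- which.max(dev)
  nb <- floor(n / 50)
  bins <- colMeans(matrix(m[seq_len(nb * 50)], nrow = 50))
  dbin <- diff(bins)
  ext_bin <- ceiling(ext / 50)
  cand <- seq_len(min(ext_bin, nb) - 1L)
  if (length(cand) == 0) cand <- 1L
  j <- cand[which.max(abs(dbin[cand]))]
  onset_bin_start <- j * 50            # start time (ms) of the bin the response begins in
  est <- onset_bin_start - 100
  25 * round(est / 25)
}

running_mean <- function(x, w) {
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# minimal-variance 100 ms baseline window; start slides at 1 ms resolution in
# [t_on - 200, t_on - 100], earliest start wins ties
baseline_stats <- function(samples, t_on, len = 100L) {
  if (t_on < 200) stop("t_on < 200 ms: no room for the baseline search")
  starts <- seq.int(t_on - 200, t_on - 100)
  starts <- starts[starts + len <= length(samples)]
  if (length(starts) == 0) stop("series too short for the baseline search")
  vars <- vapply(starts, function(s) stats::var(samples[(s + 1):(s + len)]),
                 numeric(1))
  s <- starts[which.max(vars == min(vars))]
  list(start_ms = s, value = mean(samples[(s + 1):(s + len)]))
}

#' Deflection of one trial from its pre-stimulus baseline
#'
#' The baseline is the mean of the minimum-variance 100 ms window whose
#' start lies within 200 to 100 ms before stimulus onset. The response
#' window is the 166 ms window containing the peak of the cross-trial mean
#' (the sample of largest absolute departure from the mean trace's own
#' baseline within the epoch), starting 66 ms before the peak, or halfway
#' between the epoch start and the peak when the peak falls within 66 ms of
#' the epoch start. Deflection is the absolute difference between the
#' trial's mean over that window and the trial's baseline.
#'
#' @param samples One trial's 1 kHz series.
#' @param epoch One row of [epoch_windows()] (or any list with `start_ms`,
#'   `end_ms`).
#' @param cross_trial_mean Mean series across all trials of the same cell
#'   and signal kind.
#' @param t_on Stimulus onset (ms), `>= 200`.
#' @param trial_id Optional identifier copied into the result.
#' @return One-row tibble: `trial_id`, `baseline`, `window_start_ms`,
#'   `window_end_ms`, `deflection`.
#' @export
compute_deflection <- function(samples, epoch, cross_trial_mean, t_on,
                               trial_id = NA_character_) {
  bl <- baseline_stats(samples, t_on)
  mbl <- baseline_stats(cross_trial_mean, t_on)
  e0 <- epoch$start_ms; e1 <- min(epoch$end_ms, length(cross_trial_mean) - 1)
  idx <- (floor(e0) + 1):ceiling(e1)
  peak_t <- idx[which.max(abs(cross_trial_mean[idx] - mbl$value))] - 1  # ms
  w0 <- if (peak_t - e0 < 66) (e0 + peak_t) / 2 else peak_t - 66
  w0 <- round(w0)
  w_idx <- (w0 + 1):min(w0 + 166, length(samples))
  defl <- abs(mean(samples[w_idx]) - bl$value)
  tibble::tibble(trial_id = trial_id, baseline = bl$value,
                 window_start_ms = w0, window_end_ms = w0 + 166,
                 deflection = defl)
}

#' Per-trial deflection table for one cell
#'
#' Convenience wrapper applying [compute_deflection()] to every trial of a
#' trial tibble, using the stored `t_on`/`t_off` and the requested epoch.
#'
#' @param cell Trial tibble for one cell and signal kind.
#' @param epoch `"on"` (default, the most informative for discrimination),
#'   `"full"` or `"off"`.
#' @return Tibble: `trial_id`, `stimulus_index`, `baseline`, `deflection`,
#'   window bounds.
#' @export
deflection_table <- function(cell, epoch = "on") {
  stopifnot(nrow(cell) >= 1)
  n <- min(lengths(cell$samples))
  ctm <- rowMeans(vapply(cell$samples, function(x) x[seq_len(n)], numeric(n)))
  out <- lapply(seq_len(nrow(cell)), function(i) {
    w <- epoch_windows(cell$t_on[i], cell$t_off[i])
    w <- w[w$name == epoch, ]
    cbind(compute_deflection(cell$samples[[i]], w, ctm, cell$t_on[i],
                             trial_id = cell$trial_id[i]),
          stimulus_index = cell$stimulus_index[i])
  })
  dplyr::bind_rows(out)
}
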