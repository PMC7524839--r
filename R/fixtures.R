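#' Synthetic trial-store generator
#'
#' Deterministic generator emulating the statistical shape of intracellular
#' stimulus-response data: each trial is a baseline plus a
#' stimulus-dependent step (the deflection), a stimulus-dependent damped
#' oscillation (the recoverable dynamical structure; a second-order linear
#' system is the smallest stimulus-coded dynamics a 3-D embedding with a
#' cubic library can represent), and Gaussian noise. Tuning shapes mirror
#' the taxonomy seen in cortex: roughly linear ramps, sigmoids, or
#' non-invertible Gaussian bumps.
#'
#' @param n_stimuli Number of stimulus ordinals (6 or 8 typical).
#' @param trials_per_stimulus Examples per stimulus (default 11, a typical
#'   per-stimulus trial count for single-cell recordings).
#' @param tuning `"ramp"`, `"sigmoid"`, or `"gaussian"` shape for the
#'   per-stimulus deflection means.
#' @param deflection_range Range (min, max) of mean deflections (signal
#'   units).
#' @param osc_freq_hz Oscillation frequency per stimulus (recycled);
#'   stimulus-coded dynamics when distinct.
#' @param osc_amp Oscillation amplitude per stimulus (recycled).
#' @param osc_tau_ms Oscillation decay constant (ms).
#' @param noise_sd Gaussian noise SD (signal units).
#' @param t_on,t_off Stimulus window (ms); series length `t_off + 400` ms.
#' @param signal_kind,stimulus_axis Store metadata.
#' @param cell_id Cell identifier.
#' @param seed RNG seed; generation is fully seed-deterministic.
#' @return A validated trial-store tibble.
#' @export
generate_fixture <- function(n_stimuli = 6L, trials_per_stimulus = 11L,
                             tuning = c("ramp", "sigmoid", "gaussian"),
                             deflection_range = c(5, 50),
                             osc_freq_hz = 20, osc_amp = 10,
                             osc_tau_ms = 120, noise_sd = 2,
                             t_on = 300, t_off = 900,
                             signal_kind = "excitatory_current",
                             stimulus_axis = "size",
                             cell_id = "sim01", seed = 1L) {
  tuning <- match.arg(tuning)
  i <- seq_len(n_stimuli)
  u <- (i - 1) / (n_stimuli - 1)
  shape <- switch(tuning,
                  ramp = u,
                  sigmoid = stats::plogis(8 * (u - 0.5)),
                  gaussian = exp(-((u - 0.5) / 0.25)^2 / 2))
  means <- deflection_range[1] + diff(deflection_range) * shape
  freq <- rep_len(osc_freq_hz, n_stimuli)
  amp <- rep_len(osc_amp, n_stimuli)
  len <- t_off + 400
  t_ms <- seq_len(len) - 1
  with_seed(seed, {
    rows <- list()
    for (s in i) {
      for (k in seq_len(trials_per_stimulus)) {
        on <- t_ms >= t_on & t_ms < t_off
        rel <- pmax(t_ms - t_on, 0)
        y <- numeric(len)
        y[on] <- means[s]
        osc <- amp[s] * exp(-rel / osc_tau_ms) *
          sin(2 * pi * freq[s] * rel / 1000 + stats::runif(1, 0, 2 * pi))
        y <- y + ifelse(t_ms >= t_on, osc, 0)
        if (noise_sd > 0) y <- y + stats::rnorm(len, 0, noise_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell_id = cell_id,
          trial_id = sprintf("%s_s%02d_t%02d", cell_id, s, k),
          signal_kind = signal_kind, stimulus_axis = stimulus_axis,
          stimulus_index = s, t_on = t_on, t_off = t_off,
          samples = list(y))
      }
    }
    validate_trial_store(dplyr::bind_rows(rows))
  })
}
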