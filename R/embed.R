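#' Hankel (time-delay) matrix of a scalar series
#'
#' Row `k + 1` is the series shifted by `k` samples, for `k = 0..n_delays`;
#' the column count is `length(series) - n_delays`. Column `j` is therefore
#' the delay window whose first (undelayed) sample is `series[j]`.
#'
#' @param series Numeric vector, longer than `n_delays`.
#' @param n_delays Number of one-sample delays (default 100, i.e. a 100 ms
#'   window at 1 kHz).
#' @return `(n_delays + 1) x (length - n_delays)` matrix.
#' @export
build_hankel <- function(series, n_delays = 100L) {
  n <- length(series)
  if (n <= n_delays) stop("series too short for the requested number of delays")
  ncol_ <- n - n_delays
  idx <- outer(seq_len(n_delays + 1L) - 1L, seq_len(ncol_), "+")
  matrix(series[idx], nrow = n_delays + 1L)
}

#' Time-delay dimensionality expansion of one cell's trials
#'
#' Concatenates the chosen epoch slice of every trial, builds the Hankel
#' delay matrix, takes its SVD, and returns the first `d` principal-component
#' score time courses (right singular vectors scaled by their singular
#' values) as per-trial trajectories. Each embedded point is assigned to the
#' trial owning its first (undelayed) sample, and the full set of points is
#' centered so its grand mean is the origin. Rows of the Hankel matrix are
#' not Z-scored before the SVD.
#'
#' @param cell A trial tibble (see [read_trial_store()]) for one cell and
#'   signal kind.
#' @param epoch `"on"`, `"full"`, `"off"`, or `"all"` (whole series; the
#'   default for synthetic benchmark trials that are stimulus-defined
#'   throughout).
#' @param n_delays,d Delay count and kept dimension (defaults 100 and 3).
#' @param mask_boundaries If `TRUE`, drop embedded points whose delay window
#'   straddles a trial boundary in the concatenated series.
#' @return List with `basis` (a `dd_embedding` holding singular values and
#'   orthonormal modes) and `trajectories`, a tibble with one row per trial:
#'   `trial_id`, `stimulus_index`, and `points` (T x d matrix list-column).
#' @export
expand_and_center <- function(cell, epoch = "all", n_delays = 100L, d = 3L,
                              mask_boundaries = FALSE) {
  stopifnot(nrow(cell) > 0, d >= 1)
  if (d > n_delays + 1L) stop("d_kept cannot exceed n_delays + 1")
  slices <- lapply(seq_len(nrow(cell)), function(i) {
    epoch_slice(cell$samples[[i]], cell$t_on[i], cell$t_off[i], epoch)
  })
  lens <- lengths(slices)
  series <- unlist(slices, use.names = FALSE)
  n_cols <- length(series) - n_delays
  if (n_cols < 1) stop("concatenated series too short for the requested delays")
  # Hankel Gram and scores accumulated over column blocks: identical to
  # tcrossprod/crossprod of the full matrix without materializing it
  G <- matrix(0, n_delays + 1L, n_delays + 1L)
  block <- 100000L
  for (s0 in seq(1L, n_cols, by = block)) {
    Hb <- build_hankel(series[s0:min(s0 + block - 1L + n_delays,
                                     length(series))], n_delays)
    G <- G + tcrossprod(Hb)
  }
  ev <- eigen(G, symmetric = TRUE)
  sv <- sqrt(pmax(ev$values, 0))
  U <- ev$vectors
  Ud <- U[, seq_len(d), drop = FALSE]
  scores <- matrix(0, n_cols, d)
  for (s0 in seq(1L, n_cols, by = block)) {
    s1 <- min(s0 + block - 1L, n_cols)
    Hb <- build_hankel(series[s0:(s1 + n_delays)], n_delays)
    scores[s0:s1, ] <- crossprod(Hb, Ud)
  }
  # ownership: the trial containing the undelayed (first) sample of each window
  owner <- rep.int(seq_along(lens), lens)[seq_len(n_cols)]
  keep <- rep(TRUE, n_cols)
  if (mask_boundaries) {
    last_owner <- rep.int(seq_along(lens), lens)[seq_len(n_cols) + n_delays]
    keep <- owner == last_owner
  }
  center <- colMeans(scores[keep, , drop = FALSE])
  scores <- sweep(scores, 2L, center, "-")
  trajs <- lapply(seq_along(lens), function(i) {
    scores[keep & owner == i, , drop = FALSE]
  })
  basis <- structure(list(n_delays = as.integer(n_delays), d_kept = as.integer(d),
                          singular_values = sv, modes = U, center = center,
                          epoch = epoch),
                     class = "dd_embedding")
  list(basis = basis,
       trajectories = tibble::tibble(trial_id = cell$trial_id,
                                     stimulus_index = cell$stimulus_index,
                                     points = trajs))
}

#' @export
print.dd_embedding <- function(x, ...) {
  en <- x$singular_values^2
  cat(sprintf("<dd_embedding> %d delays -> %d dims kept (%.1f%% energy)\n",
              x$n_delays, x$d_kept,
              100 * sum(en[seq_len(x$d_kept)]) / sum(en)))
  invisible(x)
}

# extract the samples of one epoch window; [start, end) in ms, sample k (1-based
# index k) is time k-1 ms
epoch_slice <- function(samples, t_on, t_off, epoch) {
  n <- length(samples)
  if (identical(epoch, "all")) return(samples)
  w <- epoch_windows(t_on, t_off)
  w <- w[w$name == epoch, ]
  if (nrow(w) != 1) stop("epoch must be one of 'on', 'full', 'off', 'all'")
  i0 <- max(0, floor(w$start_ms)); i1 <- min(n, ceiling(w$end_ms))
  if (i1 - i0 < 1) stop("epoch window lies outside the recorded series")
  samples[(i0 + 1):i1]
}
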