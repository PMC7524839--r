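# Occupancy-map maximum-likelihood decoder: the derivative-free control that
# asks whether state-space occupancy alone (no fitted dynamics) separates
# stimuli. Trajectories in 3-D tend to oscillate about a long axis, so each
# stimulus's training trajectories are described in cylindrical coordinates
# about that set's principal axis (axial z, radial r; the angle is computed
# and discarded) and summarized by a kernel-smoothed (z, r) occupancy map.

# cylindrical (z, r) coordinates of points in the frame of a reference cloud
cylindrical_coords <- function(points, center, axis) {
  q <- sweep(points, 2L, center, "-")
  z <- drop(q %*% axis)
  r <- sqrt(pmax(rowSums(q^2) - z^2, 0))
  cbind(z = z, r = r)
}

frame_of <- function(points) {
  center <- colMeans(points)
  q <- sweep(points, 2L, center, "-")
  axis <- svd(q, nu = 0, nv = 1)$v[, 1]
  list(center = center, axis = axis)
}

bin_counts <- function(zr, z_edges, r_edges) {
  zi <- pmin(pmax(findInterval(zr[, 1], z_edges, all.inside = TRUE), 1L),
             length(z_edges) - 1L)
  ri <- pmin(pmax(findInterval(zr[, 2], r_edges, all.inside = TRUE), 1L),
             length(r_edges) - 1L)
  m <- matrix(0, length(z_edges) - 1L, length(r_edges) - 1L)
  for (k in seq_along(zi)) m[zi[k], ri[k]] <- m[zi[k], ri[k]] + 1
  m
}

# separable Gaussian blur, sigma in bins, renormalized to sum 1
smooth_map <- function(m, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur1 <- function(x) {
    n <- length(x)
    xp <- c(rep(0, r), x, rep(0, r))
    vapply(seq_len(n), function(i) sum(xp[i:(i + 2 * r)] * k), numeric(1))
  }
  m <- apply(m, 2L, blur1)
  m <- t(apply(m, 1L, blur1))
  if (sum(m) > 0) m / sum(m) else m
}

#' Occupancy maximum-likelihood decoder
#'
#' Per repetition and stimulus, 75% of that stimulus's trajectories define
#' a reference frame (the set's central point and principal axis after
#' centering) and a smoothed axial-radial occupancy probability map. Each
#' held-out trajectory is scored against every stimulus by the joint
#' log-likelihood of its time points under that stimulus's map (points
#' treated as independent; probabilities floored at `eps` before the log)
#' and classified to the argmax stimulus. Aggregated over `reps`
#' repetitions.
#'
#' @param trajectories Trajectory tibble from [expand_and_center()] with
#'   `d = 3`; `>= 4` examples per stimulus.
#' @param z_bins,r_bins Grid resolution (defaults 20 x 10).
#' @param reps Hold-out repetitions (default 510).
#' @param holdout_frac Held-out fraction per stimulus (default 0.25).
#' @param sigma Gaussian smoothing bandwidth in bins (default 1).
#' @param eps Probability floor before taking logs.
#' @param seed RNG seed.
#' @return A `dd_decode_result`.
#' @export
mle_occupancy_decoder <- function(trajectories, z_bins = 20L, r_bins = 10L,
                                  reps = 510L, holdout_frac = 0.25,
                                  sigma = 1, eps = 1e-12, seed = NULL) {
  stopifnot(ncol(trajectories$points[[1]]) == 3)
  labels <- factor(trajectories$stimulus_index)
  if (any(table(labels) < 4)) stop("need >= 4 examples per stimulus")
  pts <- trajectories$points
  # global grid: pooled (z, r) ranges over own-frame coordinates
  own <- lapply(pts, function(p) cylindrical_coords(p, colMeans(p),
                                                    frame_of(p)$axis))
  zr_all <- do.call(rbind, own)
  z_span <- max(abs(zr_all[, 1])) * 1.05
  z_edges <- seq(-z_span, z_span, length.out = z_bins + 1L)
  r_edges <- seq(0, max(zr_all[, 2]) * 1.05, length.out = r_bins + 1L)
  with_seed(seed, {
    preds <- lapply(seq_len(reps), function(rep) {
      te <- holdout_indices(labels, holdout_frac)
      maps <- lapply(levels(labels), function(l) {
        tr_idx <- setdiff(which(labels == l), te)
        cloud <- do.call(rbind, pts[tr_idx])
        fr <- frame_of(cloud)
        M <- smooth_map(bin_counts(cylindrical_coords(cloud, fr$center, fr$axis),
                                   z_edges, r_edges), sigma)
        list(frame = fr, M = M)
      })
      pred <- vapply(te, function(i) {
        ll <- vapply(maps, function(mp) {
          zr <- cylindrical_coords(pts[[i]], mp$frame$center, mp$frame$axis)
          n_t <- bin_counts(zr, z_edges, r_edges)
          sum(n_t * log(pmax(mp$M, eps)))
        }, numeric(1))
        levels(labels)[which.max(ll)]
      }, character(1))
      tibble::tibble(rep = rep, truth = as.character(labels[te]), pred = pred)
    })
    decode_result("mle", dplyr::bind_rows(preds), levels(labels), reps)
  })
}
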