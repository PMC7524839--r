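# Linear stability analysis of fitted sparse ODEs: real fixed points of the
# de-normalized polynomial system, Jacobian eigenvalues, and per-stimulus
# regime summaries. The Z-scoring of the library enters the right-hand side
# as a translation plus rescaling, which the fixed-point solve and the
# Jacobian both account for.

# Jacobian of the de-normalized RHS at a point:
# J_kl = sum_m (Xi_mk / sigma_m) * dE_m/dV_l
jacobian_at <- function(coeffs, v) {
  lib <- coeffs$library
  pw <- lib$powers
  d <- lib$d
  J <- matrix(0, d, d)
  w <- sweep(coeffs$xi, 1L, coeffs$norm$sigma, "/")
  for (l in seq_len(d)) {
    dpow <- vapply(seq_len(nrow(pw)), function(m) {
      p <- pw[m, ]
      if (p[l] == 0) return(0)
      val <- p[l] * v[l]^(p[l] - 1L)
      for (j in seq_len(d)[-l]) if (p[j] > 0) val <- val * v[j]^p[j]
      val
    }, numeric(1))
    J[, l] <- colSums(w * dpow)
  }
  J
}

#' Real fixed points of a fitted sparse ODE
#'
#' Solves \eqn{\Xi^T[\mathcal{E}(V)-\mu_\Theta]/\sigma_\Theta = 0} for real
#' V. In one dimension the polynomial is solved exactly by root finding on
#' its coefficients; in higher dimensions a dense multi-start Newton
#' iteration (analytic Jacobian) is used, with solutions deduplicated at a
#' relative tolerance of 1e-6. Every returned point satisfies a scaled
#' residual below `res_tol`.
#'
#' @param coeffs A `dd_coeffs` object.
#' @param box Search box half-width per dimension (defaults to 4x the
#'   largest coefficient-implied scale, or supply the data range).
#' @param n_starts Number of Newton starts (default 300).
#' @param res_tol Residual acceptance tolerance (default 1e-8, scaled by
#'   the RHS magnitude at the search scale).
#' @param seed RNG seed for the start sampling.
#' @return Tibble with `coords` (list of d-vectors) and `residual`; may be
#'   incomplete if the solver fails to converge from all starts (warns).
#' @export
find_fixed_points <- function(coeffs, box = NULL, n_starts = 300L,
                              res_tol = 1e-8, seed = 1L) {
  d <- coeffs$library$d
  if (d == 1L) {
    raw <- denormalize_coefficients(coeffs)[, 1]
    deg <- rowSums(coeffs$library$powers)
    co <- numeric(max(deg) + 1L)
    for (m in seq_along(raw)) co[deg[m] + 1L] <- co[deg[m] + 1L] + raw[m]
    if (all(abs(co[-1]) < 1e-300)) return(empty_fp(d))
    rts <- polyroot(co)
    rts <- Re(rts[abs(Im(rts)) < 1e-8 * pmax(abs(rts), 1)])
    pts <- lapply(rts, function(x) x)
  } else {
    pts <- newton_multistart(coeffs, box, n_starts, seed)
  }
  if (length(pts) == 0) return(empty_fp(d))
  scale <- max(1, max(vapply(pts, function(p) max(abs(p)), numeric(1))))
  res <- vapply(pts, function(p) {
    max(abs(coeffs_rhs(coeffs, matrix(p, 1)))) / scale
  }, numeric(1))
  keep <- res < res_tol
  tibble::tibble(coords = pts[keep], residual = res[keep])
}

empty_fp <- function(d) tibble::tibble(coords = list(), residual = numeric(0))

newton_multistart <- function(coeffs, box, n_starts, seed) {
  d <- coeffs$library$d
  if (is.null(box)) {
    # fall back to a scale implied by the normalization statistics
    box <- rep(4 * max(1, max(abs(coeffs$norm$mu))^(1 / 2)), d)
  }
  if (length(box) == 1L) box <- rep(box, d)
  found <- list()
  with_seed(seed, {
    starts <- lapply(seq_len(n_starts), function(i) stats::runif(d, -box, box))
    for (s in starts) {
      v <- s
      ok <- FALSE
      for (it in 1:60) {
        g <- drop(coeffs_rhs(coeffs, matrix(v, 1)))
        if (!all(is.finite(g))) break
        if (max(abs(g)) < 1e-12 * max(1, max(abs(v)))) { ok <- TRUE; break }
        J <- jacobian_at(coeffs, v)
        step <- tryCatch(solve(J, g), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) break
        # damped update keeps wild cubic steps in check
        if (max(abs(step)) > 10 * max(box)) step <- step * 10 * max(box) / max(abs(step))
        v <- v - step
        if (max(abs(v)) > 1e6 * max(box)) break
      }
      if (ok) {
        dup <- any(vapply(found, function(f) {
          max(abs(f - v)) <= 1e-6 * max(1, max(abs(v)))
        }, logical(1)))
        if (!dup) found <- c(found, list(v))
      }
    }
  })
  found
}

#' Classify fixed points by Jacobian eigenvalues
#'
#' At each fixed point the Jacobian of the de-normalized system is
#' evaluated and its eigenvalues computed. With tolerance
#' `tol = 1e-6 x spectral radius`: dynamics are oscillatory iff any
#' eigenvalue has `|Im| > tol`, convergent iff the maximum real part is
#' below `-tol`, divergent iff above `tol`, neutral otherwise. A point is
#' net-convergent iff `trace(J) < 0` (the eigenvalue real parts sum
#' negative); `strictly_convergent` (max real part `< 0`) is reported
#' alongside as the alternative reading.
#'
#' @param coeffs A `dd_coeffs` object.
#' @param points Fixed-point tibble from [find_fixed_points()].
#' @return The tibble with added `eigenvalues` (list), `klass` (list of
#'   class labels), `net_convergent`, `strictly_convergent`.
#' @export
classify_fixed_points <- function(coeffs, points) {
  if (nrow(points) == 0) {
    return(dplyr::mutate(points, eigenvalues = list(), klass = list(),
                         net_convergent = logical(0),
                         strictly_convergent = logical(0)))
  }
  info <- lapply(points$coords, function(p) {
    J <- jacobian_at(coeffs, as.numeric(p))
    ev <- eigen(J, only.values = TRUE)$values
    tol <- 1e-6 * max(Mod(ev), .Machine$double.eps)
    kl <- character(0)
    if (any(abs(Im(ev)) > tol)) kl <- c(kl, "oscillatory")
    mre <- max(Re(ev))
    kl <- c(kl, if (mre < -tol) "convergent" else if (mre > tol) "divergent"
            else "neutral")
    list(ev = ev, kl = kl, net = sum(Re(ev)) < 0, strict = mre < 0)
  })
  dplyr::mutate(points,
                eigenvalues = lapply(info, `[[`, "ev"),
                klass = lapply(info, `[[`, "kl"),
                net_convergent = vapply(info, `[[`, logical(1), "net"),
                strictly_convergent = vapply(info, `[[`, logical(1), "strict"))
}

#' Per-stimulus dynamical-regime summary
#'
#' Summarizes the classified fixed points of many per-trial fitted models:
#' the distribution of real-fixed-point counts, and the fractions of
#' net-convergent and oscillatory points per stimulus.
#'
#' @param fp_table Tibble binding classified fixed points across trials,
#'   with columns `trial_id`, `stimulus_index`, `net_convergent`, `klass`.
#' @return Tibble per stimulus: `n_trials`, `mean_fp_count`,
#'   `median_fp_count`, `frac_net_convergent`, `frac_oscillatory`.
#' @export
regime_summary <- function(fp_table) {
  if (nrow(fp_table) == 0) {
    return(tibble::tibble(stimulus_index = integer(0), n_trials = integer(0),
                          mean_fp_count = numeric(0),
                          median_fp_count = numeric(0),
                          frac_net_convergent = numeric(0),
                          frac_oscillatory = numeric(0)))
  }
  osc <- vapply(fp_table$klass, function(k) "oscillatory" %in% k, logical(1))
  fp_table$oscillatory <- osc
  counts <- dplyr::summarise(
    dplyr::group_by(fp_table, .data$stimulus_index, .data$trial_id),
    n_fp = dplyr::n(), .groups = "drop")
  per_stim <- dplyr::summarise(
    dplyr::group_by(counts, .data$stimulus_index),
    n_trials = dplyr::n(), mean_fp_count = mean(.data$n_fp),
    median_fp_count = stats::median(.data$n_fp), .groups = "drop")
  fracs <- dplyr::summarise(
    dplyr::group_by(fp_table, .data$stimulus_index),
    frac_net_convergent = mean(.data$net_convergent),
    frac_oscillatory = mean(.data$oscillatory), .groups = "drop")
  dplyr::left_join(per_stim, fracs, by = "stimulus_index")
}
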