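# Precomputed per-trajectory fitting context.
#
# Everything the genetic search needs that does not depend on the mask is
# computed once per trajectory: derivative estimates, the Z-scored library,
# its Gram matrix and cross-products. A mask evaluation then reduces to
# solving small normal-equation systems, which is what makes evaluating
# hundreds of masks per generation tractable.

#' Prepare trajectories for masked sparse-ODE fitting
#'
#' @param trajectories Tibble from [expand_and_center()] (`trial_id`,
#'   `stimulus_index`, `points`).
#' @param lib Optional [build_library()]; defaults to cubic in the
#'   trajectory dimension.
#' @return A `dd_fit_context` with one precomputed entry per trajectory.
#' @export
prepare_sindy_data <- function(trajectories, lib = NULL) {
  stopifnot(nrow(trajectories) >= 1)
  d <- ncol(trajectories$points[[1]])
  if (is.null(lib)) lib <- build_library(d)
  entries <- lapply(trajectories$points, function(v) {
    de <- estimate_derivatives(v)
    theta <- poly_features(de$v, lib)
    nz <- normalize_library(theta, lib)
    dv <- de$dv
    list(v = de$v, dv = dv, theta_z = nz$theta_z, norm = nz$norm,
         G = crossprod(nz$theta_z), B = crossprod(nz$theta_z, dv),
         yss = colSums(dv^2), ymean = colMeans(dv), n = nrow(dv))
  })
  structure(list(entries = entries, lib = lib,
                 trial_id = trajectories$trial_id,
                 stimulus_index = trajectories$stimulus_index,
                 n_traj = nrow(trajectories)),
            class = "dd_fit_context")
}

#' @export
print.dd_fit_context <- function(x, ...) {
  cat(sprintf("<dd_fit_context> %d trajectories, %d-term library, d=%d\n",
              x$n_traj, nrow(x$lib$powers), x$lib$d))
  invisible(x)
}

# solve the mask-restricted least squares for one precomputed entry;
# returns xi (z-space) and per-dimension R^2
fit_entry <- function(entry, mask, lib) {
  d <- lib$d
  xi <- matrix(0, nrow(mask), d)
  r2 <- numeric(d)
  for (k in seq_len(d)) {
    sel <- which(mask[, k] != 0)
    A <- entry$G[sel, sel, drop = FALSE]
    b <- entry$B[sel, k]
    co <- tryCatch(solve(A, b), error = function(e) {
      ols_minnorm(entry$theta_z[, sel, drop = FALSE], entry$dv[, k])
    })
    xi[sel, k] <- co
    rss <- max(entry$yss[k] - 2 * sum(co * b) + drop(crossprod(co, A %*% co)), 0)
    tss <- entry$yss[k] - entry$n * entry$ymean[k]^2
    r2[k] <- if (tss > 0) 1 - rss / tss else NA_real_
  }
  list(xi = xi, r2 = r2)
}

# n_traj x n_selected feature matrix: the nonzero coefficients in mask order
features_for_mask <- function(ctx, mask) {
  sel <- which(mask != 0)
  feats <- t(vapply(ctx$entries, function(e) {
    fit_entry(e, mask, ctx$lib)$xi[sel]
  }, numeric(length(sel))))
  colnames(feats) <- paste0("c", seq_len(ncol(feats)))
  feats
}

# full dd_coeffs for one trajectory of the context under a mask
fit_trajectory_coeffs <- function(ctx, i, mask) {
  e <- ctx$entries[[i]]
  f <- fit_entry(e, mask, ctx$lib)
  new_dd_coeffs(f$xi, mask, e$norm, ctx$lib, f$r2)
}
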