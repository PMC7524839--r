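#' Polynomial library specification
#'
#' Enumerates all monomials of total degree `<= max_degree` in `d` state
#' variables, constant term first, remaining terms in graded-lexicographic
#' order. The library defines the candidate right-hand-side terms of the
#' sparse ODE \eqn{dV = \Xi^T \Theta(V)}.
#'
#' @param d Number of state dimensions (embedding dimension), `>= 1`.
#' @param max_degree Maximum total polynomial degree; default 3 (the same
#'   order as a FitzHugh-Nagumo right-hand side).
#' @return An object of class `dd_library`: a list with `d`, `max_degree`,
#'   `powers` (term-count x d integer exponent matrix) and `term_names`.
#'   Term count is `choose(d + max_degree, max_degree)`.
#' @examples
#' build_library(3)$term_names[1:5]
#' @export
build_library <- function(d, max_degree = 3L) {
  stopifnot(d >= 1, max_degree >= 1)
  grids <- rep(list(0:max_degree), d)
  pw <- as.matrix(expand.grid(grids))
  pw <- pw[rowSums(pw) <= max_degree, , drop = FALSE]
  # graded-lex: by total degree, then lexicographic on exponents of x1, x2, ...
  ord <- do.call(order, c(list(rowSums(pw)),
                          lapply(seq_len(d), function(j) -pw[, j])))
  pw <- pw[ord, , drop = FALSE]
  dimnames(pw) <- NULL
  nm <- apply(pw, 1L, function(p) {
    if (all(p == 0)) return("1")
    parts <- sprintf("x%d^%d", seq_len(d), p)[p > 0]
    paste(sub("\\^1$", "", parts), collapse = "*")
  })
  structure(list(d = as.integer(d), max_degree = as.integer(max_degree),
                 powers = pw, term_names = nm),
            class = "dd_library")
}

#' @export
print.dd_library <- function(x, ...) {
  cat(sprintf("<dd_library> d=%d, degree<=%d, %d terms: %s\n",
              x$d, x$max_degree, nrow(x$powers),
              paste(utils::head(x$term_names, 8), collapse = ", ")))
  invisible(x)
}

#' Evaluate the polynomial library on trajectory points
#'
#' @param v T x d matrix of state points (a numeric vector is treated as
#'   a one-column matrix when `d = 1`).
#' @param lib A [build_library()] object.
#' @return T x term-count matrix \eqn{\Theta}.
#' @export
poly_features <- function(v, lib) {
  v <- as_state_matrix(v, lib$d)
  n <- nrow(lib$powers)
  out <- matrix(1, nrow(v), n)
  for (j in seq_len(n)) {
    p <- lib$powers[j, ]
    for (l in which(p > 0)) out[, j] <- out[, j] * v[, l]^p[l]
  }
  colnames(out) <- lib$term_names
  out
}

as_state_matrix <- function(v, d) {
  if (is.null(dim(v))) v <- matrix(v, ncol = d)
  stopifnot(ncol(v) == d)
  v
}

#' Derivative estimation by fourth-order central differences
#'
#' Applies the 5-point fourth-order central-difference stencil per dimension
#' (exact for polynomials up to degree 4), followed by a 3-point moving
#' average; the two samples at each end, where the stencil is undefined, are
#' trimmed. One time unit is one sample (1 ms at 1 kHz).
#'
#' @param v T x d matrix of trajectory points, `T >= 7`.
#' @return A list with `dv` (T-4 x d derivative estimates) and `v`
#'   (the trimmed trajectory rows, index-aligned with `dv`).
#' @export
estimate_derivatives <- function(v) {
  v <- as.matrix(v)
  T_ <- nrow(v)
  if (T_ < 7) stop("trajectory too short for derivative estimation (need >= 7 samples)")
  i <- 3:(T_ - 2)
  dv <- (v[i - 2, , drop = FALSE] - 8 * v[i - 1, , drop = FALSE] +
           8 * v[i + 1, , drop = FALSE] - v[i + 2, , drop = FALSE]) / 12
  dv <- apply(dv, 2L, smooth3)
  if (is.null(dim(dv))) dv <- matrix(dv, ncol = ncol(v))
  list(dv = dv, v = v[i, , drop = FALSE])
}

# centered 3-point moving average, truncated windows at the edges
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  s <- x
  s[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  s[1] <- mean(x[1:2]); s[n] <- mean(x[(n - 1):n])
  s
}

#' Z-score the library columns
#'
#' Non-constant columns are centered and scaled to unit standard deviation
#' over the fitted snippet; the constant column is exempt (`mu = 0`,
#' `sigma = 1`) so that the fitted constant coefficient keeps absolute-level
#' information. The returned statistics are required to integrate or analyze
#' the fitted model in original coordinates.
#'
#' @param theta Raw library value matrix from [poly_features()].
#' @param lib The [build_library()] object that produced `theta`.
#' @return List with `theta_z`, and `norm` = list(`mu`, `sigma`).
#' @export
normalize_library <- function(theta, lib) {
  const <- rowSums(lib$powers) == 0
  mu <- colMeans(theta)
  sigma <- apply(theta, 2L, stats::sd)
  bad <- !const & (!is.finite(sigma) | sigma <= 0)
  if (any(bad)) {
    stop(sprintf("zero-variance non-constant library column(s): %s",
                 paste(lib$term_names[bad], collapse = ", ")))
  }
  mu[const] <- 0; sigma[const] <- 1
  theta_z <- sweep(sweep(theta, 2L, mu, "-"), 2L, sigma, "/")
  list(theta_z = theta_z, norm = list(mu = mu, sigma = sigma))
}

#' Masked least-squares fit of the ODE coefficient matrix
#'
#' Per output dimension, ordinary least squares of the Z-scored library
#' columns selected by the mask onto the derivative estimates. Unselected
#' entries are exactly zero. Rank-deficient selections fall back to the
#' minimum-norm solution with a warning.
#'
#' @param theta_z Z-scored library matrix (rows aligned with `dv`).
#' @param dv Derivative matrix, T' x d.
#' @param mask Binary term-count x d matrix; `>= 1` nonzero per column.
#' @param lib Library specification.
#' @param norm Normalization statistics from [normalize_library()].
#' @return A `dd_coeffs` object: `xi` (coefficients in Z-scored coordinates),
#'   `mask`, `norm`, `library`, `fit_r2` (per dimension).
#' @export
fit_coefficients <- function(theta_z, dv, mask, lib, norm) {
  dv <- as.matrix(dv)
  stopifnot(nrow(theta_z) == nrow(dv), ncol(dv) == lib$d,
            nrow(mask) == nrow(lib$powers), ncol(mask) == lib$d)
  if (any(colSums(mask != 0) == 0)) stop("mask must select >= 1 term per output dimension")
  xi <- matrix(0, nrow(mask), ncol(mask))
  r2 <- numeric(lib$d)
  for (k in seq_len(lib$d)) {
    sel <- which(mask[, k] != 0)
    X <- theta_z[, sel, drop = FALSE]
    y <- dv[, k]
    b <- ols_minnorm(X, y)
    xi[sel, k] <- b
    res <- y - X %*% b
    tss <- sum((y - mean(y))^2)
    r2[k] <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  }
  new_dd_coeffs(xi, mask, norm, lib, r2)
}

new_dd_coeffs <- function(xi, mask, norm, lib, fit_r2) {
  structure(list(xi = xi, mask = mask, norm = norm, library = lib,
                 fit_r2 = fit_r2),
            class = "dd_coeffs")
}

#' @export
print.dd_coeffs <- function(x, ...) {
  cat(sprintf("<dd_coeffs> %d x %d, %d nonzero, fit R2: %s\n",
              nrow(x$xi), ncol(x$xi), sum(x$xi != 0),
              paste(sprintf("%.3f", x$fit_r2), collapse = ", ")))
  invisible(x)
}

ols_minnorm <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) {
    qr.coef(qrX, y)
  } else {
    warning("rank-deficient library selection; using minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(sv$v[, pos, drop = FALSE] %*%
           ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
  }
}

#' De-normalized polynomial coefficients
#'
#' Converts a fitted `dd_coeffs` (coefficients on Z-scored library columns)
#' to coefficients on raw monomials, folding the column means into the
#' constant term: \eqn{dV = \Xi^T[\Theta - \mu]/\sigma} becomes an ordinary
#' polynomial system.
#'
#' @param coeffs A `dd_coeffs` object.
#' @return term-count x d matrix of raw-coordinate coefficients.
#' @export
denormalize_coefficients <- function(coeffs) {
  xi <- coeffs$xi
  mu <- coeffs$norm$mu; sigma <- coeffs$norm$sigma
  raw <- sweep(xi, 1L, sigma, "/")
  const <- which(rowSums(coeffs$library$powers) == 0)
  raw[const, ] <- raw[const, ] - colSums(sweep(xi, 1L, mu / sigma, "*")) +
    xi[const, ] * (mu[const] / sigma[const])  # constant has mu=0: no-op kept explicit
  raw
}

# RHS of the fitted system in original coordinates, rows of v -> rows of dv
coeffs_rhs <- function(coeffs, v) {
  theta <- poly_features(v, coeffs$library)
  tz <- sweep(sweep(theta, 2L, coeffs$norm$mu, "-"), 2L, coeffs$norm$sigma, "/")
  tz %*% coeffs$xi
}

#' Integrate a fitted sparse ODE
#'
#' Forward-Euler integration with the de-normalization change of coordinates
#' applied at every step: \eqn{V'(t) = V'(t-1) + \Xi^T[\mathcal{E}(V'(t-1)) -
#' \mu_\Theta]/\sigma_\Theta}, one step per sample. A stiff-solver mode
#' (`method = "lsoda"`) is available; fitted models are frequently stiff and
#' may still blow up, which is reported as a flag rather than an error.
#'
#' @param coeffs A `dd_coeffs` object.
#' @param ic Initial condition, length-d vector.
#' @param n_steps Number of integration steps.
#' @param method `"euler"` (default) or `"lsoda"`.
#' @param blowup_scale Divergence guard: integration truncates once any
#'   coordinate exceeds `1e6 * blowup_scale` in magnitude.
#' @return List with `path` (matrix, up to `n_steps + 1` rows including the
#'   initial condition) and `blew_up` flag.
#' @export
integrate_model <- function(coeffs, ic, n_steps, method = c("euler", "lsoda"),
                            blowup_scale = 1) {
  method <- match.arg(method)
  d <- coeffs$library$d
  stopifnot(length(ic) == d)
  lim <- 1e6 * max(blowup_scale, .Machine$double.eps)
  if (method == "lsoda") {
    rhs <- function(t, y, p) list(drop(coeffs_rhs(coeffs, matrix(y, 1))))
    out <- try(deSolve::ode(y = as.numeric(ic), times = 0:n_steps, func = rhs,
                            parms = NULL, method = "lsoda"), silent = TRUE)
    if (inherits(out, "try-error")) {
      return(list(path = matrix(ic, 1), blew_up = TRUE))
    }
    path <- unname(as.matrix(out)[, -1, drop = FALSE])
    bad <- which(!is.finite(rowSums(path)) | apply(abs(path), 1, max) > lim)
    if (length(bad)) {
      return(list(path = path[seq_len(min(bad) - 1), , drop = FALSE], blew_up = TRUE))
    }
    return(list(path = path, blew_up = FALSE))
  }
  path <- matrix(NA_real_, n_steps + 1L, d)
  path[1, ] <- ic
  v <- matrix(as.numeric(ic), 1)
  for (t in seq_len(n_steps)) {
    v <- v + coeffs_rhs(coeffs, v)
    if (!all(is.finite(v)) || max(abs(v)) > lim) {
      return(list(path = path[seq_len(t), , drop = FALSE], blew_up = TRUE))
    }
    path[t + 1L, ] <- v
  }
  list(path = path, blew_up = FALSE)
}

#' Screen integration initial conditions against the source trajectory
#'
#' A candidate is accepted iff, integrating for the source's duration, the
#' simulated trajectory neither blows up nor collapses: for every dimension
#' `std(simulated) <= 5 * std(source)` and `std(simulated) >= std(source)/20`.
#'
#' @param coeffs Fitted `dd_coeffs`.
#' @param source T x d source trajectory the candidates were drawn from.
#' @param candidates List of length-d numeric initial conditions.
#' @return Logical vector marking accepted candidates.
#' @export
screen_initial_conditions <- function(coeffs, source, candidates) {
  source <- as.matrix(source)
  sds <- apply(source, 2L, stats::sd)
  n_steps <- nrow(source) - 1L
  scale <- max(abs(source))
  vapply(candidates, function(ic) {
    sim <- integrate_model(coeffs, ic, n_steps, blowup_scale = scale)
    if (sim$blew_up || nrow(sim$path) < nrow(source)) return(FALSE)
    ssd <- apply(sim$path, 2L, stats::sd)
    all(ssd <= 5 * sds) && all(ssd >= sds / 20)
  }, logical(1))
}
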