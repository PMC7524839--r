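#' Tidy a decode result
#'
#' @param x A `dd_decode_result`.
#' @param ... Unused.
#' @return Per-label tibble with F1 scores.
#' @export
tidy.dd_decode_result <- function(x, ...) {
  dplyr::mutate(x$per_label, mode = x$mode)
}

#' One-row summary of a decode result
#'
#' @param x A `dd_decode_result`.
#' @param ... Unused.
#' @export
glance.dd_decode_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, ccr = x$ccr, macro_f1 = x$macro_f1,
                 n_reps = x$n_reps, n_predictions = nrow(x$predictions))
}

#' Tidy a fitted coefficient matrix
#'
#' One row per nonzero coefficient: library term, output dimension,
#' Z-scored and de-normalized values.
#'
#' @param x A `dd_coeffs`.
#' @param ... Unused.
#' @export
tidy.dd_coeffs <- function(x, ...) {
  raw <- denormalize_coefficients(x)
  idx <- which(x$mask != 0, arr.ind = TRUE)
  tibble::tibble(term = x$library$term_names[idx[, 1]],
                 dimension = idx[, 2],
                 coefficient = x$xi[idx],
                 coefficient_raw = raw[idx])
}

#' One-row summary of a fitted coefficient matrix
#'
#' @param x A `dd_coeffs`.
#' @param ... Unused.
#' @export
glance.dd_coeffs <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x$xi), d = ncol(x$xi),
                 n_nonzero = sum(x$xi != 0),
                 sparsity = mean(x$mask != 0),
                 mean_fit_r2 = mean(x$fit_r2))
}

#' Tidy an embedding basis
#'
#' @param x A `dd_embedding`.
#' @param ... Unused.
#' @return Tibble of singular values and energy fractions.
#' @export
tidy.dd_embedding <- function(x, ...) {
  en <- x$singular_values^2
  tibble::tibble(mode = seq_along(en), singular_value = x$singular_values,
                 energy_fraction = en / sum(en),
                 kept = seq_along(en) <= x$d_kept)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
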