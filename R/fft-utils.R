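# Unitary FFT helpers shared by the scanner and the reconstructions.
# The unitary convention makes Parseval identities exact, so k-space
# energy checks and the per-frequency separation of the smoothness
# penalty hold without bookkeeping factors.

#' Unitary n-dimensional FFT
#'
#' Forward discrete Fourier transform scaled by `1/sqrt(V)` so that the
#' transform is an isometry (Parseval-exact). The DC component sits at the
#' first array index; use [centered_freq()] to map indices to centered
#' spatial frequencies.
#'
#' @param x A numeric or complex vector/array.
#' @return A complex array of the same shape.
#' @export
ufft <- function(x) stats::fft(x) / sqrt(length(x))

#' Unitary n-dimensional inverse FFT
#'
#' @param x A complex vector/array.
#' @return A complex array of the same shape.
#' @export
uifft <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Centered spatial frequency for 1-based grid indices
#'
#' Maps 1-based FFT array indices along an axis of length `n` to integer
#' frequencies in `[-floor(n/2), ceiling(n/2) - 1]`, placing DC (index 1)
#' at frequency 0 and the grid "center" of the shifted spectrum at
#' `-floor(n/2)`.
#'
#' @param idx Integer vector of 1-based indices.
#' @param n Axis length.
#' @return Integer vector of centered frequencies.
#' @export
centered_freq <- function(idx, n) {
  k <- idx - 1L
  ifelse(k < ceiling(n / 2), k, k - n)
}

# Linearize 1-based (i, j, k) grid indices (column-major, matching how R
# stores arrays) into a single 1-based index.
linear_index <- function(kx, ky, kz, grid_shape) {
  (kz - 1L) * grid_shape[1] * grid_shape[2] + (ky - 1L) * grid_shape[1] + kx
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
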