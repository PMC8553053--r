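# Reconstructed / ground-truth image time series container.

#' Image time series
#'
#' Container for a 3D+time image series: a 4D array `[x, y, z, t]`
#' (real or complex), the temporal interval length `dt` (s) and the
#' midpoint time of each frame.
#'
#' @param data 4D numeric or complex array `[x, y, z, t]`.
#' @param dt Temporal interval length (s).
#' @param times Frame midpoint times (s); defaults to `(i - 0.5) * dt`.
#' @param solver Optional solver log (list), attached by
#'   [eca_reconstruct()].
#' @param kspace Optional `[T x V]` complex matrix of the per-frame
#'   spatial Fourier coefficients (row `t` = unitary FFT of frame `t`);
#'   attached by [eca_reconstruct()] so that measured-entry data
#'   fidelity can be checked bit-exactly.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, dt, times = NULL, solver = NULL, kspace = NULL) {
  d <- dim(data)
  if (length(d) == 3) {
    data <- array(data, c(d, 1))
    d <- dim(data)
  }
  stopifnot(length(d) == 4)
  if (is.null(times)) times <- (seq_len(d[4]) - 0.5) * dt
  stopifnot(length(times) == d[4], all(diff(times) > 0) || d[4] == 1)
  structure(list(data = data, dt = dt, times = times,
                 grid_shape = d[1:3], n_times = d[4], solver = solver,
                 kspace = kspace),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %s x %d frames, dt = %g s, %s\n",
              paste(x$grid_shape, collapse = "x"), x$n_times, x$dt,
              if (is.complex(x$data)) "complex" else "real"))
  invisible(x)
}

#' Long tibble view of an image series
#'
#' One row per voxel-frame; complex data is reduced to magnitude.
#'
#' @param x An `image_series`.
#' @param voxels Optional linear voxel indices to restrict to.
#' @param ... Unused.
#' @return Tibble with columns `voxel`, `time`, `value`.
#' @method as_tibble image_series
#' @export
as_tibble.image_series <- function(x, voxels = NULL, ...) {
  V <- prod(x$grid_shape)
  if (is.null(voxels)) voxels <- seq_len(V)
  m <- series_matrix(x)[voxels, , drop = FALSE]
  tibble::tibble(voxel = rep(voxels, times = x$n_times),
                 time = rep(x$times, each = length(voxels)),
                 value = as.vector(m))
}

# [V x T] magnitude matrix of a series (voxels in linear order).
series_matrix <- function(x) {
  V <- prod(x$grid_shape)
  m <- matrix(x$data, nrow = V, ncol = x$n_times)
  if (is.complex(m)) Mod(m) else m
}

#' Write an image series as a 4D NIfTI volume
#'
#' Stores the magnitude as float32 with the temporal spacing `dt` in the
#' fourth `pixdim` slot. Complex data (if any) can be stored losslessly
#' with [write_image_series_csv()].
#'
#' @param x An `image_series`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_image_series_nifti <- function(x, path) {
  mag <- array(as.numeric(series_matrix(x)), dim = c(x$grid_shape, x$n_times))
  img <- RNifti::asNifti(mag,
                         reference = list(pixdim = c(-1, 1, 1, 1, x$dt, 0, 0, 0)),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume as an image series
#'
#' @param path NIfTI file path.
#' @return An `image_series` (real-valued); `dt` from the temporal pixdim.
#' @export
read_image_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  dt <- hdr$pixdim[5]
  if (!is.finite(dt) || dt <= 0) dt <- 1
  image_series(array(as.numeric(img), dim = dim(img)), dt = dt)
}

#' Write / read an image series (including complex data) as CSV
#'
#' Plain-text exact representation: a header JSON sidecar
#' (`<path>.meta.json`) holds `grid_shape`, `dt` and `times`; the CSV has
#' columns `voxel`, `frame`, `re`, `im` with full double precision.
#'
#' @param x An `image_series`.
#' @param path CSV path.
#' @return `path` (write) or an `image_series` (read).
#' @export
write_image_series_csv <- function(x, path) {
  v <- as.vector(x$data)
  df <- data.frame(voxel = rep(seq_len(prod(x$grid_shape)), times = x$n_times),
                   frame = rep(seq_len(x$n_times), each = prod(x$grid_shape)),
                   re = Re(v), im = Im(v))
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(grid_shape = x$grid_shape, dt = x$dt, times = x$times),
                       paste0(path, ".meta.json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_image_series_csv
#' @export
read_image_series_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  gs <- as.integer(meta$grid_shape)
  times <- as.numeric(meta$times)
  dat <- array(complex(real = df$re, imaginary = df$im), dim = c(gs, length(times)))
  if (all(df$im == 0)) dat <- array(Re(dat), dim = dim(dat))
  image_series(dat, dt = as.numeric(meta$dt), times = times)
}

# Full-precision text rendering of numeric columns (round-trip exact for
# doubles via 17 significant digits).
format_full <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}
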