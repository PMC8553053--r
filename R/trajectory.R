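# Time-tagged Cartesian k-space orderings. The readout axis (kx) is
# always fully sampled per line; orderings permute the phase-encode
# (ky, kz) lines. UnWRAP (Undersampling With Repeated Advancing Phase)
# splits the phase-encode plane into f contiguous sections, each section
# into f sheaves, and interleaves one sheaf per section so that every
# sweep_time/f window sees a uniform spread of spatial-frequency bands.

# Split `n` items into `f` contiguous blocks; the last block absorbs any
# remainder. Returns the block id (1..f) of each item.
contiguous_blocks <- function(n, f) {
  base <- n %/% f
  if (base == 0) rlang::abort(sprintf("Cannot split %d lines into %d sections.", n, f))
  sizes <- rep(base, f)
  sizes[f] <- sizes[f] + n %% f
  rep(seq_len(f), times = sizes)
}

#' UnWRAP k-space trajectory
#'
#' Generates a time-tagged Cartesian trajectory. Phase-encode lines are
#' linearized in centered order (ascending centered ky frequency, then
#' centered kz), split into `f` contiguous sections, and each section
#' into `f` sheaves; acquisition takes the first sheaf of every section
#' before any section's second sheaf, and so on. Sample timestamps are
#' uniform across the sweep, so with a reconstruction interval of
#' `sweep_time / f` each interval holds exactly one sheaf from every
#' section. `f = 1` reduces to a plain sequential raster. Within every
#' sweep each grid point is acquired exactly once (Nyquist complete).
#'
#' @param grid_shape Integer `(nx, ny, nz)`; `nx` is the readout axis.
#' @param sweep_time Duration (s) of one Nyquist-complete pass.
#' @param f Number of sections (and sheaves per section). Must not exceed
#'   the phase-encode line count `ny * nz`; when it does not divide the
#'   line count the last section/sheaf absorbs the remainder.
#' @param n_sweeps Number of consecutive identical sweeps.
#' @return A tibble of class `k_trajectory` with one row per sample:
#'   `sample`, `kx`, `ky`, `kz` (1-based grid indices, DC at index 1),
#'   `line`, `section`, `sheaf`, `time` (s). Attributes: `grid_shape`,
#'   `sweep_time`, `f`, `n_sweeps`.
#' @examples
#' tr <- unwrap_trajectory(c(8, 14, 14), sweep_time = 3.5, f = 14)
#' @export
unwrap_trajectory <- function(grid_shape, sweep_time = 3.5, f = 14, n_sweeps = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), sweep_time > 0, n_sweeps >= 1)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  n_lines <- ny * nz
  if (f > n_lines) rlang::abort("`f` cannot exceed the number of phase-encode lines.")

  # phase-encode lines in centered linear order
  ky_sorted <- order(centered_freq(seq_len(ny), ny))
  kz_sorted <- order(centered_freq(seq_len(nz), nz))
  lines <- tibble::tibble(
    line = seq_len(n_lines),
    ky = ky_sorted[((seq_len(n_lines) - 1L) %/% nz) + 1L],
    kz = kz_sorted[((seq_len(n_lines) - 1L) %% nz) + 1L]
  )
  lines$section <- contiguous_blocks(n_lines, f)
  # a section smaller than f cannot hold f sheaves; clamp (degrades the
  # per-interval spectral uniformity but preserves Nyquist completeness)
  lines$sheaf <- unlist(lapply(split(lines$line, lines$section),
                               function(ix) contiguous_blocks(length(ix), min(f, length(ix)))),
                        use.names = FALSE)

  # acquisition order: sheaf-major, then section, then within-sheaf order
  ord <- order(lines$sheaf, lines$section, lines$line)
  lines <- lines[ord, ]

  V <- nx * n_lines
  one_sweep <- tibble::tibble(
    kx = rep(seq_len(nx), times = n_lines),
    ky = rep(lines$ky, each = nx),
    kz = rep(lines$kz, each = nx),
    line = rep(lines$line, each = nx),
    section = rep(lines$section, each = nx),
    sheaf = rep(lines$sheaf, each = nx)
  )
  traj <- one_sweep[rep(seq_len(V), times = n_sweeps), ]
  traj$sample <- seq_len(V * n_sweeps)
  traj$time <- (traj$sample - 1L) * (sweep_time / V)
  traj <- traj[, c("sample", "kx", "ky", "kz", "line", "section", "sheaf", "time")]
  structure(tibble::as_tibble(traj),
            grid_shape = as.integer(grid_shape), sweep_time = sweep_time,
            f = as.integer(f), n_sweeps = as.integer(n_sweeps),
            class = c("k_trajectory", class(tibble::tibble())))
}

traj_meta <- function(traj) {
  list(grid_shape = attr(traj, "grid_shape"), sweep_time = attr(traj, "sweep_time"),
       f = attr(traj, "f"), n_sweeps = attr(traj, "n_sweeps"))
}

#' Partition a trajectory into reconstruction intervals
#'
#' Assigns every sample to the half-open time interval
#' `[i * dt, (i + 1) * dt)` containing its timestamp. Intervals are
#' disjoint and jointly exhaustive; `n_intervals = ceiling(duration / dt)`.
#'
#' @param traj A `k_trajectory` (or any tibble with a `time` column plus
#'   `sweep_time` / `n_sweeps` attributes).
#' @param dt Interval length (s); must be positive and no longer than the
#'   scan duration.
#' @return A list of class `k_partition`: `interval` (integer per
#'   sample), `dt`, `n_intervals`, `midpoints`, `counts` (tibble of
#'   per-interval sample counts).
#' @export
partition_trajectory <- function(traj, dt) {
  stopifnot_scalar(dt)
  if (dt <= 0) rlang::abort("`dt` must be positive.")
  meta <- traj_meta(traj)
  duration <- if (!is.null(meta$sweep_time)) meta$sweep_time * meta$n_sweeps else max(traj$time) + dt
  if (dt > duration + 1e-12) rlang::abort("`dt` is longer than the scan duration.")
  interval <- as.integer(floor(traj$time / dt)) + 1L
  n_intervals <- as.integer(ceiling(duration / dt - 1e-9))
  counts <- dplyr::count(tibble::tibble(interval = interval), .data$interval, name = "n_samples")
  structure(list(interval = interval, dt = dt, n_intervals = n_intervals,
                 midpoints = (seq_len(n_intervals) - 0.5) * dt,
                 duration = duration, counts = counts),
            class = "k_partition")
}

#' @export
print.k_partition <- function(x, ...) {
  cat(sprintf("<k_partition> %d intervals of dt = %g s over %g s\n",
              x$n_intervals, x$dt, x$duration))
  invisible(x)
}

#' Acceleration factor alpha = V * T / N
#'
#' Reconstructed voxel-time points per acquired k-space sample: `V`
#' voxels per volume, `T` reconstructed time points, `N` samples. A
#' Nyquist-complete sweep reconstructed at its own sweep time gives 1;
#' reconstructing a 3.5 s sweep at 0.25 s gives 14.
#'
#' @param x A `k_trajectory` (with `partition`), or a list/data frame
#'   with fields `V`, `T`, `N`.
#' @param partition A `k_partition` (required when `x` is a trajectory).
#' @return The acceleration factor (numeric scalar).
#' @export
acceleration_factor <- function(x, partition = NULL) {
  if (inherits(x, "k_trajectory")) {
    if (is.null(partition)) rlang::abort("Provide `partition` with a trajectory.")
    V <- prod(attr(x, "grid_shape"))
    T_ <- partition$n_intervals
    N <- nrow(x)
  } else {
    V <- x$V; T_ <- x$T; N <- x$N
  }
  if (is.null(N) || N <= 0) rlang::abort("`N` must be positive.")
  V * T_ / N
}

#' Per-interval spatial-frequency band histogram
#'
#' For each reconstruction interval, counts samples per frequency band of
#' the phase-encode plane. Bands are `n_bands` contiguous blocks of the
#' centered line ordering (the cross-section bands the sampling scheme is
#' designed around), recomputed from the (ky, kz) geometry — the score
#' therefore does not depend on how the trajectory's sections happen to
#' be labeled. The uniformity score is
#' `1 - mean(per-interval CV of band counts) / sqrt(n_bands - 1)`:
#' 1 when every interval covers all bands equally, 0 when each interval
#' is concentrated in a single band.
#'
#' @param traj A `k_trajectory`.
#' @param partition A `k_partition` of `traj`.
#' @param n_bands Number of bands (default: the trajectory's `f`).
#' @return A tibble `interval`, `band`, `n` with attribute
#'   `uniformity_score`.
#' @export
spectral_uniformity <- function(traj, partition, n_bands = NULL) {
  meta <- traj_meta(traj)
  gs <- meta$grid_shape
  if (is.null(n_bands)) n_bands <- max(meta$f %||% 8L, 2L)
  if (n_bands < 2) rlang::abort("`n_bands` must be at least 2.")
  # centered linear position of each sample's phase-encode line
  nz <- gs[3]
  lin <- (match(centered_freq(traj$ky, gs[2]),
                sort(centered_freq(seq_len(gs[2]), gs[2]))) - 1L) * nz +
    match(centered_freq(traj$kz, gs[3]),
          sort(centered_freq(seq_len(gs[3]), gs[3])))
  n_lines <- gs[2] * gs[3]
  band <- contiguous_blocks(n_lines, n_bands)[lin]
  df <- tibble::tibble(interval = partition$interval, band = band) |>
    dplyr::count(.data$interval, .data$band)
  cv <- df |>
    tidyr::complete(interval = seq_len(partition$n_intervals),
                    band = seq_len(n_bands), fill = list(n = 0L)) |>
    dplyr::group_by(.data$interval) |>
    dplyr::summarise(cv = stats::sd(.data$n) / mean(.data$n), .groups = "drop")
  structure(df, uniformity_score = 1 - mean(cv$cv) / sqrt(n_bands - 1))
}

#' Write / read a trajectory as CSV
#'
#' Plain-text exchange format: sample index, 1-based grid indices and
#' float64 timestamps, with grid/sweep metadata in a JSON sidecar.
#'
#' @param traj A `k_trajectory`.
#' @param path CSV path.
#' @return `path` (write) or a `k_trajectory` (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(format_full(df), path, row.names = FALSE, quote = FALSE)
  meta <- traj_meta(traj)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  structure(tibble::as_tibble(df),
            grid_shape = as.integer(meta$grid_shape),
            sweep_time = as.numeric(meta$sweep_time),
            f = as.integer(meta$f), n_sweeps = as.integer(meta$n_sweeps),
            class = c("k_trajectory", class(tibble::tibble())))
}
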