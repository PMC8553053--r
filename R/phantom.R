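# Continuous-time digital breast phantom: static background plus additive
# contrast enhancement in vessel voxels (Parker population AIF) and lesion
# voxels (truncated-exponential empirical model), rendered through a
# spoiled gradient-echo (SPGR) signal model.

#' Empirical lesion enhancement parameters
#'
#' Parameters of the truncated-exponential empirical model of tracer
#' concentration in lesion voxels:
#' `C(t) = A * (1 - exp(-alpha * (t - t0)))` for `t >= t0`, 0 before.
#'
#' @param A Upper limit of tracer concentration (mM). Must be >= 0.
#' @param alpha Uptake rate (1/s). Must be >= 0.
#' @param t0 Bolus arrival time (s). Must be >= 0.
#' @return A tibble with columns `A`, `alpha`, `t0` (one row per parameter
#'   set; arguments are recycled to a common length).
#' @examples
#' emm_params(A = 1.56, alpha = 0.14, t0 = 15)
#' @export
emm_params <- function(A = 1.56, alpha = 0.14, t0 = 15) {
  p <- tibble::tibble(A = as.numeric(A), alpha = as.numeric(alpha), t0 = as.numeric(t0))
  if (any(p$A < 0) || any(p$alpha < 0) || any(p$t0 < 0)) {
    rlang::abort("`A`, `alpha` and `t0` must all be non-negative.")
  }
  p
}

#' Lesion contrast concentration (truncated exponential model)
#'
#' Evaluates the empirical lesion uptake model
#' `C(t) = A * (1 - exp(-alpha * (t - t0)))` truncated to zero before the
#' bolus arrival time `t0`. The curve is continuous at `t0`, monotone
#' non-decreasing, and saturates at `A`.
#'
#' @param t Time (s); vectorized.
#' @param params A one-row data frame (or list) with `A`, `alpha`, `t0`,
#'   e.g. from [emm_params()]. Alternatively a multi-row data frame when
#'   `t` has length 1 or matching length.
#' @return Concentration (mM), same length as the broadcast of inputs.
#' @examples
#' lesion_concentration(25, emm_params(1.56, 0.14, 15))
#' @export
lesion_concentration <- function(t, params = emm_params()) {
  stopifnot(all(is.finite(t)))
  A <- params$A
  alpha <- params$alpha
  t0 <- params$t0
  if (any(A < 0) || any(alpha < 0)) {
    rlang::abort("`A` and `alpha` must be non-negative.")
  }
  dt <- t - t0
  ifelse(dt >= 0, A * (1 - exp(-alpha * dt)), 0)
}

#' Parker population arterial input function parameters
#'
#' Population-average AIF of Parker et al.: a sum of two Gaussians plus an
#' exponential decay modulated by a sigmoid. Native parameter units are
#' minutes (centers, widths, decay and sigmoid rates) and mM
#' (amplitudes); evaluation time is in seconds. `t0` is a per-voxel
#' arrival-time offset in seconds; the AIF is identically zero before it.
#'
#' @param a1,a2 Gaussian scaling constants (mM * min).
#' @param m1,m2 Gaussian centers (min).
#' @param s1,s2 Gaussian widths (min). Must be > 0.
#' @param alpha Amplitude of the exponential tail (mM).
#' @param beta Decay rate of the exponential tail (1/min). Must be > 0.
#' @param s Sigmoid steepness (1/min).
#' @param tau Sigmoid center (min).
#' @param t0 Arrival-time offset (s).
#' @return A list of class `aif_params`.
#' @export
aif_params <- function(a1 = 0.809, a2 = 0.330,
                       m1 = 0.17046, m2 = 0.365,
                       s1 = 0.0563, s2 = 0.132,
                       alpha = 1.050, beta = 0.1685,
                       s = 38.078, tau = 0.483,
                       t0 = 0) {
  if (s1 <= 0 || s2 <= 0) rlang::abort("Gaussian widths `s1`, `s2` must be positive.")
  if (beta <= 0) rlang::abort("Exponential decay rate `beta` must be positive.")
  structure(list(a1 = a1, a2 = a2, m1 = m1, m2 = m2, s1 = s1, s2 = s2,
                 alpha = alpha, beta = beta, s = s, tau = tau, t0 = t0),
            class = "aif_params")
}

#' Parker population arterial input function
#'
#' Blood-plasma contrast concentration at time `t` (seconds) for the
#' Parker population AIF, shifted so that concentration is exactly zero
#' before the arrival offset `params$t0` (and for all negative shifted
#' times).
#'
#' @param t Time (s); vectorized.
#' @param params An [aif_params()] object. A `t0` argument overrides the
#'   offset stored in `params`.
#' @param t0 Optional arrival-time offset (s) overriding `params$t0`.
#' @return Concentration (mM), non-negative.
#' @export
parker_aif <- function(t, params = aif_params(), t0 = NULL) {
  stopifnot(all(is.finite(t)))
  p <- params
  off <- if (is.null(t0)) p$t0 else t0
  tm <- (t - off) / 60  # minutes since arrival
  gauss <- function(a, m, s) a / (s * sqrt(2 * pi)) * exp(-(tm - m)^2 / (2 * s^2))
  c_t <- gauss(p$a1, p$m1, p$s1) + gauss(p$a2, p$m2, p$s2) +
    p$alpha * exp(-p$beta * tm) / (1 + exp(-p$s * (tm - p$tau)))
  c_t[tm <= 0] <- 0
  pmax(c_t, 0)
}

#' Spoiled gradient-echo signal model parameters
#'
#' @param flip_angle Flip angle (degrees), in (0, 90).
#' @param TR Repetition time (ms); must exceed `TE`.
#' @param TE Echo time (ms); must be positive. Kept for provenance; T2*
#'   decay is not modeled, so `TE` does not enter the signal equation.
#' @param r1 Longitudinal relaxivity of the contrast agent (1/s/mM).
#' @param T1_background,T1_lesion,T1_vessel Baseline T1 (s) per tissue
#'   class; defaults are typical 3T values for fibroglandular tissue and
#'   blood.
#' @param m0 Equilibrium magnetization scale (a.u.).
#' @return A list of class `signal_model_params`.
#' @export
signal_model_params <- function(flip_angle = 10, TR = 3.2, TE = 1.6,
                                r1 = 4.5,
                                T1_background = 1.4, T1_lesion = 1.4,
                                T1_vessel = 1.6, m0 = 1) {
  if (flip_angle <= 0 || flip_angle >= 90) rlang::abort("`flip_angle` must be in (0, 90) degrees.")
  if (!(TR > TE && TE > 0)) rlang::abort("Require TR > TE > 0 (ms).")
  structure(list(flip_angle = flip_angle, TR = TR, TE = TE, r1 = r1,
                 T1_background = T1_background, T1_lesion = T1_lesion,
                 T1_vessel = T1_vessel, m0 = m0),
            class = "signal_model_params")
}

#' Steady-state SPGR signal for a given contrast concentration
#'
#' Standard spoiled gradient-echo steady-state signal with linear
#' relaxivity: `R1 = 1/T1 + r1 * C`,
#' `S = m0 * sin(FA) * (1 - E1) / (1 - cos(FA) * E1)` with
#' `E1 = exp(-TR * R1)` (TR converted from ms to s). Strictly increasing
#' in `C`; equals the native baseline signal at `C = 0`.
#'
#' @param C Contrast agent concentration (mM); vectorized, must be >= 0.
#' @param params A [signal_model_params()] object.
#' @param T1 Baseline T1 (s) to use; defaults to `params$T1_background`.
#' @param m0 Optional per-voxel equilibrium magnetization overriding
#'   `params$m0`; vectorized.
#' @return Signal (a.u.).
#' @export
spgr_signal <- function(C, params = signal_model_params(), T1 = NULL, m0 = NULL) {
  if (any(C < 0)) rlang::abort("Concentration `C` must be non-negative.")
  T1 <- if (is.null(T1)) params$T1_background else T1
  m0 <- if (is.null(m0)) params$m0 else m0
  fa <- params$flip_angle * pi / 180
  R1 <- 1 / T1 + params$r1 * C
  E1 <- exp(-(params$TR / 1000) * R1)
  m0 * sin(fa) * (1 - E1) / (1 - cos(fa) * E1)
}

# Exact truncated-normal sampler (left truncation at `lower`) via inverse
# probability transform; vectorized, avoids rejection loops.
rtruncnorm0 <- function(n, mean, sd, lower = 0) {
  if (all(sd == 0)) return(rep_len(pmax(mean, lower), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Phantom configuration
#'
#' Describes a procedural digital breast phantom: grid geometry, an
#' ellipsoidal lesion, straight tubular vessels running along the x axis,
#' per-voxel enhancement parameter distributions, and the signal model.
#' Lesion parameters are drawn per voxel from truncated-normal
#' distributions (truncated at 0) with the given means/SDs; defaults are
#' the case-1 lesion statistics (A = 1.56 +/- 0.45 mM,
#' alpha = 0.14 +/- 0.13 1/s, t0 = 15 +/- 2.2 s). Vessel arrival offsets
#' vary as a smooth linear gradient along each vessel axis.
#'
#' @param grid_shape Integer vector of 3 voxel counts `(nx, ny, nz)`.
#' @param lesion List with `center` (3 voxel coords), `radii` (3 voxel
#'   radii), and `A`, `alpha`, `t0` each as `c(mean, sd)`. `NULL` for no
#'   lesion.
#' @param vessels List with `centers` (matrix/list of (y, z) centers),
#'   `radius` (voxels), `t0_base` (s, arrival at x = 1 for each vessel),
#'   `t0_span` (s, arrival increase across the x extent; set 0 for a
#'   constant offset). `NULL` for no vessels.
#' @param background Static background signal: `NULL` (default) renders
#'   the background tissue's own SPGR baseline signal, keeping the whole
#'   image on the signal-model scale so enhancement amplitudes are
#'   physiological relative to baseline; alternatively a scalar level
#'   (a.u.) or a 3D array of per-voxel values.
#' @param signal A [signal_model_params()] object.
#' @param aif An [aif_params()] object (vessel enhancement shape).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 8),
                           lesion = list(center = c(16, 22, 4), radii = c(7, 6, 3),
                                         A = c(1.56, 0.45), alpha = c(0.14, 0.13),
                                         t0 = c(15, 2.2)),
                           vessels = list(centers = list(c(8, 3), c(26, 6)),
                                          radius = 1.6,
                                          t0_base = c(8, 9), t0_span = 4),
                           background = NULL,
                           signal = signal_model_params(),
                           aif = aif_params()) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  structure(list(grid_shape = as.integer(grid_shape), lesion = lesion,
                 vessels = vessels, background = background,
                 signal = signal, aif = aif),
            class = "phantom_config")
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  x <- (seq_len(nx) - center[1]) / radii[1]
  y <- (seq_len(ny) - center[2]) / radii[2]
  z <- (seq_len(nz) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = grid_shape)
}

tube_mask_x <- function(grid_shape, center_yz, radius) {
  ny <- grid_shape[2]; nz <- grid_shape[3]
  y <- seq_len(ny) - center_yz[1]
  z <- seq_len(nz) - center_yz[2]
  d2 <- outer(y^2, z^2, `+`)
  sec <- d2 <= radius^2
  aperm(array(rep(sec, each = grid_shape[1]), dim = grid_shape), c(1, 2, 3))
}

#' Build a digital phantom
#'
#' Realizes a [phantom_config()] into a concrete phantom: boolean vessel
#' and lesion masks (disjoint; vessels take precedence on overlap of the
#' procedural shapes), per-voxel enhancement parameters drawn from the
#' configured truncated-normal distributions, and the static background.
#' Generation is deterministic for a fixed `seed`. User-supplied masks
#' (3D logical arrays in `config$lesion$mask` / `config$vessels$mask`)
#' may replace the procedural geometry and are rejected if they overlap.
#'
#' @param config A [phantom_config()].
#' @param seed Integer RNG seed for the parameter draws.
#' @return A list of class `eca_phantom` with elements `grid_shape`,
#'   `background` (3D array), `vessel_mask`, `lesion_mask` (3D logical),
#'   `lesion_params` (tibble: `voxel`, `A`, `alpha`, `t0`),
#'   `vessel_params` (tibble: `voxel`, `t0`), `signal`, `aif`, `config`,
#'   `seed`.
#' @export
build_phantom <- function(config = phantom_config(), seed = 1L) {
  gs <- config$grid_shape
  V <- prod(gs)

  lesion_mask <- array(FALSE, gs)
  vessel_mask <- array(FALSE, gs)
  vessel_t0 <- NULL

  user_lesion <- !is.null(config$lesion$mask)
  user_vessel <- !is.null(config$vessels$mask)
  if (user_lesion) {
    lesion_mask <- array(as.logical(config$lesion$mask), gs)
  } else if (!is.null(config$lesion)) {
    lesion_mask <- ellipsoid_mask(gs, config$lesion$center, config$lesion$radii)
  }
  if (user_vessel) {
    vessel_mask <- array(as.logical(config$vessels$mask), gs)
  } else if (!is.null(config$vessels)) {
    centers <- config$vessels$centers
    nves <- length(centers)
    t0_base <- rep_len(config$vessels$t0_base, nves)
    span <- config$vessels$t0_span %||% 0
    t0_map <- array(NA_real_, gs)
    for (j in seq_len(nves)) {
      m <- tube_mask_x(gs, centers[[j]], config$vessels$radius)
      idx <- which(m)
      xpos <- ((idx - 1L) %% gs[1]) + 1L
      frac <- if (gs[1] > 1) (xpos - 1) / (gs[1] - 1) else 0
      t0_map[idx] <- t0_base[j] + span * frac
      vessel_mask <- vessel_mask | m
    }
    vessel_t0 <- t0_map
  }

  if (user_lesion && user_vessel && any(lesion_mask & vessel_mask)) {
    rlang::abort("User-supplied lesion and vessel masks overlap.")
  }
  # procedural shapes may graze each other; vessels win
  lesion_mask <- lesion_mask & !vessel_mask

  set.seed(seed)
  les_idx <- which(lesion_mask)
  lesion_params <- tibble::tibble(voxel = integer(0), A = numeric(0),
                                  alpha = numeric(0), t0 = numeric(0))
  if (length(les_idx) > 0) {
    lp <- config$lesion
    lesion_params <- tibble::tibble(
      voxel = les_idx,
      A = rtruncnorm0(length(les_idx), lp$A[1], lp$A[2]),
      alpha = rtruncnorm0(length(les_idx), lp$alpha[1], lp$alpha[2]),
      t0 = rtruncnorm0(length(les_idx), lp$t0[1], lp$t0[2])
    )
  }

  ves_idx <- which(vessel_mask)
  vessel_params <- tibble::tibble(voxel = integer(0), t0 = numeric(0))
  if (length(ves_idx) > 0) {
    t0v <- if (!is.null(vessel_t0)) vessel_t0[ves_idx] else rep(config$vessels$t0_base[1], length(ves_idx))
    vessel_params <- tibble::tibble(voxel = ves_idx, t0 = t0v)
  }

  bg <- config$background
  if (is.null(bg)) bg <- spgr_signal(0, config$signal, T1 = config$signal$T1_background)
  background <- array(as.numeric(bg), gs)

  structure(list(grid_shape = gs, background = background,
                 vessel_mask = vessel_mask, lesion_mask = lesion_mask,
                 lesion_params = lesion_params, vessel_params = vessel_params,
                 signal = config$signal, aif = config$aif,
                 config = config, seed = seed),
            class = "eca_phantom")
}

#' @export
print.eca_phantom <- function(x, ...) {
  cat(sprintf("<eca_phantom> %s voxels (%s), %d lesion, %d vessel\n",
              prod(x$grid_shape), paste(x$grid_shape, collapse = "x"),
              nrow(x$lesion_params), nrow(x$vessel_params)))
  invisible(x)
}

# Enhancement (signal above background) for the masked voxels of a
# phantom at a vector of times. Returns a matrix [n_masked_voxels x n_times]
# together with the linear voxel indices, ordered lesion then vessel.
phantom_enhancement <- function(ph, times) {
  sig <- ph$signal
  n_t <- length(times)
  les <- ph$lesion_params
  ves <- ph$vessel_params
  out_idx <- c(les$voxel, ves$voxel)
  enh <- matrix(0, nrow = length(out_idx), ncol = n_t)
  if (nrow(les) > 0) {
    dt <- outer(-les$t0, times, `+`)          # t - t0, [voxel x time]
    C <- les$A * (1 - exp(-les$alpha * dt))   # recycles by row
    C[dt < 0] <- 0
    s0 <- spgr_signal(0, sig, T1 = sig$T1_lesion)
    enh[seq_len(nrow(les)), ] <- spgr_signal(C, sig, T1 = sig$T1_lesion) - s0
  }
  if (nrow(ves) > 0) {
    tm <- outer(-ves$t0, times, `+`)          # time since arrival
    C <- matrix(parker_aif(as.vector(tm), ph$aif, t0 = 0), nrow = nrow(ves))
    s0 <- spgr_signal(0, sig, T1 = sig$T1_vessel)
    enh[nrow(les) + seq_len(nrow(ves)), ] <- spgr_signal(C, sig, T1 = sig$T1_vessel) - s0
  }
  list(index = out_idx, enhancement = enh)
}

#' Evaluate a phantom at a continuous time point
#'
#' Renders the phantom's full image volume at time `t` (s): the static
#' background plus the additive SPGR enhancement of every lesion and
#' vessel voxel. Before the earliest arrival time the result equals the
#' background exactly.
#'
#' @param ph An `eca_phantom` from [build_phantom()].
#' @param t Time (s), scalar, >= 0.
#' @return A 3D numeric array of signal values (a.u.).
#' @export
evaluate_phantom <- function(ph, t) {
  stopifnot_scalar(t)
  if (t < 0) rlang::abort("`t` must be >= 0.")
  vol <- ph$background
  pe <- phantom_enhancement(ph, t)
  if (length(pe$index) > 0) vol[pe$index] <- vol[pe$index] + pe$enhancement[, 1]
  vol
}

#' Ground-truth image series at partition midpoints
#'
#' Evaluates the phantom's signal function at the center of the temporal
#' window of each reconstruction interval, producing the reference series
#' against which reconstructions are scored.
#'
#' @param ph An `eca_phantom`.
#' @param partition A `k_partition` from [partition_trajectory()], or any
#'   list with elements `dt` and `n_intervals`.
#' @return An [image_series()] of `n_intervals` real volumes with times at
#'   the interval midpoints.
#' @export
ground_truth_series <- function(ph, partition) {
  n <- partition$n_intervals
  dt <- partition$dt
  if (is.null(n) || n < 1) rlang::abort("Partition must contain at least one interval.")
  mids <- (seq_len(n) - 0.5) * dt
  V <- prod(ph$grid_shape)
  dat <- array(0, dim = c(ph$grid_shape, n))
  pe <- phantom_enhancement(ph, mids)
  for (i in seq_len(n)) {
    vol <- ph$background
    if (length(pe$index) > 0) vol[pe$index] <- vol[pe$index] + pe$enhancement[, i]
    dat[, , , i] <- vol
  }
  image_series(dat, dt = dt, times = mids)
}

#' Per-voxel masked-tissue tibble for a phantom
#'
#' Long view of the phantom's enhancing voxels: one row per lesion or
#' vessel voxel with its linear index, grid coordinates, tissue class and
#' enhancement parameters.
#'
#' @param x An `eca_phantom`.
#' @param ... Unused.
#' @return A tibble with columns `voxel`, `x`, `y`, `z`, `tissue`, `A`,
#'   `alpha`, `t0`.
#' @method as_tibble eca_phantom
#' @export
as_tibble.eca_phantom <- function(x, ...) {
  gs <- x$grid_shape
  coords <- function(idx) {
    k0 <- idx - 1L
    tibble::tibble(x = k0 %% gs[1] + 1L,
                   y = (k0 %/% gs[1]) %% gs[2] + 1L,
                   z = k0 %/% (gs[1] * gs[2]) + 1L)
  }
  les <- dplyr::bind_cols(tibble::tibble(voxel = x$lesion_params$voxel),
                          coords(x$lesion_params$voxel),
                          tibble::tibble(tissue = "lesion", A = x$lesion_params$A,
                                         alpha = x$lesion_params$alpha, t0 = x$lesion_params$t0))
  ves <- dplyr::bind_cols(tibble::tibble(voxel = x$vessel_params$voxel),
                          coords(x$vessel_params$voxel),
                          tibble::tibble(tissue = "vessel", A = NA_real_,
                                         alpha = NA_real_, t0 = x$vessel_params$t0))
  dplyr::bind_rows(les, ves)
}

#' Read or write a phantom configuration as YAML
#'
#' @param config A [phantom_config()].
#' @param path File path.
#' @return `write_phantom_config()` returns `path` invisibly;
#'   `read_phantom_config()` returns a `phantom_config`.
#' @export
write_phantom_config <- function(config, path) {
  cfg <- config
  cfg$signal <- unclass(cfg$signal)
  cfg$aif <- unclass(cfg$aif)
  cfg$background <- if (is.array(cfg$background)) as.numeric(cfg$background) else cfg$background
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vessels <- raw$vessels
  if (!is.null(vessels$centers)) vessels$centers <- lapply(vessels$centers, unlist)
  phantom_config(grid_shape = unlist(raw$grid_shape),
                 lesion = if (is.null(raw$lesion)) NULL else lapply(raw$lesion, unlist),
                 vessels = vessels,
                 background = if (length(raw$background) > 1) array(unlist(raw$background), unlist(raw$grid_shape)) else raw$background,
                 signal = do.call(signal_model_params, raw$signal),
                 aif = do.call(aif_params, raw$aif))
}

#' Export phantom masks and parameter maps as NIfTI volumes
#'
#' Writes `vessel_mask.nii.gz`, `lesion_mask.nii.gz`, `background.nii.gz`
#' and per-parameter maps (`A`, `alpha`, `t0`) into `dir`.
#'
#' @param ph An `eca_phantom`.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of file paths.
#' @export
write_phantom_nifti <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- ph$grid_shape
  files <- character(0)
  wr <- function(arr, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(arr), gs)), p)
    p
  }
  files <- c(files, wr(ph$vessel_mask, "vessel_mask"), wr(ph$lesion_mask, "lesion_mask"),
             wr(ph$background, "background"))
  maps <- list(A = NA, alpha = NA, t0 = NA)
  for (nm in names(maps)) {
    m <- array(0, gs)
    if (nm %in% c("A", "alpha")) {
      m[ph$lesion_params$voxel] <- ph$lesion_params[[nm]]
    } else {
      m[ph$lesion_params$voxel] <- ph$lesion_params$t0
      m[ph$vessel_params$voxel] <- ph$vessel_params$t0
    }
    files <- c(files, wr(m, paste0("param_", nm)))
  }
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
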