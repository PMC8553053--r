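# Shared fixtures: small phantoms, random constrained-reconstruction
# instances, and the dense constrained least-squares oracle used to
# cross-check the ECA solver.

# Small dynamic phantom on a compact grid (one lesion blob, one vessel);
# geometry scales with the grid so every size has enhancing voxels.
small_phantom <- function(grid_shape = c(8, 8, 4), seed = 1,
                          lesion_sd = c(0, 0, 0), vessels = TRUE) {
  gs <- grid_shape
  cfg <- phantom_config(
    grid_shape = gs,
    lesion = list(center = pmax(round(gs * c(0.35, 0.7, 0.5)), 1),
                  radii = pmax(gs / 5, 1.1),
                  A = c(1.56, lesion_sd[1]), alpha = c(0.14, lesion_sd[2]),
                  t0 = c(15, lesion_sd[3])),
    vessels = if (vessels) list(centers = list(pmax(round(c(gs[2] * 0.25, gs[3] * 0.5)), 1)),
                                radius = 1.1,
                                t0_base = 8, t0_span = 2) else NULL)
  build_phantom(cfg, seed = seed)
}

# Phantom with a single enhancing lesion voxel given by explicit masks.
one_voxel_phantom <- function(grid_shape = c(4, 4, 2), voxel = c(2, 3, 1),
                              A = 1.56, alpha = 0.14, t0 = 15) {
  mask <- array(FALSE, grid_shape)
  mask[voxel[1], voxel[2], voxel[3]] <- TRUE
  cfg <- phantom_config(grid_shape = grid_shape,
                        lesion = list(mask = mask, A = c(A, 0),
                                      alpha = c(alpha, 0), t0 = c(t0, 0)),
                        vessels = NULL)
  build_phantom(cfg, seed = 1)
}

# Hand-built partition (no trajectory needed).
manual_partition <- function(interval, dt, n_intervals) {
  structure(list(interval = as.integer(interval), dt = dt,
                 n_intervals = as.integer(n_intervals),
                 midpoints = (seq_len(n_intervals) - 0.5) * dt,
                 duration = n_intervals * dt,
                 counts = dplyr::count(tibble::tibble(interval = interval),
                                       interval, name = "n_samples")),
            class = "k_partition")
}

# Random constrained-reconstruction instance: every (frequency, interval)
# pair is measured independently with probability p_meas; measured values
# are arbitrary complex numbers. Returns the k_samples tibble, partition
# and the [T x K] embedding used by the oracle.
random_instance <- function(seed, max_vt = 2048, p_meas = 0.3) {
  set.seed(seed)
  shapes <- list(c(2, 2, 2), c(4, 2, 2), c(4, 4, 2), c(4, 4, 4), c(8, 4, 2))
  gs <- shapes[[sample.int(length(shapes), 1)]]
  V <- prod(gs)
  t_hi <- max(4L, min(48L, max_vt %/% V))
  T_ <- if (t_hi == 4L) 4L else sample(4:t_hi, 1)
  dt <- 0.5
  M <- matrix(stats::runif(T_ * V) < p_meas, T_, V)
  if (!any(M)) M[1, 1] <- TRUE
  Y <- matrix(0 + 0i, T_, V)
  Y[M] <- complex(real = stats::rnorm(sum(M)), imaginary = stats::rnorm(sum(M)))
  pos <- which(M, arr.ind = TRUE)           # (interval, k)
  k0 <- pos[, 2] - 1L
  samples <- tibble::tibble(
    sample = seq_len(nrow(pos)),
    kx = (k0 %% gs[1]) + 1L,
    ky = ((k0 %/% gs[1]) %% gs[2]) + 1L,
    kz = (k0 %/% (gs[1] * gs[2])) + 1L,
    time = (pos[, 1] - 0.5) * dt,
    value = Y[M]
  )
  samples <- structure(samples, grid_shape = as.integer(gs),
                       sweep_time = T_ * dt, n_sweeps = 1L,
                       update_interval = NA_real_, noise = NULL,
                       class = c("k_samples", class(tibble::tibble())))
  list(samples = samples, partition = manual_partition(pos[, 1], dt, T_),
       M = M, Y = Y, gs = gs, T_ = T_, V = V)
}

# Independent dense oracle: build the full least-squares system
#   minimize || W^(1/2) D F^(-1) y ||^2 + lambda ||y||^2
# over the stacked Fourier series y = vec(Y) (t fastest), with measured
# entries eliminated as constants, and solve the dense normal equations.
# Construction uses only base linear algebra plus the FFT for the DFT
# matrix; it shares no code with the CG solver.
dense_eca_oracle <- function(inst, cfg) {
  gs <- inst$gs; V <- inst$V; T_ <- inst$T_
  Finv <- vapply(seq_len(V), function(j) {
    e <- numeric(V); e[j] <- 1
    as.vector(stats::fft(array(e, gs), inverse = TRUE)) / sqrt(V)
  }, complex(V))
  D <- diff(diag(T_), differences = cfg$diff_order)
  w <- if (is.null(cfg$weights)) rep(1, V) else as.vector(cfg$weights)
  diag_scale <- if (cfg$diff_order == 1) {
    if (T_ >= 3) 2 else 1
  } else if (T_ >= 5) 6 else 4
  lambda <- cfg$lambda_rel * diag_scale * max(w)
  B <- kronecker(diag(sqrt(w)) %*% Finv, D)
  Baug <- rbind(B, sqrt(lambda) * diag(T_ * V))
  m <- which(as.vector(inst$M))
  f <- setdiff(seq_len(T_ * V), m)
  zm <- as.vector(inst$Y)[m]
  Bf <- Baug[, f, drop = FALSE]
  Bm <- Baug[, m, drop = FALSE]
  H <- Conj(t(Bf)) %*% Bf
  rhs <- -Conj(t(Bf)) %*% (Bm %*% zm)
  zf <- solve(H, rhs)
  y <- complex(T_ * V)
  y[m] <- zm
  y[f] <- zf
  matrix(y, T_, V)
}

# k-space [T x K] matrix of a reconstructed series.
series_kspace <- function(series) {
  if (!is.null(series$kspace)) return(series$kspace)
  t(vapply(seq_len(series$n_times),
           function(t) as.vector(ecarecon::ufft(series$data[, , , t])),
           complex(prod(series$grid_shape))))
}
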