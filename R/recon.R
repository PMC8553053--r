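# Image reconstruction from time-tagged k-space.
#
# IFFT baseline: one inverse FFT per Nyquist-complete sweep.
#
# ECA: minimize the quadratic temporal-smoothness penalty
#   sum_v w_v sum_t |Delta X_v(t)|^2  +  lambda * sum |X|^2
# over the image series X = (X_1, ..., X_T), subject to the hard
# constraint that every measured Fourier entry of X~_t equals the value
# acquired during interval t. Constraints are handled by variable
# elimination (only unmeasured Fourier entries are optimized, measured
# entries enter as constants), so data fidelity holds bit-exactly. The
# normal equations are solved by conjugate gradient. With uniform voxel
# weights, Parseval (unitary FFT) separates the problem per k-frequency
# and the operator needs no FFTs; with non-uniform weights each operator
# application transforms to the voxel domain and back.

#' ECA reconstruction configuration
#'
#' @param lambda_rel Tikhonov regularization strength relative to the
#'   penalty's diagonal scale (the actual `lambda` is `lambda_rel` times
#'   the largest diagonal entry of the temporal difference operator's
#'   normal matrix). `0` disables regularization.
#' @param tol CG stopping tolerance on the relative residual.
#' @param max_iter Maximum CG iterations; non-convergence is flagged on
#'   the returned solver log (and warned), never silent.
#' @param diff_order Temporal difference order of the penalty: 1
#'   (default; gives the spline-like piecewise-linear behavior between
#'   measurements) or 2.
#' @param weights Optional per-voxel penalty weight volume (3D array,
#'   >= 0). `NULL` means uniform weights.
#' @param init CG initialization: `"zero"` (zero-filling) or `"static"`
#'   (a static pre-contrast volume replicated over time; reduces the
#'   end-point undershoot).
#' @param init_volume 3D image volume for `init = "static"`.
#' @return A list of class `eca_config`.
#' @export
eca_config <- function(lambda_rel = 1e-3, tol = 1e-8, max_iter = 500L,
                       diff_order = 1L, weights = NULL,
                       init = c("zero", "static"), init_volume = NULL) {
  init <- match.arg(init)
  if (lambda_rel < 0) rlang::abort("`lambda_rel` must be >= 0.")
  if (tol <= 0) rlang::abort("`tol` must be positive.")
  if (!diff_order %in% c(1L, 2L)) rlang::abort("`diff_order` must be 1 or 2.")
  if (!is.null(weights) && any(weights < 0)) rlang::abort("`weights` must be >= 0.")
  if (init == "static" && is.null(init_volume)) {
    rlang::abort("`init = \"static\"` requires `init_volume`.")
  }
  structure(list(lambda_rel = lambda_rel, tol = tol, max_iter = as.integer(max_iter),
                 diff_order = as.integer(diff_order), weights = weights,
                 init = init, init_volume = init_volume),
            class = "eca_config")
}

# Temporal forward difference of the configured order on a [T x K]
# matrix (rows = time), and its adjoint.
tdiff <- function(Z, order = 1L) {
  for (i in seq_len(order)) Z <- Z[-1, , drop = FALSE] - Z[-nrow(Z), , drop = FALSE]
  Z
}

tdiff_adj <- function(R, order = 1L) {
  zero <- function(m) matrix(0 + 0i, 1, ncol(m))
  for (i in seq_len(order)) R <- rbind(zero(R), R) - rbind(R, zero(R))
  R
}

# Largest diagonal entry of D^T D for first/second differences (T >= 2).
penalty_diag_scale <- function(T_, order) {
  if (order == 1L) {
    if (T_ >= 3) 2 else 1
  } else {
    if (T_ >= 5) 6 else 4
  }
}

#' Temporal smoothness penalty of an image series
#'
#' `sum_v w_v sum_t |Delta X_v(t)|^2 + lambda * sum |X|^2` with `Delta`
#' the configured temporal difference. Non-negative; with `lambda = 0`
#' it is zero iff the series is temporally constant.
#'
#' @param x An [image_series()] (real or complex), or a `[V x T]` matrix.
#' @param cfg An [eca_config()].
#' @return Scalar penalty value.
#' @export
smoothness_penalty <- function(x, cfg = eca_config()) {
  m <- if (inherits(x, "image_series")) matrix(x$data, nrow = prod(x$grid_shape)) else as.matrix(x)
  T_ <- ncol(m)
  if (T_ < 2) rlang::abort("Penalty requires at least 2 time points.")
  w <- if (is.null(cfg$weights)) rep(1, nrow(m)) else as.vector(cfg$weights)
  D <- tdiff(t(m), cfg$diff_order)               # [(T-order) x V]
  lambda <- cfg$lambda_rel * penalty_diag_scale(T_, cfg$diff_order) * max(w)
  sum(w * colSums(Mod(D)^2)) + lambda * sum(Mod(m)^2)
}

# Measured-entry embedding: [T x K] value matrix and logical mask from a
# sample set and partition. Duplicate measurements of the same
# (frequency, interval) pair are averaged.
measured_embedding <- function(samples, partition) {
  gs <- attr(samples, "grid_shape")
  K <- prod(gs)
  T_ <- partition$n_intervals
  idx <- linear_index(samples$kx, samples$ky, samples$kz, gs)
  pos <- (idx - 1L) * T_ + partition$interval     # [T x K] linear position
  agg_re <- rowsum(Re(samples$value), pos)
  agg_im <- rowsum(Im(samples$value), pos)
  cnt <- rowsum(rep(1L, length(pos)), pos)
  upos <- as.integer(rownames(agg_re))
  M <- matrix(FALSE, T_, K)
  Y <- matrix(0 + 0i, T_, K)
  M[upos] <- TRUE
  Y[upos] <- complex(real = agg_re / cnt, imaginary = agg_im / cnt)
  list(Y = Y, M = M, n_dup = sum(cnt > 1))
}

# The CG normal operator restricted to free entries: A(Z) =
# P_free (D^T W D + lambda I) applied to a [T x K] matrix that is zero at
# measured entries. With uniform weights the voxel-domain weighting
# commutes with the FFT and no transforms are needed.
eca_apply <- function(Z, M, cfg, lambda, grid_shape = NULL) {
  G <- eca_apply_full(Z, cfg, lambda, grid_shape)
  G[M] <- 0 + 0i
  G
}

#' Apply the ECA normal operator to a free-entry image series
#'
#' The linear operator inside the conjugate-gradient solve:
#' `A = P_free (D^T W D + lambda I) P_free` acting on the unmeasured
#' Fourier entries (measured entries are eliminated as constants). The
#' operator is self-adjoint and positive semidefinite (definite when
#' `lambda > 0`).
#'
#' @param Y Complex `[T x K]` matrix (rows = reconstruction intervals,
#'   columns = linearized k-frequencies), zero at measured entries.
#' @param cfg An [eca_config()].
#' @param measured Logical `[T x K]` mask of measured entries.
#' @param grid_shape Grid shape (needed only for non-uniform weights).
#' @return Complex `[T x K]` matrix `A %*% Y` (zero at measured entries).
#' @export
normal_operator_apply <- function(Y, cfg = eca_config(), measured, grid_shape = NULL) {
  stopifnot(is.matrix(Y), identical(dim(Y), dim(measured)))
  w <- if (is.null(cfg$weights)) 1 else max(cfg$weights)
  lambda <- cfg$lambda_rel * penalty_diag_scale(nrow(Y), cfg$diff_order) * w
  Z <- Y
  Z[measured] <- 0 + 0i
  eca_apply(Z, measured, cfg, lambda, grid_shape)
}

# Conjugate gradient on the free-entry normal equations. With uniform
# voxel weights the operator is block-diagonal per k-frequency, so the
# columns are independent systems and CG runs batched with per-column
# step sizes; non-uniform weights couple the columns through the voxel
# domain and CG runs globally on the stacked system.
eca_cg <- function(b, M, cfg, lambda, grid_shape, Z0 = NULL) {
  T_ <- nrow(b); K <- ncol(b)
  per_col <- is.null(cfg$weights)
  csum <- if (per_col) function(m) colSums(m) else function(m) sum(m)
  scale_cols <- if (per_col) {
    function(m, a) m * rep(a, each = T_)
  } else {
    function(m, a) m * a
  }
  Z <- if (is.null(Z0)) matrix(0 + 0i, T_, K) else Z0
  r <- b - eca_apply(Z, M, cfg, lambda, grid_shape)
  p <- r
  rho <- csum(Mod(r)^2)
  # convergence is judged against the larger of the RHS norm and the
  # initial residual, so columns with b = 0 but a nonzero start (e.g.
  # static init under Tikhonov) still iterate to their solution
  ref <- pmax(sqrt(csum(Mod(b)^2)), sqrt(rho))
  active <- ref > 0
  tol2 <- (cfg$tol * pmax(ref, .Machine$double.xmin))^2
  iter <- 0L
  while (iter < cfg$max_iter && any(rho[active] > tol2[active])) {
    Ap <- eca_apply(p, M, cfg, lambda, grid_shape)
    pAp <- csum(Re(Conj(p) * Ap))
    alpha <- ifelse(pAp > 0, rho / pAp, 0)
    Z <- Z + scale_cols(p, alpha)
    r <- r - scale_cols(Ap, alpha)
    rho_new <- csum(Mod(r)^2)
    beta <- ifelse(rho > 0, rho_new / rho, 0)
    p <- r + scale_cols(p, beta)
    rho <- rho_new
    iter <- iter + 1L
  }
  rel <- sqrt(rho) / pmax(ref, .Machine$double.xmin)
  list(Z = Z, iterations = iter,
       final_residual = if (any(active)) max(rel[active]) else 0,
       converged = all(rho[active] <= tol2[active]))
}

#' ECA reconstruction
#'
#' Reconstructs an image series at the temporal resolution of the
#' partition by minimizing the temporal smoothness penalty subject to
#' exact agreement with every measured k-space entry in its time
#' interval. Measured Fourier entries of the output match the data
#' bit-exactly; unmeasured entries are solved by conjugate gradient on
#' the eliminated normal equations. When every interval is fully sampled
#' the constraints determine the solution completely and the output
#' equals the sweep IFFT reconstruction.
#'
#' @param samples A `k_samples` tibble.
#' @param partition A `k_partition` consistent with the sample
#'   timestamps.
#' @param cfg An [eca_config()].
#' @return A complex [image_series()] with `dt = partition$dt`; element
#'   `solver` carries the CG log (`iterations`, `final_residual`,
#'   `converged`, `lambda`, `n_duplicate_measurements`).
#' @export
eca_reconstruct <- function(samples, partition, cfg = eca_config()) {
  gs <- attr(samples, "grid_shape")
  K <- prod(gs)
  T_ <- partition$n_intervals
  if (length(partition$interval) != nrow(samples)) {
    rlang::abort("Partition does not match the sample set.")
  }
  emb <- measured_embedding(samples, partition)
  wmax <- if (is.null(cfg$weights)) 1 else max(cfg$weights)
  lambda <- cfg$lambda_rel * penalty_diag_scale(T_, cfg$diff_order) * wmax

  b <- -eca_apply(emb$Y, emb$M, cfg, lambda, gs)
  Z0 <- NULL
  if (cfg$init == "static") {
    kvol <- as.vector(ufft(array(cfg$init_volume, gs)))
    Z0 <- matrix(kvol, T_, K, byrow = TRUE)
    Z0[emb$M] <- 0 + 0i
  }
  sol <- eca_cg(b, emb$M, cfg, lambda, gs, Z0 = Z0)
  if (!sol$converged) {
    rlang::warn(sprintf(
      "ECA CG did not reach tol %.1e in %d iterations (final residual %.2e).",
      cfg$tol, cfg$max_iter, sol$final_residual))
  }
  Y <- sol$Z
  Y[emb$M] <- emb$Y[emb$M]
  dat <- array(0 + 0i, c(gs, T_))
  for (t in seq_len(T_)) dat[, , , t] <- uifft(array(Y[t, ], gs))
  image_series(dat, dt = partition$dt, times = partition$midpoints,
               kspace = Y,
               solver = list(iterations = sol$iterations,
                             final_residual = sol$final_residual,
                             converged = sol$converged, lambda = lambda,
                             n_duplicate_measurements = emb$n_dup))
}

# Unrestricted normal operator (D^T W D + lambda I) on a [T x K] matrix.
eca_apply_full <- function(Z, cfg, lambda, grid_shape) {
  T_ <- nrow(Z)
  if (is.null(cfg$weights)) {
    tdiff_adj(tdiff(Z, cfg$diff_order), cfg$diff_order) + lambda * Z
  } else {
    w <- as.vector(cfg$weights)
    K <- ncol(Z)
    X <- matrix(0 + 0i, T_, K)
    for (t in seq_len(T_)) X[t, ] <- as.vector(uifft(array(Z[t, ], grid_shape)))
    DX <- tdiff(X, cfg$diff_order)
    G_img <- tdiff_adj(DX * rep(w, each = nrow(DX)), cfg$diff_order)
    G <- matrix(0 + 0i, T_, K)
    for (t in seq_len(T_)) G[t, ] <- as.vector(ufft(array(G_img[t, ], grid_shape)))
    G + lambda * Z
  }
}

#' Sweep-by-sweep IFFT reconstruction
#'
#' The conventional ultrafast baseline: assembles each Nyquist-complete
#' sweep into a full k-space grid and applies one unitary inverse FFT per
#' sweep, producing one volume per sweep time.
#'
#' @param samples A `k_samples` tibble containing whole sweeps.
#' @return A complex [image_series()] with `dt` equal to the sweep time.
#' @export
ifft_reconstruct <- function(samples) {
  meta <- samples_meta(samples)
  grids <- assemble_sweeps(samples)
  T_ <- length(grids)
  dat <- array(0 + 0i, c(meta$grid_shape, T_))
  for (s in seq_len(T_)) dat[, , , s] <- uifft(grids[[s]])
  image_series(dat, dt = meta$sweep_time,
               times = (seq_len(T_) - 0.5) * meta$sweep_time)
}
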