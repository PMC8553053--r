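test_that("smoothness penalty matches hand-computed values", {
  cfg0 <- eca_config(lambda_rel = 0)
  # single voxel, series (0, 1, 0), first differences: 1^2 + (-1)^2 = 2
  expect_equal(smoothness_penalty(matrix(c(0, 1, 0), 1, 3), cfg0), 2)
  expect_equal(smoothness_penalty(matrix(5, 1, 7), cfg0), 0)
  # linearity in the per-voxel weights (lambda = 0)
  m <- matrix(rnorm(12), 2, 6)
  w1 <- eca_config(lambda_rel = 0, weights = array(1, c(2, 1, 1)))
  w2 <- eca_config(lambda_rel = 0, weights = array(2, c(2, 1, 1)))
  expect_equal(smoothness_penalty(m, w2), 2 * smoothness_penalty(m, w1))
  # second differences: (0,1,0) -> (0 - 2 + 0)^2 = 4
  expect_equal(smoothness_penalty(matrix(c(0, 1, 0), 1, 3),
                                  eca_config(lambda_rel = 0, diff_order = 2)), 4)
  # Tikhonov term: lambda = lambda_rel * diag scale (= 2 for T >= 3)
  expect_equal(smoothness_penalty(matrix(c(0, 1, 0), 1, 3),
                                  eca_config(lambda_rel = 0.5)), 2 + 1 * 2 * 0.5)
  expect_error(smoothness_penalty(matrix(1, 1, 1), cfg0))
  expect_error(eca_config(lambda_rel = -1))
  expect_error(eca_config(diff_order = 3))
})

test_that("IFFT reconstruction assembles one volume per sweep", {
  ph <- small_phantom(grid_shape = c(6, 6, 4))
  tr <- unwrap_trajectory(c(6, 6, 4), sweep_time = 3.5, f = 4, n_sweeps = 16)
  s <- acquire(ph, tr)
  rec <- ifft_reconstruct(s)
  expect_equal(rec$n_times, 16)                      # 56 s / 3.5 s
  expect_equal(rec$dt, 3.5)
  # compositional consistency: each k-entry of frame s equals the sample
  # acquired at that entry's time (FFT of frame == assembled sweep grid)
  g2 <- ufft(rec$data[, , , 2])
  sel <- s$time >= 3.5 & s$time < 7
  idx <- (s$kz[sel] - 1) * 36 + (s$ky[sel] - 1) * 6 + s$kx[sel]
  expect_equal(max(Mod(g2[idx] - s$value[sel])), 0, tolerance = 1e-12)
  # incomplete sweep rejected
  expect_error(ifft_reconstruct(s[-5, ]), "Nyquist")
})

test_that("fully sampled intervals make ECA equal IFFT", {
  ph <- small_phantom(grid_shape = c(6, 6, 2))
  tr <- unwrap_trajectory(c(6, 6, 2), sweep_time = 3.5, f = 4, n_sweeps = 4)
  s <- add_noise(acquire(ph, tr), 0.001, seed = 2)
  part <- partition_trajectory(tr, 3.5)
  eca <- eca_reconstruct(s, part, eca_config())
  rec <- ifft_reconstruct(s)
  expect_equal(max(Mod(eca$data - rec$data)), 0, tolerance = 1e-12)
})

test_that("ECA recovers a static noiseless phantom exactly at every t", {
  ph <- build_phantom(phantom_config(grid_shape = c(6, 6, 2), lesion = NULL,
                                     vessels = NULL), seed = 1)
  tr <- unwrap_trajectory(c(6, 6, 2), sweep_time = 3.5, f = 6, n_sweeps = 4)
  s <- acquire(ph, tr)
  part <- partition_trajectory(tr, 0.25)
  eca <- eca_reconstruct(s, part, eca_config(lambda_rel = 0, tol = 1e-12))
  expect_equal(max(Mod(sweep(eca$data, 1:3, ph$background, `-`))), 0,
               tolerance = 1e-10)
})

test_that("measured k-space entries are honored bit-exactly", {
  inst <- random_instance(11)
  eca <- eca_reconstruct(inst$samples, inst$partition, eca_config())
  expect_identical(eca$kspace[inst$M], inst$Y[inst$M])
})

test_that("lambda = 0 uniform-weight ECA is per-frequency linear interpolation", {
  ph <- small_phantom(grid_shape = c(4, 4, 4))
  tr <- unwrap_trajectory(c(4, 4, 4), sweep_time = 2, f = 4, n_sweeps = 6)
  s <- acquire(ph, tr)
  part <- partition_trajectory(tr, 0.5)
  eca <- eca_reconstruct(s, part, eca_config(lambda_rel = 0, tol = 1e-12,
                                             max_iter = 2000))
  emb <- ecarecon:::measured_embedding(s, part)
  T_ <- part$n_intervals
  Y <- matrix(0 + 0i, T_, 64)
  for (k in seq_len(64)) {
    mt <- which(emb$M[, k])
    Y[, k] <- complex(
      real = stats::approx(mt, Re(emb$Y[mt, k]), xout = seq_len(T_), rule = 2)$y,
      imaginary = stats::approx(mt, Im(emb$Y[mt, k]), xout = seq_len(T_), rule = 2)$y)
  }
  expect_lt(max(Mod(eca$kspace - Y)), 1e-9 * max(Mod(Y)))
})

test_that("ECA matches the dense constrained least-squares oracle", {
  inst <- random_instance(101, max_vt = 512)
  cfg <- eca_config(tol = 1e-13, max_iter = 5000)
  eca <- eca_reconstruct(inst$samples, inst$partition, cfg)
  oracle <- dense_eca_oracle(inst, cfg)
  rel <- sqrt(sum(Mod(eca$kspace - oracle)^2) / sum(Mod(oracle)^2))
  expect_lt(rel, 1e-8)
  # non-uniform per-voxel weights follow the same normal equations
  set.seed(202)
  w <- array(runif(inst$V, 0.2, 3), inst$gs)
  cfgw <- eca_config(tol = 1e-13, max_iter = 5000, weights = w)
  ecaw <- eca_reconstruct(inst$samples, inst$partition, cfgw)
  oraclew <- dense_eca_oracle(inst, cfgw)
  relw <- sqrt(sum(Mod(ecaw$kspace - oraclew)^2) / sum(Mod(oraclew)^2))
  expect_lt(relw, 1e-8)
})

test_that("the normal operator is self-adjoint, PSD and Tikhonov-bounded", {
  set.seed(7)
  inst <- random_instance(7, max_vt = 256)
  T_ <- inst$T_; K <- inst$V
  rz <- function() {
    m <- matrix(complex(real = rnorm(T_ * K), imaginary = rnorm(T_ * K)), T_, K)
    m[inst$M] <- 0 + 0i
    m
  }
  ip <- function(a, b) sum(Conj(a) * b)
  for (cfg in list(eca_config(lambda_rel = 1e-3),
                   eca_config(lambda_rel = 0.05, diff_order = 2),
                   eca_config(lambda_rel = 1e-2,
                              weights = array(runif(K, 0.5, 2), inst$gs)))) {
    lambda <- cfg$lambda_rel *
      ecarecon:::penalty_diag_scale(T_, cfg$diff_order) *
      (if (is.null(cfg$weights)) 1 else max(cfg$weights))
    for (rep in 1:3) {
      y <- rz(); z <- rz()
      Ay <- normal_operator_apply(y, cfg, inst$M, inst$gs)
      Az <- normal_operator_apply(z, cfg, inst$M, inst$gs)
      expect_lt(Mod(ip(Ay, z) - ip(y, Az)), 1e-10 * sqrt(sum(Mod(y)^2) * sum(Mod(z)^2)))
      expect_gte(Re(ip(Ay, y)), 0)
      expect_gte(Re(ip(Ay, y)), lambda * sum(Mod(y)^2) * (1 - 1e-10))
    }
  }
})

test_that("regularized solutions are unique and init-independent", {
  inst <- random_instance(31, max_vt = 256)
  cfg0 <- eca_config(tol = 1e-12, max_iter = 5000)
  e1 <- eca_reconstruct(inst$samples, inst$partition, cfg0)
  init_vol <- array(rnorm(inst$V), inst$gs)
  cfg1 <- eca_config(tol = 1e-12, max_iter = 5000, init = "static",
                     init_volume = init_vol)
  e2 <- eca_reconstruct(inst$samples, inst$partition, cfg1)
  expect_lt(max(Mod(e1$kspace - e2$kspace)), 1e-7 * max(Mod(e1$kspace)))
  expect_true(e1$solver$converged)
  expect_gt(e1$solver$iterations, 0)
})

test_that("zero-fill init with regularization undershoots at the end points", {
  # constant phantom: every frequency's time course should be constant;
  # with zero-fill + Tikhonov the reconstruction decays toward zero
  # outside the measured range, reproducing the end-point undershoot
  ph <- build_phantom(phantom_config(grid_shape = c(4, 4, 2), lesion = NULL,
                                     vessels = NULL, background = 2), seed = 1)
  tr <- unwrap_trajectory(c(4, 4, 2), sweep_time = 2, f = 8, n_sweeps = 4)
  s <- acquire(ph, tr)
  part <- partition_trajectory(tr, 0.25)
  und <- function(lr) {
    e <- eca_reconstruct(s, part, eca_config(lambda_rel = lr, tol = 1e-12,
                                             max_iter = 5000))
    dc <- e$kspace[, 1]                      # DC frequency time course
    mt <- range(which(ecarecon:::measured_embedding(s, part)$M[, 1]))
    c(first = Mod(dc[mt[1]]) - Mod(dc[1]),
      last = Mod(dc[mt[2]]) - Mod(dc[length(dc)]))
  }
  u_big <- und(0.05)
  u_small <- und(1e-4)
  expect_gt(u_big["first"], 0)
  expect_gt(u_big["last"], 0)
  # undershoot shrinks as lambda -> 0
  expect_lt(u_small["first"], u_big["first"])
  expect_lt(u_small["last"], u_big["last"])
})

test_that("non-convergence is flagged, never silent", {
  inst <- random_instance(55, max_vt = 256)
  expect_warning(
    e <- eca_reconstruct(inst$samples, inst$partition,
                         eca_config(tol = 1e-14, max_iter = 1L)),
    "did not reach")
  expect_false(e$solver$converged)
})

test_that("image series NIfTI and CSV round-trips preserve data", {
  ph <- small_phantom(grid_shape = c(4, 4, 2))
  tr <- unwrap_trajectory(c(4, 4, 2), 2, 2, n_sweeps = 3)
  rec <- ifft_reconstruct(add_noise(acquire(ph, tr), 0.001, seed = 1))
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_image_series_nifti(rec, nii)
  back <- read_image_series_nifti(nii)
  expect_equal(back$dt, rec$dt, tolerance = 1e-6)
  mag <- ecarecon:::series_matrix(rec)
  expect_equal(ecarecon:::series_matrix(back), mag, tolerance = 1e-6)  # float32
  csv <- withr::local_tempfile(fileext = ".csv")
  write_image_series_csv(rec, csv)
  back2 <- read_image_series_csv(csv)
  expect_identical(back2$data, rec$data)                               # exact
  expect_identical(back2$times, rec$times)
})
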