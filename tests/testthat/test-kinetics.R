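test_that("vessel BAT is the earliest time of peak enhancement", {
  times <- c(0.125, 0.375, 0.625, 0.875, 1.125)
  expect_equal(bat_vessel(data.frame(time = times, value = c(0, 1, 5, 2, 1))),
               0.625)
  # ties resolve to the earlier time
  expect_equal(bat_vessel(data.frame(time = times, value = c(0, 5, 1, 5, 0))),
               0.375)
  expect_true(is.na(bat_vessel(data.frame(time = times, value = rep(2, 5)))))
  expect_error(bat_vessel(data.frame(time = 1:2, value = 1:2)))
  # noiseless sampled Parker curve: within one dt of the dense-grid peak
  dt <- 0.25
  ts <- seq(0.125, 60, by = dt)
  cur <- data.frame(time = ts, value = parker_aif(ts, t0 = 10))
  dense <- seq(0, 60, by = 0.001)
  ref <- dense[which.max(parker_aif(dense, t0 = 10))]
  expect_lt(abs(bat_vessel(cur) - ref), dt)
})

test_that("lesion BAT is the earliest 20%-of-maximum crossing", {
  times <- c(1, 2, 3, 4, 5)
  cur <- data.frame(time = times, enhancement = c(0, 0, 0.1, 0.3, 0.5))
  expect_equal(bat_lesion(cur), 3)                  # 0.1 >= 0.2 * 0.5
  # monotone curve: unique crossing
  mono <- data.frame(time = times, enhancement = c(0, 0.05, 0.2, 0.6, 1))
  expect_equal(bat_lesion(mono), 3)
  expect_true(is.na(bat_lesion(data.frame(time = times, enhancement = rep(0, 5)))))
  # estimator-on-truth reference for the empirical lesion model
  p <- emm_params(1.56, 0.14, 15)
  dense <- seq(0, 56, by = 0.001)
  ref <- bat_lesion(data.frame(time = dense,
                               enhancement = lesion_concentration(dense, p)))
  coarse_t <- seq(0.125, 56, by = 0.25)
  est <- bat_lesion(data.frame(time = coarse_t,
                               enhancement = lesion_concentration(coarse_t, p)))
  expect_lt(abs(est - ref), 0.25)
})

test_that("BAT estimators are shift-equivariant and scale-invariant", {
  set.seed(1)
  for (i in 1:5) {
    ts <- seq(0.125, 40, by = 0.25)
    v <- parker_aif(ts, t0 = 5 + i)
    e <- lesion_concentration(ts, emm_params(1 + i / 5, 0.1, 8 + i))
    delta <- 1.75
    expect_equal(bat_vessel(data.frame(time = ts + delta, value = v)),
                 bat_vessel(data.frame(time = ts, value = v)) + delta)
    expect_equal(bat_lesion(data.frame(time = ts + delta, enhancement = e)),
                 bat_lesion(data.frame(time = ts, enhancement = e)) + delta)
    expect_equal(bat_vessel(data.frame(time = ts, value = 3.7 * v)),
                 bat_vessel(data.frame(time = ts, value = v)))
    expect_equal(bat_lesion(data.frame(time = ts, enhancement = 3.7 * e)),
                 bat_lesion(data.frame(time = ts, enhancement = e)))
  }
})

test_that("modified Akima interpolation reproduces lines and flat segments", {
  x <- seq(0, 10, by = 0.5)
  # linear data: interpolant and derivative exact
  expect_equal(makima(x, 2 * x + 1, seq(0.1, 9.9, by = 0.01)),
               2 * seq(0.1, 9.9, by = 0.01) + 1, tolerance = 1e-12)
  expect_equal(initial_slope_vessel(data.frame(time = x, value = 2 * x + 1)), 2,
               tolerance = 1e-10)
  expect_equal(initial_slope_vessel(data.frame(time = x, value = rep(4, 21))), 0)
  # no overshoot on a flat-then-step sequence (the "modified" weighting)
  y <- c(0, 0, 0, 0, 0, 1, 2, 3, 3, 3, 3)
  xs <- seq_along(y)
  vals <- makima(xs, y, seq(1, 5, by = 0.01))
  expect_lt(max(abs(vals)), 1e-12)                   # flat segment stays flat
  expect_error(makima(1:4, 1:4, 2))
})

test_that("Akima max-derivative matches a dense finite-difference oracle", {
  # densely sampled smooth section of the AIF (past the onset, where the
  # truncated model is continuous)
  ts <- seq(9, 40, by = 0.05)
  cur <- data.frame(time = ts, value = parker_aif(ts, t0 = 8))
  slope <- initial_slope_vessel(cur)
  dense <- seq(9, 40, by = 0.001)
  fd <- max(diff(parker_aif(dense, t0 = 8)) / 0.001)
  expect_equal(slope, fd, tolerance = 0.02)
})

test_that("EMM PSE fit recovers parameters on noiseless curves", {
  ts <- seq(0.125, 56, by = 0.25)
  truth <- list(A = 100, alpha = 0.14, t0 = 15)
  pse <- 100 * (1 - exp(-0.14 * pmax(ts - 15, 0)))
  fit <- fit_emm_pse(data.frame(time = ts, pse = pse))
  expect_true(fit$converged)
  expect_equal(fit$A, truth$A, tolerance = 1e-4)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-4)
  expect_equal(fit$t0, truth$t0, tolerance = 1e-4)
  expect_equal(fit$slope, truth$A * truth$alpha, tolerance = 1e-4)
  # time-shift equivariance
  fit2 <- fit_emm_pse(data.frame(time = ts + 3, pse = pse))
  expect_equal(fit2$t0, truth$t0 + 3, tolerance = 1e-3)
  expect_equal(fit2$A, truth$A, tolerance = 1e-3)
  expect_equal(fit2$alpha, truth$alpha, tolerance = 1e-3)
  # all-zero curve
  fit0 <- fit_emm_pse(data.frame(time = ts, pse = rep(0, length(ts))))
  expect_equal(fit0$A, 0)
  expect_equal(fit0$slope, 0)
  # alternative (rational) uptake model is pluggable and self-consistent
  pser <- 80 * 0.1 * pmax(ts - 12, 0)^2 / (1 + 0.1 * pmax(ts - 12, 0)^2)
  fitr <- fit_emm_pse(data.frame(time = ts, pse = pser), model = "rational")
  expect_equal(fitr$A, 80, tolerance = 1e-3)
  expect_equal(fitr$t0, 12, tolerance = 1e-3)
  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, c("A", "alpha", "t0", "slope"))
  expect_true(glance(fit)$converged)
})

test_that("paired error ratios summarize method comparisons", {
  err_b <- c(1, 2, 3, 4, 5, 6, 8, 10)
  st <- paired_error_ratio(err_b / 2, err_b, n_boot = 200)
  expect_equal(st$median, 0.5)
  expect_equal(st$improvement, 2)
  st1 <- paired_error_ratio(err_b, err_b, n_boot = 200)
  expect_equal(st1$median, 1)
  # zero denominators excluded and counted
  st2 <- paired_error_ratio(c(err_b / 2, 1), c(err_b, 0), n_boot = 200)
  expect_equal(st2$n_zero_denom, 1)
  expect_equal(st2$n, 8)
  expect_error(paired_error_ratio(numeric(0), numeric(0)))
  expect_identical(nrow(tidy(st)), 1L)
  expect_identical(glance(st)$n, 8L)
})

test_that("median CI from the bootstrap covers at the nominal rate", {
  # lognormal ratios; 95% (z = 1.96) interval, coverage within MC error
  set.seed(42)
  true_med <- exp(0.3)
  n <- 400; reps <- 100
  hits <- vapply(seq_len(reps), function(i) {
    r <- stats::rlnorm(n, meanlog = 0.3, sdlog = 0.8)
    st <- paired_error_ratio(r, rep(1, n), conf_z = 1.96, n_boot = 200, seed = i)
    st$ci_low <= true_med && true_med <= st$ci_high
  }, logical(1))
  cov <- mean(hits)
  expect_gte(cov, 0.88)
  expect_lte(cov, 1.0)
})

test_that("voxel error statistics summarize proportional errors", {
  ph <- small_phantom(grid_shape = c(4, 4, 2))
  tr <- unwrap_trajectory(c(4, 4, 2), 2, 2, n_sweeps = 3)
  truth <- ground_truth_series(ph, partition_trajectory(tr, 2))
  st0 <- voxel_error_stats(truth, truth)
  expect_true(all(st0$summary$median_pct == 0))
  # recon = 1.01 * truth: proportional error exactly 1%, MAD 0
  scaled <- image_series(truth$data * 1.01, dt = truth$dt, times = truth$times)
  st1 <- voxel_error_stats(scaled, truth)
  expect_equal(st1$summary$median_pct, 1, tolerance = 1e-10)
  expect_equal(st1$summary$mad_pct, 0, tolerance = 1e-10)
  # known injected error field reproduces its analytic median / MAD
  set.seed(9)
  e <- rnorm(prod(dim(truth$data)), sd = 0.01)
  noisy <- image_series(truth$data * (1 + 0), dt = truth$dt, times = truth$times)
  noisy$data <- truth$data + array(e, dim(truth$data))
  stn <- voxel_error_stats(noisy, truth, tissue = as_tibble(ph))
  V <- prod(truth$grid_shape)
  per_vox <- rowMeans(abs(matrix(e, V, truth$n_times))) /
    rowMeans(ecarecon:::series_matrix(truth)) * 100
  expect_equal(sort(stn$per_voxel$error_pct), sort(per_vox), tolerance = 1e-10)
  expect_true(all(c("lesion", "vessel", "background") %in% stn$summary$tissue))
  bad <- image_series(truth$data[, , , 1:2, drop = FALSE], dt = truth$dt,
                      times = truth$times[1:2])
  expect_error(voxel_error_stats(bad, truth), "match")
})

test_that("extract_curves computes baselines and PSE and drops end points", {
  ph <- small_phantom(grid_shape = c(8, 8, 4))
  tr <- unwrap_trajectory(c(8, 8, 4), 3.5, 4, n_sweeps = 8)
  truth <- ground_truth_series(ph, partition_trajectory(tr, 3.5))
  vox <- ph$lesion_params$voxel[1]
  cur <- extract_curves(truth, vox, baseline_until = 5, exclude_endpoints = TRUE)
  expect_equal(nrow(cur), 6)                         # 8 frames minus both ends
  expect_false(any(cur$time %in% truth$times[c(1, 8)]))
  expect_equal(unique(cur$baseline), ph$background[vox], tolerance = 1e-12)
  expect_equal(cur$pse, 100 * (cur$value - cur$baseline) / cur$baseline)
})
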