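# Kinetic analysis of reconstructed voxel time courses: bolus arrival
# time (BAT), initial enhancement slope, and the paired error-ratio
# statistics used to compare reconstructions.

#' Extract voxel enhancement curves from an image series
#'
#' Long tibble of magnitude time courses for selected voxels, with a
#' per-voxel baseline (mean signal over the pre-contrast window) and
#' percent signal enhancement `pse = 100 * (S - S0) / S0`. The first and
#' last reconstructed time points can be excluded from kinetic analysis
#' (default), which removes the end-point undershoot of regularized
#' reconstructions from the fits.
#'
#' @param series An [image_series()].
#' @param voxels Linear voxel indices.
#' @param baseline_until Time (s); frames with midpoints strictly before
#'   this are averaged into the baseline. If no frame qualifies the first
#'   frame is used.
#' @param exclude_endpoints Drop the first and last time points.
#' @return Tibble `voxel`, `time`, `value`, `baseline`, `enhancement`,
#'   `pse`.
#' @export
extract_curves <- function(series, voxels, baseline_until = 5,
                           exclude_endpoints = TRUE) {
  df <- as_tibble.image_series(series, voxels = voxels)
  base <- df |>
    dplyr::filter(.data$time < baseline_until) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::summarise(baseline = mean(.data$value), .groups = "drop")
  if (nrow(base) == 0) {
    base <- df |>
      dplyr::filter(.data$time == min(.data$time)) |>
      dplyr::select("voxel", baseline = "value")
  }
  keep <- series$times
  if (exclude_endpoints && length(keep) > 2) keep <- keep[-c(1, length(keep))]
  df |>
    dplyr::filter(.data$time %in% keep) |>
    dplyr::left_join(base, by = "voxel") |>
    dplyr::mutate(enhancement = .data$value - .data$baseline,
                  pse = 100 * .data$enhancement / .data$baseline)
}

#' Bolus arrival time in vessel voxels: time of peak enhancement
#'
#' Returns the time of the global maximum of the curve; on ties the
#' earliest time wins. An all-constant curve has no peak and returns
#' `NA`.
#'
#' @param curve Data frame with `time` and `value` columns (signal or
#'   enhancement; any increasing transform of signal gives the same
#'   answer).
#' @return BAT (s), or `NA_real_` for a flat curve.
#' @export
bat_vessel <- function(curve) {
  t <- curve$time; v <- curve$value
  if (length(t) < 3) rlang::abort("Need at least 3 time points.")
  if (max(v) == min(v)) return(NA_real_)
  t[which.max(v)]
}

#' Bolus arrival time in lesion voxels: 20%-of-maximum rule
#'
#' Earliest time at which enhancement over baseline reaches or exceeds
#' `frac` (default 20%) of its maximum over the curve.
#'
#' @param curve Data frame with `time` and `enhancement` columns (signal
#'   minus baseline), or `time`/`value` already baseline-subtracted.
#' @param frac Threshold fraction of maximum enhancement.
#' @return BAT (s), or `NA_real_` for a non-enhancing voxel.
#' @export
bat_lesion <- function(curve, frac = 0.2) {
  t <- curve$time
  e <- curve$enhancement %||% curve$value
  mx <- max(e)
  if (mx <= 0) return(NA_real_)
  t[which(e >= frac * mx)[1]]
}

# Modified Akima node derivatives: weights
#   w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]| / 2   (right-side)
#   w2 = |d[i-1] - d[i-2]| + |d[i-1] + d[i-2]| / 2 (left-side)
# with secant slopes d extended by quadratic extrapolation at the ends.
# Flat segments get exactly zero derivative (no overshoot).
makima_derivatives <- function(x, y) {
  n <- length(x)
  d <- diff(y) / diff(x)                     # n - 1 secant slopes
  # extend by linear extrapolation of the slope sequence at both ends:
  # de has length n + 3 and de[i + 1] is the secant slope left of node i
  d0 <- 2 * d[1] - d[2]
  dm1 <- 2 * d0 - d[1]
  dn <- 2 * d[n - 1] - d[n - 2]
  dn1 <- 2 * dn - d[n - 1]
  de <- c(dm1, d0, d, dn, dn1)
  der <- numeric(n)
  for (i in seq_len(n)) {
    dl2 <- de[i]; dl1 <- de[i + 1]; dr1 <- de[i + 2]; dr2 <- de[i + 3]
    w1 <- abs(dr2 - dr1) + abs(dr2 + dr1) / 2
    w2 <- abs(dl1 - dl2) + abs(dl1 + dl2) / 2
    der[i] <- if (w1 + w2 == 0) 0 else (w1 * dl1 + w2 * dr1) / (w1 + w2)
  }
  der
}

#' Modified Akima interpolation
#'
#' Piecewise-cubic Hermite interpolant with the modified Akima
#' derivative weighting, which reproduces linear data exactly and
#' avoids overshoot on flat segments.
#'
#' @param x,y Data nodes (x strictly increasing, length >= 5).
#' @param xout Evaluation points.
#' @param deriv 0 for values, 1 for the first derivative.
#' @return Numeric vector of interpolant (or derivative) values.
#' @export
makima <- function(x, y, xout, deriv = 0) {
  n <- length(x)
  if (n < 5) rlang::abort("Modified Akima interpolation needs at least 5 points.")
  if (any(diff(x) <= 0)) rlang::abort("`x` must be strictly increasing.")
  m <- makima_derivatives(x, y)
  i <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  h <- x[i + 1] - x[i]
  s <- (xout - x[i]) / h
  h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2;    h11 <- s^3 - s^2
  if (deriv == 0) {
    h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
  } else {
    d00 <- (6 * s^2 - 6 * s) / h; d10 <- 3 * s^2 - 4 * s + 1
    d01 <- (-6 * s^2 + 6 * s) / h; d11 <- 3 * s^2 - 2 * s
    d00 * y[i] + d10 * m[i] + d01 * y[i + 1] + d11 * m[i + 1]
  }
}

#' Initial enhancement slope in vessel voxels
#'
#' Interpolates the voxel time course with the modified Akima method and
#' returns the maximum of the interpolant's first derivative on a dense
#' grid (default 10 ms).
#'
#' @param curve Data frame with `time` and `value` (or `pse`) columns;
#'   at least 5 points.
#' @param grid_dt Dense evaluation step (s).
#' @return Maximum first derivative (value units per second).
#' @export
initial_slope_vessel <- function(curve, grid_dt = 0.01) {
  t <- curve$time
  v <- curve$pse %||% curve$value
  if (length(t) < 5) rlang::abort("Need at least 5 time points for the Akima slope.")
  grid <- seq(min(t), max(t), by = grid_dt)
  max(makima(t, v, grid, deriv = 1))
}

emm_pse_model <- function(model = c("exp", "rational")) {
  model <- match.arg(model)
  if (model == "exp") {
    function(t, A, alpha, t0) A * (1 - exp(-alpha * pmax(t - t0, 0)))
  } else {
    function(t, A, alpha, t0) {
      u <- pmax(t - t0, 0)
      A * alpha * u^2 / (1 + alpha * u^2)
    }
  }
}

#' Fit the piecewise empirical model to a lesion PSE curve
#'
#' Nonlinear least-squares fit of `PSE(t) = A * (1 - exp(-alpha *
#' (t - t0)))` for `t >= t0` (0 before), whose right-derivative at `t0`
#' is the initial enhancement slope `A * alpha`. The uptake model is
#' pluggable: `model = "rational"` fits
#' `A * alpha * (t - t0)^2 / (1 + alpha * (t - t0)^2)` instead (note its
#' initial slope is 0, so the `A * alpha` slope reading applies only to
#' the default model). Fitting is Levenberg-Marquardt with multiple `t0`
#' starting points; a non-convergent fit is flagged on the result.
#'
#' @param curve Data frame with `time` and `pse` (or `value`) columns,
#'   covering a pre-onset plateau and an uptake phase.
#' @param model Uptake model form.
#' @param n_starts Number of `t0` starting values across the time range.
#' @return An object of class `emm_fit` with elements `A`, `alpha`,
#'   `t0`, `slope` (`A * alpha`), `residual_norm`, `converged`, `model`;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
fit_emm_pse <- function(curve, model = c("exp", "rational"), n_starts = 8) {
  model <- match.arg(model)
  t <- curve$time
  y <- curve$pse %||% curve$value
  fmod <- emm_pse_model(model)
  if (max(y) <= 0) {
    return(structure(list(A = 0, alpha = 0, t0 = NA_real_, slope = 0,
                          residual_norm = sqrt(sum(y^2)), converged = TRUE,
                          model = model, data = tibble::tibble(time = t, pse = y)),
                     class = "emm_fit"))
  }
  df <- data.frame(t = t, y = y)
  t0_grid <- stats::quantile(t, probs = seq(0.05, 0.7, length.out = n_starts))
  best <- NULL
  for (t0s in t0_grid) {
    a0 <- max(y)
    al0 <- max(1 / (max(t) - t0s), 0.05)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ fmod(t, A, alpha, t0),
                        data = df,
                        start = list(A = a0, alpha = al0, t0 = t0s),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::residuals(fit)^2))
      if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NA_real_, alpha = NA_real_, t0 = NA_real_,
                          slope = NA_real_, residual_norm = NA_real_,
                          converged = FALSE, model = model,
                          data = tibble::tibble(time = t, pse = y)),
                     class = "emm_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(A = unname(cf["A"]), alpha = unname(cf["alpha"]),
                 t0 = unname(cf["t0"]), slope = unname(cf["A"] * cf["alpha"]),
                 residual_norm = best$rn, converged = TRUE, model = model,
                 data = tibble::tibble(time = t, pse = y)),
            class = "emm_fit")
}

#' @export
print.emm_fit <- function(x, ...) {
  cat(sprintf("<emm_fit %s> A = %.4g, alpha = %.4g /s, t0 = %.4g s, slope = %.4g (%s)\n",
              x$model, x$A, x$alpha, x$t0, x$slope,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy emm_fit
#' @export
tidy.emm_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "alpha", "t0", "slope"),
                 estimate = c(x$A, x$alpha, x$t0, x$slope))
}

#' @method glance emm_fit
#' @export
glance.emm_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, converged = x$converged,
                 model = x$model, n = nrow(x$data))
}

#' Paired error-ratio statistics for two reconstruction methods
#'
#' Treats per-voxel error ratios (method A error / method B error) as a
#' distribution and reports the median with a `z * SE` confidence
#' interval about it (default `z = 5`, the two-sided level corresponding
#' to p < 1e-6). The standard error of the median is estimated by
#' bootstrap; a normal-approximation order-statistic interval is
#' reported as a cross-check. Voxels with zero denominator error are
#' excluded from the ratio distribution and counted separately.
#'
#' @param err_a,err_b Matched non-negative per-voxel errors (method A:
#'   typically ECA; method B: the IFFT baseline).
#' @param conf_z Half-width of the interval in standard errors.
#' @param n_boot Bootstrap resamples for the SE of the median.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `error_ratio` with `median`, `se`,
#'   `ci_low`, `ci_high`, `ci_order_stat` (cross-check interval), `mad`,
#'   `improvement` (`1 / median`), `n`, `n_zero_denom`; supports
#'   `tidy()` and `glance()`.
#' @export
paired_error_ratio <- function(err_a, err_b, conf_z = 5, n_boot = 1000, seed = 1L) {
  stopifnot(length(err_a) == length(err_b))
  ok <- is.finite(err_a) & is.finite(err_b)
  err_a <- err_a[ok]; err_b <- err_b[ok]
  zero <- err_b == 0
  ratio <- err_a[!zero] / err_b[!zero]
  n <- length(ratio)
  if (n == 0) rlang::abort("No voxels with nonzero denominator error.")
  med <- stats::median(ratio)
  set.seed(seed)
  boot_meds <- vapply(seq_len(n_boot), function(i) {
    stats::median(ratio[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  se <- stats::sd(boot_meds)
  # order-statistic normal approximation at the same level
  p <- stats::pnorm(conf_z)
  k <- stats::qbinom(c(1 - p, p), n, 0.5)
  srt <- sort(ratio)
  ci_os <- srt[pmin(pmax(k, 1), n)]
  structure(list(median = med, se = se,
                 ci_low = med - conf_z * se, ci_high = med + conf_z * se,
                 ci_order_stat = ci_os, conf_z = conf_z,
                 mad = stats::mad(ratio),
                 improvement = 1 / med, n = n,
                 n_zero_denom = sum(zero), ratios = ratio),
            class = "error_ratio")
}

#' @export
print.error_ratio <- function(x, ...) {
  cat(sprintf("<error_ratio> median %.4g +/- %.2g (%g-sigma CI [%.4g, %.4g]), improvement %.3gx, n = %d\n",
              x$median, x$se, x$conf_z, x$ci_low, x$ci_high, x$improvement, x$n))
  invisible(x)
}

#' @method tidy error_ratio
#' @export
tidy.error_ratio <- function(x, ...) {
  tibble::tibble(estimate = x$median, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @method glance error_ratio
#' @export
glance.error_ratio <- function(x, ...) {
  tibble::tibble(median = x$median, se = x$se, mad = x$mad,
                 improvement = x$improvement, n = x$n,
                 n_zero_denom = x$n_zero_denom)
}

#' Voxel-wise image fidelity statistics
#'
#' Proportional absolute voxel error between a reconstruction and the
#' ground truth: `|recon - truth|` per voxel-frame, normalized by the
#' voxel's ground-truth time-mean, averaged over frames, and summarized
#' per tissue class by the median and median absolute deviation (in
#' percent).
#'
#' @param recon,truth [image_series()] objects with matching shapes and
#'   frame counts.
#' @param tissue Optional tibble `voxel`, `tissue` (e.g. from
#'   [as_tibble.eca_phantom()]); unlabeled voxels are summarized as
#'   `"background"`.
#' @return A list with `per_voxel` (tibble `voxel`, `tissue`,
#'   `error_pct`) and `summary` (tibble `tissue`, `median_pct`,
#'   `mad_pct`, `n`).
#' @export
voxel_error_stats <- function(recon, truth, tissue = NULL) {
  if (!identical(recon$grid_shape, truth$grid_shape) ||
      recon$n_times != truth$n_times) {
    rlang::abort("Reconstruction and truth series shapes do not match.")
  }
  R <- series_matrix(recon)
  G <- series_matrix(truth)
  scale <- rowMeans(G)
  scale[scale == 0] <- NA_real_
  err <- rowMeans(abs(R - G)) / scale * 100
  pv <- tibble::tibble(voxel = seq_along(err), error_pct = err)
  if (is.null(tissue)) {
    pv$tissue <- "all"
  } else {
    pv <- dplyr::left_join(pv, tissue[, c("voxel", "tissue")], by = "voxel") |>
      dplyr::mutate(tissue = dplyr::coalesce(.data$tissue, "background"))
  }
  summ <- pv |>
    dplyr::filter(is.finite(.data$error_pct)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(median_pct = stats::median(.data$error_pct),
                     mad_pct = stats::mad(.data$error_pct),
                     n = dplyr::n(), .groups = "drop")
  list(per_voxel = pv, summary = summ)
}

# Dense analytic ground-truth curves for the phantom's enhancing voxels.
# Returns tibble voxel, tissue, bat_ref computed by applying the same
# estimators used on reconstructions to a densely sampled noiseless
# truth curve (removes estimator quantization bias from the comparison).
truth_bat_reference <- function(ph, duration, dense_dt = 0.01) {
  times <- seq(0, duration, by = dense_dt)
  pe <- phantom_enhancement(ph, times)
  info <- as_tibble.eca_phantom(ph)
  stopifnot(identical(pe$index, info$voxel))
  bat <- vapply(seq_along(pe$index), function(i) {
    cur <- tibble::tibble(time = times, value = pe$enhancement[i, ],
                          enhancement = pe$enhancement[i, ])
    if (info$tissue[i] == "vessel") bat_vessel(cur) else bat_lesion(cur)
  }, numeric(1))
  tibble::tibble(voxel = pe$index, tissue = info$tissue, bat_ref = bat)
}

#' Per-voxel bolus-arrival-time comparison of two reconstructions
#'
#' Estimates BAT for every enhancing phantom voxel from both
#' reconstructions (time-of-peak in vessels, 20%-of-maximum rule in
#' lesions) and scores each against the same estimator applied to the
#' densely sampled noiseless ground-truth curve.
#'
#' @param eca,ifft Reconstructed [image_series()] objects.
#' @param ph The `eca_phantom` that generated the data.
#' @param baseline_until Pre-contrast window end (s) for baselines.
#' @param exclude_endpoints Drop first/last reconstructed time points.
#' @param dense_dt Step (s) of the dense ground-truth reference grid.
#' @return Tibble `voxel`, `tissue`, `bat_ref`, `bat_eca`, `bat_ifft`,
#'   `err_eca`, `err_ifft`.
#' @export
bat_analysis <- function(eca, ifft, ph, baseline_until = 5,
                         exclude_endpoints = TRUE, dense_dt = 0.01) {
  duration <- max(eca$times) + eca$dt / 2
  ref <- truth_bat_reference(ph, duration, dense_dt)
  est_for <- function(series) {
    curves <- extract_curves(series, ref$voxel, baseline_until = baseline_until,
                             exclude_endpoints = exclude_endpoints)
    curves |>
      dplyr::left_join(ref[, c("voxel", "tissue")], by = "voxel") |>
      dplyr::group_by(.data$voxel, .data$tissue) |>
      dplyr::summarise(bat = if (dplyr::first(.data$tissue) == "vessel") {
        bat_vessel(dplyr::pick("time", "value"))
      } else {
        bat_lesion(dplyr::pick("time", "enhancement"))
      }, .groups = "drop")
  }
  e <- est_for(eca) |> dplyr::rename(bat_eca = "bat")
  f <- est_for(ifft) |> dplyr::rename(bat_ifft = "bat")
  ref |>
    dplyr::left_join(e[, c("voxel", "bat_eca")], by = "voxel") |>
    dplyr::left_join(f[, c("voxel", "bat_ifft")], by = "voxel") |>
    dplyr::mutate(err_eca = abs(.data$bat_eca - .data$bat_ref),
                  err_ifft = abs(.data$bat_ifft - .data$bat_ref))
}

#' BAT improvement factors from a [bat_analysis()] table
#'
#' Per-tissue paired error-ratio statistics; `improvement` is the
#' reciprocal of the median per-voxel (ECA error / IFFT error) ratio.
#'
#' @param bat_tbl Output of [bat_analysis()].
#' @param ... Passed to [paired_error_ratio()].
#' @return Tibble with one row per tissue class: the [glance()] columns
#'   of the corresponding `error_ratio`.
#' @export
bat_improvement <- function(bat_tbl, ...) {
  bat_tbl |>
    dplyr::filter(is.finite(.data$err_eca), is.finite(.data$err_ifft)) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::group_modify(function(d, key) {
      glance(paired_error_ratio(d$err_eca, d$err_ifft, ...))
    }) |>
    dplyr::ungroup()
}
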