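#' Arrival-time container
#'
#' Per-channel feature-point (displacement peak) times with quality flags, the
#' intermediate product of the time-to-peak estimators.
#'
#' @param positions Channel lateral positions (m), strictly increasing.
#' @param times Arrival times (s); may be `NA` where `valid` is `FALSE`.
#' @param amplitudes Peak displacement per channel (micrometres).
#' @param valid Logical per-channel flag: a usable peak was found.
#' @param method Detection method tag.
#' @return Object of class `swe_arrivals`.
#' @export
arrival_times <- function(positions, times, amplitudes = rep(NA_real_, length(positions)),
                          valid = rep(TRUE, length(positions)), method = "SPM") {
  if (any(diff(positions) <= 0)) stop("channel positions must be strictly increasing")
  if (length(times) != length(positions) || length(valid) != length(positions))
    stop("positions, times and valid must have equal length")
  if (any(valid & !is.finite(times)))
    stop("arrival times must be finite wherever the valid flag is set")
  structure(list(positions = as.numeric(positions), times = as.numeric(times),
                 amplitudes = as.numeric(amplitudes), valid = as.logical(valid),
                 method = method),
            class = "swe_arrivals")
}

#' @export
print.swe_arrivals <- function(x, ...) {
  cat(sprintf("<swe_arrivals> %s: %d channels, %d valid\n",
              x$method, length(x$positions), sum(x$valid)))
  invisible(x)
}

#' @export
as.data.frame.swe_arrivals <- function(x, ...) {
  data.frame(position_m = x$positions, arrival_s = x$times,
             amplitude_um = x$amplitudes, valid = x$valid)
}

resolve_window <- function(field, window) {
  tvec <- field$time
  if (is.null(window)) return(seq_along(tvec))
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing time interval c(a, b)")
  if (window[1] < tvec[1] - 1e-12 || window[2] > tvec[length(tvec)] + 1e-12)
    stop("window must lie inside the time axis")
  which(tvec >= window[1] & tvec <= window[2])
}

#' Sample-resolution time-to-peak arrival detection (SPM)
#'
#' For each lateral channel the arrival time is the time-axis value at the
#' maximum displacement sample inside the window; temporal resolution is thus
#' one sampling interval (1/PRF). Ties are broken toward the earliest sample.
#' Channels whose maximum lies on a window boundary, or that are identically
#' zero, are flagged invalid.
#'
#' @param field A [displacement_field()] with at least 3 lateral channels.
#' @param depth_index Depth row to analyse (1-based).
#' @param window Optional time interval `c(a, b)` (s) restricting the search,
#'   e.g. to suppress reflections. Default: the full trace.
#' @return An [arrival_times()] object tagged `"SPM"`.
#' @export
detect_arrivals_spm <- function(field, depth_index = 1L, window = NULL) {
  sl <- field_slice(field, depth_index)
  if (nrow(sl) < 3L) stop("need at least 3 lateral channels")
  idx <- resolve_window(field, window)
  tw <- field$time[idx]
  n <- nrow(sl)
  times <- rep(NA_real_, n); amps <- rep(NA_real_, n); ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- sl[i, idx]
    if (all(tr == 0)) next
    p <- which.max(tr)                     # earliest max on ties
    if (p == 1L || p == length(tr)) next   # boundary peak: unreliable
    times[i] <- tw[p]; amps[i] <- tr[p]; ok[i] <- TRUE
  }
  if (!any(ok)) stop("no channel produced a valid peak")
  arrival_times(field$lateral, times, amps, ok, method = "SPM")
}

#' Sub-sample time-to-peak arrival detection (TDPM)
#'
#' Refines the discrete peak to sub-sample precision: each trace is first
#' upsampled by cubic-spline interpolation by `upsample_factor`, the discrete
#' maximum located, and the peak position refined by a three-point parabolic
#' fit on the upsampled grid. The refined time always lies within one original
#' sample of the discrete peak. This is the high-temporal-resolution variant
#' of the time-to-peak family.
#'
#' @inheritParams detect_arrivals_spm
#' @param upsample_factor Integer >= 1; spline upsampling factor (default 8).
#' @param parabolic Apply the final three-point parabolic refinement
#'   (default `TRUE`). With `upsample_factor = 1` and `parabolic = FALSE`
#'   TDPM reduces exactly to SPM.
#' @return An [arrival_times()] object tagged `"TDPM"`.
#' @export
detect_arrivals_tdpm <- function(field, depth_index = 1L, upsample_factor = 8L,
                                 parabolic = TRUE, window = NULL) {
  if (upsample_factor < 1) stop("upsample_factor must be >= 1")
  upsample_factor <- as.integer(upsample_factor)
  sl <- field_slice(field, depth_index)
  if (nrow(sl) < 3L) stop("need at least 3 lateral channels")
  idx <- resolve_window(field, window)
  tw <- field$time[idx]
  dt <- field$time[2] - field$time[1]
  n <- nrow(sl)
  times <- rep(NA_real_, n); amps <- rep(NA_real_, n); ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    tr <- sl[i, idx]
    if (all(tr == 0)) next
    p0 <- which.max(tr)                        # discrete peak, original grid
    if (p0 == 1L || p0 == length(tr)) next     # no 3-point neighbourhood
    if (upsample_factor > 1L) {
      up <- stats::spline(tw, tr, n = (length(tw) - 1L) * upsample_factor + 1L,
                          method = "fmm")
      tu <- up$x; yu <- up$y
      # search only the +/- one-original-sample neighbourhood of the peak
      lo <- (p0 - 2L) * upsample_factor + 1L
      hi <- p0 * upsample_factor + 1L
      q <- lo - 1L + which.max(yu[lo:hi])
      q <- min(max(q, 2L), length(yu) - 1L)
    } else {
      tu <- tw; yu <- tr; q <- p0
    }
    if (parabolic) {
      ref <- parabolic_vertex(tu[(q - 1):(q + 1)], yu[(q - 1):(q + 1)])
      t_hat <- ref$x; a_hat <- ref$y
    } else {
      t_hat <- tu[q]; a_hat <- yu[q]
    }
    # refinement stays within one original sample of the discrete peak
    t_hat <- min(max(t_hat, tw[p0] - dt), tw[p0] + dt)
    times[i] <- t_hat; amps[i] <- a_hat; ok[i] <- TRUE
  }
  if (!any(ok)) stop("no channel produced a valid peak")
  arrival_times(field$lateral, times, amps, ok, method = "TDPM")
}

# Vertex of the parabola through three (x, y) points with uniform x spacing.
# Exact for quadratic data; degenerate (flat) triples return the centre.
parabolic_vertex <- function(x3, y3) {
  h <- x3[2] - x3[1]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (abs(denom) < .Machine$double.eps * max(abs(y3), 1))
    return(list(x = x3[2], y = y3[2]))
  delta <- 0.5 * (y3[1] - y3[3]) / denom
  list(x = x3[2] + delta * h,
       y = y3[2] - 0.25 * (y3[1] - y3[3]) * delta)
}

#' Shear-wave speed from a position-on-time linear regression
#'
#' Ordinary least squares of channel position (m) on arrival time (s) over the
#' valid channels; the slope is the shear-wave speed directly and the fit's
#' coefficient of determination is the goodness of fit. (The reciprocal
#' orientation, time on position, is the common alternative; position-on-time
#' is used so that slope = speed without division.)
#'
#' @param arrivals An [arrival_times()] object with >= 3 valid channels.
#' @param robust Optional single-pass outlier trim: refit after excluding
#'   points whose residual exceeds 3 estimated residual standard deviations.
#'   Off by default so that estimator differences are attributable to peak
#'   detection alone.
#' @return An `swe_estimate`: list with `speed` (m/s), `r_squared`,
#'   `intercept` (m at t = 0), `n_channels_used`, `method`.
#' @export
fit_speed_regression <- function(arrivals, robust = FALSE) {
  stopifnot(inherits(arrivals, "swe_arrivals"))
  keep <- arrivals$valid
  if (sum(keep) < 3L) stop("need at least 3 valid channels for the regression")
  x <- arrivals$positions[keep]; t <- arrivals$times[keep]
  if (diff(range(t)) == 0) stop("all arrival times equal: speed undefined (infinite)")
  fit <- stats::lm(x ~ t)
  if (robust) {
    r <- stats::residuals(fit)
    inl <- abs(r) <= 3 * stats::sd(r)
    if (sum(inl) >= 3L && any(!inl)) {
      x <- x[inl]; t <- t[inl]
      fit <- stats::lm(x ~ t)
    }
  }
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted slope <= 0: non-physical propagation (check window/channels)")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((x - mean(x))^2)
  sws_estimate(speed = slope, r_squared = r2,
               intercept = unname(stats::coef(fit)[1]),
               n_channels_used = length(t), method = arrivals$method)
}

sws_estimate <- function(speed, r_squared, intercept, n_channels_used, method,
                         diagnostics = NULL) {
  structure(list(speed = speed, r_squared = r_squared, intercept = intercept,
                 n_channels_used = n_channels_used, method = method,
                 diagnostics = diagnostics),
            class = "swe_estimate")
}

#' @export
print.swe_estimate <- function(x, ...) {
  cat(sprintf("<swe_estimate> %s: %.4g m/s (R^2 %.4f, %d channels)\n",
              x$method, x$speed, x$r_squared, x$n_channels_used))
  invisible(x)
}

#' Time-shift (cross-correlation) speed estimation (TSPM)
#'
#' For each adjacent channel pair the inter-channel delay is the lag
#' maximising the discrete cross-correlation within `± max_lag`, refined to
#' sub-sample precision by a three-point parabolic fit on the correlation
#' peak. Cumulative delays versus channel position are then fed to
#' [fit_speed_regression()]. Pairs whose correlation maximum sits on the
#' `± max_lag` boundary are dropped.
#'
#' @inheritParams detect_arrivals_spm
#' @param max_lag Maximum admissible inter-channel delay (s); must be at
#'   least the expected per-pair delay.
#' @return An `swe_estimate` tagged `"TSPM"`.
#' @export
estimate_tspm <- function(field, depth_index = 1L, max_lag = NULL) {
  sl <- field_slice(field, depth_index)
  n <- nrow(sl)
  if (n < 3L) stop("need at least 3 lateral channels")
  dt <- field$time[2] - field$time[1]
  if (is.null(max_lag)) max_lag <- (length(field$time) - 1L) * dt / 2
  lmax <- max(1L, floor(max_lag / dt))
  lag_s <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    lag_s[i] <- pair_lag(sl[i, ], sl[i + 1L, ], dt, lmax)
  }
  good <- !is.na(lag_s)
  # cumulative arrival epochs at each channel reachable through valid pairs
  pos <- field$lateral
  cum_t <- rep(NA_real_, n); cum_t[1] <- 0
  for (i in seq_len(n - 1L)) {
    if (!is.na(cum_t[i]) && good[i]) cum_t[i + 1L] <- cum_t[i] + lag_s[i]
  }
  keep <- !is.na(cum_t)
  if (sum(keep) < 3L)
    stop("fewer than 3 cumulative time points survive the lag search")
  arr <- arrival_times(pos[keep], cum_t[keep],
                       amplitudes = apply(sl[keep, , drop = FALSE], 1, max),
                       method = "TSPM")
  fit_speed_regression(arr)
}

# Sub-sample delay between traces a and b (b lags a by the returned seconds).
# Integer-lag correlation peak, spline-upsampled around the peak, then a
# three-point parabolic fit — the same refinement recipe as TDPM. NA when the
# peak sits on the +/- lmax boundary (delay out of admissible range).
pair_lag <- function(a, b, dt, lmax, upsample = 8L) {
  cc <- cross_correlation(a, b, lmax)
  p <- which.max(cc)
  if (p == 1L || p == length(cc)) return(NA_real_)
  lags <- (seq_along(cc) - lmax - 1L) * dt
  up <- stats::spline(lags, cc, n = (length(cc) - 1L) * upsample + 1L,
                      method = "fmm")
  lo <- (p - 2L) * upsample + 1L
  hi <- p * upsample + 1L
  q <- lo - 1L + which.max(up$y[lo:hi])
  q <- min(max(q, 2L), length(up$y) - 1L)
  parabolic_vertex(up$x[(q - 1L):(q + 1L)], up$y[(q - 1L):(q + 1L)])$x
}

# Discrete cross-correlation c(L) = sum_t b(t) a(t - L) for L in -lmax..lmax:
# positive best lag means b is a delayed copy of a.
cross_correlation <- function(a, b, lmax) {
  n <- length(a)
  vapply(-lmax:lmax, function(L) {
    ta <- seq_len(n) - L
    ok <- ta >= 1L & ta <= n
    sum(b[ok] * a[ta[ok]])
  }, numeric(1))
}

#' Radon-sum group-velocity estimation
#'
#' Searches the space-time displacement image for the straight trajectory
#' `t = t0 + (x - x1) / c` maximising the integrated absolute displacement
#' (linear interpolation along the trajectory; samples outside the time window
#' contribute zero). The candidate speeds are `n_speeds` log-spaced values
#' over `speed_range`; intercepts span the time axis at the sampling step.
#' Resolution is limited by the speed grid. The reported `r_squared` is the
#' normalised peak sharpness: (peak sum - median sum over the grid) / peak
#' sum.
#'
#' @inheritParams detect_arrivals_spm
#' @param speed_range Ordered positive candidate interval `c(min, max)` (m/s).
#' @param n_speeds Number of log-spaced candidate speeds (default 201).
#' @param n_intercepts Number of onset intercepts (default: one per time
#'   sample).
#' @return An `swe_estimate` tagged `"RADON"`; errors if the maximiser lies on
#'   the boundary of `speed_range` (widen the range).
#' @export
estimate_radon <- function(field, depth_index = 1L, speed_range = c(0.5, 8),
                           n_speeds = 201L, n_intercepts = NULL) {
  if (length(speed_range) != 2L || any(speed_range <= 0) ||
      speed_range[1] >= speed_range[2])
    stop("speed_range must be a positive ordered interval")
  sl <- field_slice(field, depth_index)
  if (nrow(sl) < 3L) stop("need at least 3 lateral channels")
  tvec <- field$time
  speeds <- radon_speed_grid(speed_range, n_speeds)
  t0s <- if (is.null(n_intercepts)) tvec else
    seq(tvec[1], tvec[length(tvec)], length.out = n_intercepts)
  xrel <- field$lateral - field$lateral[1]
  absd <- abs(sl)
  sums <- matrix(0, length(speeds), length(t0s))
  for (si in seq_along(speeds)) {
    acc <- numeric(length(t0s))
    for (ci in seq_len(nrow(sl))) {
      tq <- t0s + xrel[ci] / speeds[si]
      acc <- acc + stats::approx(tvec, absd[ci, ], xout = tq,
                                 yleft = 0, yright = 0)$y
    }
    sums[si, ] <- acc
  }
  best <- arrayInd(which.max(sums), dim(sums))
  si <- best[1]; ti <- best[2]
  if (si == 1L || si == length(speeds))
    stop(sprintf("Radon maximiser at the boundary of speed_range [%g, %g]: widen the range",
                 speed_range[1], speed_range[2]))
  peak <- sums[si, ti]
  sharp <- (peak - stats::median(sums)) / peak
  sws_estimate(speed = speeds[si], r_squared = max(0, min(1, sharp)),
               intercept = t0s[ti], n_channels_used = nrow(sl),
               method = "RADON",
               diagnostics = list(speed_grid_step = if (si < length(speeds))
                 speeds[si + 1L] - speeds[si] else NA_real_))
}

#' Candidate speed grid used by [estimate_radon()]
#' @param speed_range Ordered positive interval (m/s).
#' @param n_speeds Number of candidates.
#' @return Log-spaced speeds (m/s).
#' @export
radon_speed_grid <- function(speed_range, n_speeds) {
  exp(seq(log(speed_range[1]), log(speed_range[2]), length.out = n_speeds))
}

#' One-call shear-wave speed estimation
#'
#' Dispatches to the requested estimator and returns its `swe_estimate`.
#'
#' @inheritParams detect_arrivals_spm
#' @param method `"spm"`, `"tdpm"`, `"tspm"` or `"radon"`.
#' @param ... Passed to the method-specific function.
#' @return An `swe_estimate`.
#' @export
estimate_sws <- function(field, method = c("spm", "tdpm", "tspm", "radon"),
                         depth_index = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         spm = fit_speed_regression(detect_arrivals_spm(field, depth_index, ...)),
         tdpm = fit_speed_regression(detect_arrivals_tdpm(field, depth_index, ...)),
         tspm = estimate_tspm(field, depth_index, ...),
         radon = estimate_radon(field, depth_index, ...))
}
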