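# --- SPM -------------------------------------------------------------------

test_that("SPM returns the exact sample time of a unit impulse per channel", {
  dt <- 1e-4
  m <- matrix(0, 4, 50)
  ks <- c(10, 17, 25, 33)
  for (i in 1:4) m[i, ks[i]] <- 1
  f <- matrix_field(m, dt = dt)
  arr <- detect_arrivals_spm(f)
  expect_equal(arr$times, (ks - 1) * dt)
  expect_true(all(arr$valid))
})

test_that("SPM picks the grid sample nearest the analytic Gaussian peak", {
  set.seed(7)
  dt <- 1e-4
  tvec <- seq(0, 6e-3, by = dt)
  for (rep in 1:25) {
    peaks <- sort(runif(3, 1e-3, 5e-3))
    m <- t(vapply(peaks, function(p) exp(-0.5 * ((tvec - p) / 4e-4)^2),
                  numeric(length(tvec))))
    f <- matrix_field(m, dt = dt)
    arr <- detect_arrivals_spm(f)
    # oracle: argmax of dense evaluation of the analytic pulse, rounded to grid
    dense_t <- seq(0, 6e-3, by = dt / 1000)
    want <- vapply(peaks, function(p) {
      dense <- exp(-0.5 * ((dense_t - p) / 4e-4)^2)
      tvec[which.min(abs(tvec - dense_t[which.max(dense)]))]
    }, numeric(1))
    expect_equal(arr$times, want)
  }
})

test_that("SPM flags all-zero channels and window-boundary peaks invalid", {
  dt <- 1e-4
  m <- matrix(0, 4, 50)
  m[1, 20] <- 1; m[2, 1] <- 1; m[3, 50] <- 1    # interior, left edge, right edge
  f <- matrix_field(m, dt = dt)
  arr <- detect_arrivals_spm(f)
  expect_identical(arr$valid, c(TRUE, FALSE, FALSE, FALSE))
  # window restriction moves the boundary
  m2 <- matrix(0, 3, 50); m2[, 25] <- 1
  f2 <- matrix_field(m2, dt = dt)
  # every peak sits on the window edge: all channels invalid is an error
  expect_error(detect_arrivals_spm(f2, window = c(24, 40) * dt), "no channel")
  expect_error(detect_arrivals_spm(matrix_field(matrix(0, 3, 50))),
               "no channel")
})

# --- TDPM ------------------------------------------------------------------

test_that("TDPM is exact on a sampled parabola with an off-grid vertex", {
  dt <- 1e-4
  tvec <- seq(0, 3e-3, by = dt)
  vertex <- 3.37 * dt
  m <- rbind(10 - (tvec - vertex)^2 * 1e6,
             10 - (tvec - vertex - 5 * dt)^2 * 1e6,
             10 - (tvec - vertex - 10 * dt)^2 * 1e6)
  arr <- detect_arrivals_tdpm(matrix_field(m, dt = dt))
  expect_equal(arr$times[1], vertex, tolerance = 1e-9 / vertex)
  expect_lt(abs(arr$times[1] - vertex), 1e-9)
})

test_that("TDPM beats SPM against the analytic Gaussian peak over random phases", {
  set.seed(42)
  dt <- 2e-4                                  # deliberately coarse sampling
  tvec <- seq(0, 8e-3, by = dt)
  n_worse <- 0L
  for (rep in 1:100) {
    peaks <- 2e-3 + c(0, 1e-3, 2e-3) + runif(1, 0, dt)   # random peak phase
    m <- t(vapply(peaks, function(p) exp(-0.5 * ((tvec - p) / 5e-4)^2),
                  numeric(length(tvec))))
    f <- matrix_field(m, dt = dt)
    e_spm <- abs(detect_arrivals_spm(f)$times - peaks)
    e_tdpm <- abs(detect_arrivals_tdpm(f)$times - peaks)
    n_worse <- n_worse + any(e_tdpm > e_spm + 1e-12)
  }
  expect_identical(n_worse, 0L)
})

test_that("TDPM with unit upsampling and no parabolic refinement reduces to SPM", {
  f <- moveout_field(speed = 2)
  a_spm <- detect_arrivals_spm(f)
  a_red <- detect_arrivals_tdpm(f, upsample_factor = 1, parabolic = FALSE)
  expect_equal(a_red$times, a_spm$times)
  expect_identical(a_red$valid, a_spm$valid)
})

test_that("TDPM refinement stays within one original sample of the discrete peak", {
  set.seed(13)
  dt <- 1e-4
  for (rep in 1:20) {
    m <- matrix(runif(3 * 60), 3, 60)         # rough traces
    f <- matrix_field(m, dt = dt)
    a_spm <- detect_arrivals_spm(f)
    a_tdpm <- detect_arrivals_tdpm(f)
    both <- a_spm$valid & a_tdpm$valid
    if (any(both))
      expect_true(all(abs(a_tdpm$times[both] - a_spm$times[both]) <= dt + 1e-12))
  }
})

# --- regression ------------------------------------------------------------

test_that("perfect linear moveout gives exact speed and unit R^2", {
  x <- seq(2e-3, 9e-3, by = 1e-3)
  arr <- arrival_times(x, x / 2)
  e <- fit_speed_regression(arr)
  expect_equal(e$speed, 2, tolerance = 1e-12)
  expect_equal(e$r_squared, 1, tolerance = 1e-9)
  expect_identical(e$n_channels_used, length(x))
})

test_that("regression equals the closed-form normal equations on jittered arrivals", {
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    x <- seq(1e-3, by = 1e-3, length.out = n)
    t <- x / runif(1, 1, 6) + rnorm(n, sd = 5e-5)
    if (any(diff(t) <= 0) || diff(range(t)) == 0) t <- sort(t)
    arr <- arrival_times(x, t)
    got <- fit_speed_regression(arr)
    want <- oracle_ols(t, x)
    if (want$slope <= 0) next
    expect_equal(got$speed, want$slope, tolerance = 1e-12)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
})

test_that("degenerate arrival sets are rejected", {
  x <- c(1e-3, 2e-3, 3e-3)
  expect_error(fit_speed_regression(arrival_times(x, rep(2e-3, 3))),
               "infinite")
  expect_error(fit_speed_regression(arrival_times(x, c(3e-3, 2e-3, 1e-3))),
               "slope <= 0")
  arr <- arrival_times(x, x / 2, valid = c(TRUE, TRUE, FALSE))
  expect_error(fit_speed_regression(arr), "at least 3 valid")
})

test_that("robust pass drops a gross outlier and recovers the clean fit", {
  x <- seq(1e-3, 2e-2, by = 1e-3)              # 20 channels
  t <- x / 3
  t[10] <- t[10] + 8e-4                        # one corrupted arrival
  arr <- arrival_times(x, t)
  plain <- fit_speed_regression(arr)
  robust <- fit_speed_regression(arr, robust = TRUE)
  expect_gt(abs(plain$speed - 3), abs(robust$speed - 3))
  expect_equal(robust$speed, 3, tolerance = 1e-9)
  expect_identical(robust$n_channels_used, 19L)
})

# --- TSPM ------------------------------------------------------------------

test_that("TSPM is exact for integer-sample shifted copies", {
  dt <- 1e-4
  tvec <- seq(0, 8e-3, by = dt)
  base <- exp(-0.5 * ((tvec - 2e-3) / 4e-4)^2)
  lateral <- seq(2e-3, 6e-3, by = 1e-3)        # dx = 1 mm, c = 2 m/s: 5 samples
  m <- t(vapply(seq_along(lateral) - 1,
                function(k) exp(-0.5 * ((tvec - 2e-3 - k * 5 * dt) / 4e-4)^2),
                numeric(length(tvec))))
  f <- matrix_field(m, dt = dt, lateral = lateral)
  e <- estimate_tspm(f)
  expect_equal(e$speed, 1e-3 / (5 * dt), tolerance = 1e-9)
  expect_identical(e$method, "TSPM")
})

test_that("TSPM lags match a dense-grid correlation oracle for fractional shifts", {
  f <- moveout_field(speed = 2.3, dt = 1e-4)   # non-integer inter-channel shift
  e <- estimate_tspm(f)
  expect_equal(e$speed, 2.3, tolerance = 0.01)
  # dense oracle for the first channel pair
  sl <- field_slice(f)
  dt <- 1e-4
  lag_grid <- seq(-2e-3, 2e-3, by = dt / 50)
  tvec <- f$time
  corr <- vapply(lag_grid, function(L) {
    shifted <- spline(tvec, sl[1, ], xout = tvec - L, method = "fmm")$y
    sum(sl[2, ] * shifted)
  }, numeric(1))
  want_lag <- lag_grid[which.max(corr)]
  got_lag <- swetools:::pair_lag(sl[1, ], sl[2, ], dt, 20L)
  expect_lt(abs(got_lag - want_lag), dt / 10)
})

test_that("TSPM rejects too few channels and boundary-limited lags", {
  f2 <- moveout_field(lateral = c(3e-3, 4e-3, 5e-3))
  sl <- field_slice(f2)[1:2, ]
  f_two <- matrix_field(sl, lateral = c(3e-3, 4e-3))
  expect_error(estimate_tspm(f_two), "at least 3")
  # max_lag smaller than the true delay: every pair lands on the boundary
  f <- moveout_field(speed = 2, lateral = seq(3e-3, 7e-3, by = 1e-3))
  expect_error(estimate_tspm(f, max_lag = 2e-4), "fewer than 3 cumulative")
})

# --- Radon -----------------------------------------------------------------

test_that("Radon recovers an exactly representable moveout speed", {
  f <- moveout_field(speed = 2)
  # log-spaced grid over [0.5, 8] with 201 points contains 2.0 exactly
  e <- estimate_radon(f, speed_range = c(0.5, 8), n_speeds = 201)
  expect_equal(e$speed, 2, tolerance = 1e-12)
  expect_gt(e$r_squared, 0.5)
})

test_that("Radon equals an exhaustive independent grid search", {
  set.seed(21)
  for (rep in 1:8) {
    speed <- runif(1, 1.2, 4)
    f <- moveout_field(speed = speed, duration = 6e-3,
                       lateral = seq(3e-3, 7e-3, by = 1e-3))
    n_speeds <- 41L
    rng <- c(0.8, 6)
    got <- estimate_radon(f, speed_range = rng, n_speeds = n_speeds)
    # brute force, double loop, written independently
    speeds <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_speeds))
    sl <- abs(field_slice(f)); tvec <- f$time
    xrel <- f$lateral - f$lateral[1]
    best <- -Inf; best_c <- NA
    for (c0 in speeds) for (t0 in tvec) {
      s <- 0
      for (ci in seq_along(xrel)) {
        tq <- t0 + xrel[ci] / c0
        if (tq >= tvec[1] && tq <= tvec[length(tvec)]) {
          j <- findInterval(tq, tvec)
          j <- min(j, length(tvec) - 1L)
          w <- (tq - tvec[j]) / (tvec[j + 1] - tvec[j])
          s <- s + (1 - w) * sl[ci, j] + w * sl[ci, j + 1]
        }
      }
      if (s > best) { best <- s; best_c <- c0 }
    }
    expect_equal(got$speed, best_c, tolerance = 1e-12)
  }
})

test_that("Radon errors when the maximiser sits on the speed-range boundary", {
  f <- moveout_field(speed = 2)
  expect_error(estimate_radon(f, speed_range = c(3, 5)), "widen the range")
  expect_error(estimate_radon(f, speed_range = c(5, 3)), "ordered")
})

# --- consistency across methods -------------------------------------------

test_that("all four estimators agree with truth on noiseless linear moveout", {
  f <- simulate_displacement(test_medium(mu_kpa = 9),
                             push_pulse(attenuation = 30), test_grid())
  c_true <- 3
  dt <- 1e-4
  aperture <- diff(range(f$lateral))
  e_spm <- estimate_sws(f, "spm")
  expect_lt(abs(e_spm$speed - c_true), c_true^2 * dt / aperture)
  for (m in c("tdpm", "tspm")) {
    e <- estimate_sws(f, m)
    expect_lt(abs(e$speed - c_true) / c_true, 1e-3)
    expect_gt(e$r_squared, 1 - 1e-6)          # residual sub-sample detection error
  }
  e_r <- estimate_radon(f, speed_range = c(1, 6), n_speeds = 301)
  step <- max(diff(radon_speed_grid(c(1, 6), 301)))
  expect_lt(abs(e_r$speed - c_true), step)
})

test_that("r_squared does not improve with added noise, in expectation", {
  f <- simulate_displacement(test_medium(mu_kpa = 4),
                             push_pulse(attenuation = 30), test_grid())
  r2 <- vapply(c(Inf, 30, 15), function(snr) {
    mean(vapply(1:10, function(s) {
      fn <- if (is.infinite(snr)) f else add_noise(f, snr, seed = s)
      estimate_sws(fn, "tdpm")$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2) <= 1e-12))
})
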