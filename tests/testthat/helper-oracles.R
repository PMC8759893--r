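# Independent oracles and small shared fixtures. Every oracle here is coded
# from the defining formula, not by calling the implementation under test.

# Travel time from x0 to x through a piecewise-constant lateral speed profile,
# by brute-force fine-step numeric integration of 1/c(s).
oracle_travel_time <- function(medium, depth_index, x0, x, n_steps = 2e5) {
  c_node <- sqrt(medium$mu[, depth_index] / medium$rho)
  xg <- medium$lateral
  c_at <- function(s) {
    i <- findInterval(s, xg, rightmost.closed = TRUE)
    c_node[pmin(pmax(i, 1L), length(xg) - 1L)]
  }
  a <- min(x0, x); b <- max(x0, x)
  if (a == b) return(0)
  # exact cell-aware integration: split [a, b] at every grid breakpoint
  brk <- sort(unique(c(a, b, xg[xg > a & xg < b])))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  sum(diff(brk) / c_at(mid))
}

# Closed-form ordinary least squares of y on x (normal equations).
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# AUC by exhaustive positive x negative pair counting, ties one half.
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# ICC(2,1) with mean squares taken from a two-way stats::aov fit.
oracle_icc21 <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exhaustive Youden scan over all distinct thresholds (rule: score >= thr).
oracle_youden <- function(labels, scores) {
  thr <- sort(unique(scores))
  best <- -Inf; out <- NULL
  for (th in thr) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    j <- sens + spec - 1
    if (j > best) { best <- j; out <- list(threshold = th, youden = j) }
  }
  out
}

# Small fast acquisition used across estimator tests: 10 channels, 8 ms.
test_grid <- function(dt = 1e-4, duration = 8e-3,
                      lateral = seq(3e-3, 7.5e-3, by = 5e-4), depths = 0) {
  acquisition_grid(dt = dt, duration = duration, lateral = lateral,
                   depths = depths)
}

test_medium <- function(mu_kpa = 4, eta = 0, depth = 0) {
  build_phantom("homogeneous", lateral = seq(0, 0.01, by = 2.5e-4),
                depth = depth, shear_modulus_kpa = mu_kpa,
                viscosity_pa_s = eta)
}

# Synthetic field with per-channel traces supplied as a channels x time matrix.
matrix_field <- function(m, dt = 1e-4, lateral = NULL) {
  nt <- ncol(m)
  if (is.null(lateral)) lateral <- seq_len(nrow(m)) * 1e-3
  displacement_field(array(m, dim = c(nrow(m), 1L, nt)),
                     time_axis = (seq_len(nt) - 1) * dt,
                     lateral_axis = lateral, mode = "synthetic")
}

# Gaussian-pulse moveout field at speed c with analytic peak times x/c + t0.
moveout_field <- function(speed = 2, t0 = 1e-3, width = 3e-4, dt = 1e-4,
                          lateral = seq(3e-3, 7.5e-3, by = 5e-4),
                          duration = 8e-3, amp = 10) {
  tvec <- seq(0, duration, by = dt)
  m <- t(vapply(lateral, function(x)
    amp * exp(-0.5 * ((tvec - t0 - x / speed) / width)^2), numeric(length(tvec))))
  matrix_field(m, dt = dt, lateral = lateral)
}
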