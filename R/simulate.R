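#' Simulate a shear-wave displacement field
#'
#' Propagates the acoustic-radiation-force push through the medium and samples
#' particle displacement on the acquisition grid. Depth is a batch axis: each
#' tracked depth row propagates independently along the lateral direction.
#'
#' Two propagation models are available:
#' \describe{
#'   \item{kinematic}{`u(x, t) = A(x) g(t - tau(x))` where
#'     `tau(x) = push_time + integral of ds / c(s)` along the lateral ray from
#'     the push to `x`, `c(s) = sqrt(mu(s)/rho)` (piecewise constant between
#'     medium nodes), `A(x) = amplitude * exp(-attenuation * |x - x0|)` and
#'     `g` the Gaussian push profile. Handles laterally heterogeneous media;
#'     ignores viscosity.}
#'   \item{viscoelastic}{Per depth row, Fourier synthesis
#'     `u(x, t) = Re IFFT[ G(omega) exp(-i k(omega) |x - x0|) ]` with the Voigt
#'     complex wavenumber `k = omega sqrt(rho / (mu + i omega eta))` on the
#'     branch `Re k > 0, Im k <= 0` (outgoing, decaying). Requires the medium
#'     to be laterally homogeneous at each tracked depth; the time window is
#'     zero-padded to at least 4x its length to suppress wrap-around.}
#' }
#'
#' @param medium A [medium_model()].
#' @param push A [push_pulse()]; its position must lie inside the lateral grid.
#' @param grid An [acquisition_grid()]; tracked positions/depths must lie
#'   inside the medium.
#' @param mode `"kinematic"` or `"viscoelastic"`.
#' @param two_sided If `FALSE` (default) tracked channels are expected on one
#'   side of the push; propagation uses `|x - x0|` either way.
#' @return A noiseless [displacement_field()].
#' @export
simulate_displacement <- function(medium, push, grid,
                                  mode = c("kinematic", "viscoelastic"),
                                  two_sided = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(medium, "swe_medium"), inherits(push, "swe_push"),
            inherits(grid, "swe_grid"))
  if (push$position < min(medium$lateral) || push$position > max(medium$lateral))
    stop("push position lies outside the medium's lateral grid")
  if (any(grid$lateral < min(medium$lateral) | grid$lateral > max(medium$lateral)))
    stop("tracked lateral positions must lie inside the medium's lateral grid")
  if (!two_sided && any(grid$lateral < push$position))
    stop("one-sided acquisition: tracked channels must sit at or beyond the push position ",
         "(set two_sided = TRUE for channels on both sides)")
  di <- match_depths(medium, grid)
  tvec <- seq(0, grid$duration, by = grid$dt)
  nl <- length(grid$lateral); nd <- length(di); nt <- length(tvec)

  # slowest arrival must fit inside the window (plus 3 pulse widths of tail)
  tau_all <- vapply(seq_along(di), function(j)
    travel_times(medium, di[j], push$position, grid$lateral) + push$push_time,
    numeric(nl))
  tau_all <- matrix(tau_all, nl, nd)
  t_need <- max(tau_all) + 3 * push$width
  if (t_need > grid$duration)
    stop(sprintf("acquisition duration %.4g s too short: farthest arrival needs at least %.4g s",
                 grid$duration, t_need))

  vals <- array(0, dim = c(nl, nd, nt))
  if (push$amplitude > 0) {
    if (mode == "kinematic") {
      amp <- push$amplitude * exp(-push$attenuation * abs(grid$lateral - push$position))
      for (j in seq_len(nd)) for (i in seq_len(nl)) {
        vals[i, j, ] <- amp[i] * exp(-0.5 * ((tvec - tau_all[i, j]) / push$width)^2)
      }
    } else {
      for (j in seq_len(nd)) {
        row <- depth_row_props(medium, di[j])
        vals[, j, ] <- viscoelastic_row(
          mu = row$mu, eta = row$eta, rho = medium$rho,
          dist = abs(grid$lateral - push$position),
          tvec = tvec, push = push)
      }
    }
  }
  displacement_field(vals, tvec, grid$lateral, grid$depths,
                     noise_seed = NULL, mode = mode,
                     provenance = sprintf("simulate_displacement(%s)", mode))
}

match_depths <- function(medium, grid) {
  di <- vapply(grid$depths, function(z) {
    i <- which.min(abs(medium$depth - z))
    if (abs(medium$depth[i] - z) > 1e-9)
      stop("tracked depth ", z, " m is not a medium grid depth")
    i
  }, integer(1))
  di
}

depth_row_props <- function(medium, depth_index) {
  mu <- medium$mu[, depth_index]
  eta <- medium$eta[, depth_index]
  if (diff(range(mu)) > 1e-9 * max(mu) || diff(range(eta)) > 1e-9 * max(eta, 1))
    stop("viscoelastic mode requires a laterally homogeneous medium at each tracked depth")
  list(mu = mu[1], eta = eta[1])
}

# Lateral travel time from x0 to each target position at one depth row.
# Speed is piecewise constant per grid cell, taking the left node's value;
# equals the integral of 1/c(s) ds exactly for such profiles.
travel_times <- function(medium, depth_index, x0, targets) {
  xg <- medium$lateral
  c_node <- sqrt(medium$mu[, depth_index] / medium$rho)
  slow <- 1 / c_node[-length(c_node)]            # per-cell slowness
  dx <- diff(xg)
  cum <- c(0, cumsum(slow * dx))                 # travel time from xg[1] to node
  at <- function(x) {
    i <- findInterval(x, xg, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(xg) - 1L)
    cum[i] + (x - xg[i]) * slow[i]
  }
  abs(at(targets) - at(x0))
}

# Dispersive propagation of the Gaussian push over distances `dist` for one
# homogeneous Voigt depth row. Returns n_dist x n_time matrix (micrometres).
viscoelastic_row <- function(mu, eta, rho, dist, tvec, push) {
  nt <- length(tvec)
  dt <- tvec[2] - tvec[1]
  n_pad <- stats::nextn(4L * nt, 2)
  g <- push$amplitude *
    exp(-0.5 * ((seq_len(n_pad) - 1) * dt - push$push_time)^2 / push$width^2)
  G <- stats::fft(g)
  m_pos <- 0:(n_pad %/% 2)                       # non-negative frequency bins
  omega <- 2 * pi * m_pos / (n_pad * dt)
  k <- complex(real = 0, imaginary = 0) * omega
  pos <- omega > 0
  k[pos] <- omega[pos] * sqrt(rho / complex(real = mu, imaginary = omega[pos] * eta))
  # principal sqrt gives Re k > 0, Im k <= 0 (outgoing, decaying with e^{+i omega t})
  out <- matrix(0, length(dist), nt)
  for (ii in seq_along(dist)) {
    H <- exp(-1i * k * dist[ii])
    spec <- G
    spec[m_pos + 1L] <- spec[m_pos + 1L] * H
    # hermitian mirror for negative frequencies
    neg_src <- 2:(ceiling(n_pad / 2))
    spec[n_pad + 2L - neg_src] <- Conj(spec[neg_src])
    u <- Re(stats::fft(spec, inverse = TRUE)) / n_pad
    out[ii, ] <- u[seq_len(nt)]
  }
  out
}

#' Add seeded Gaussian noise at a prescribed signal-to-noise ratio
#'
#' Adds zero-mean white Gaussian noise whose variance is set from the field's
#' mean signal power so that `10 log10(signal power / noise power) = snr_db`.
#' With a depth-resolved `snr_db` vector each depth row gets its own noise
#' variance computed from that row's signal power (depth-dependent signal
#' degradation is modelled as depth-indexed SNR, not wave physics).
#'
#' @param field A noiseless [displacement_field()] (layering noise on an
#'   already-noisy field requires `allow_layering = TRUE`).
#' @param snr_db Target SNR in dB: scalar, or vector with one value per depth.
#'   `Inf` is the no-noise sentinel and returns the field unchanged.
#' @param seed Integer seed; the same (field, snr_db, seed) triple is
#'   bit-reproducible. The global RNG state is left untouched.
#' @param allow_layering Permit adding noise on top of existing noise.
#' @return A new `swe_field`; the input is not modified.
#' @export
add_noise <- function(field, snr_db, seed, allow_layering = FALSE) {
  stopifnot(inherits(field, "swe_field"))
  if (any(is.na(snr_db)) || any(is.nan(snr_db)) || any(snr_db == -Inf))
    stop("snr_db must be finite (or +Inf for the no-noise sentinel)")
  if (!is.null(field$noise_seed) && !allow_layering)
    stop("field already carries noise (seed ", field$noise_seed,
         "); pass allow_layering = TRUE to stack noise")
  if (all(is.infinite(snr_db))) return(field)
  nd <- length(field$depth)
  if (!(length(snr_db) %in% c(1L, nd)))
    stop("snr_db must be scalar or one value per depth (", nd, ")")
  snr_db <- rep_len(snr_db, nd)
  seed <- as.integer(seed)
  out <- field
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (j in seq_len(nd)) {
    if (is.infinite(snr_db[j])) next
    sl <- field$values[, j, , drop = FALSE]
    p_sig <- mean(sl^2)
    sd_n <- sqrt(p_sig / 10^(snr_db[j] / 10))
    out$values[, j, ] <- sl + array(stats::rnorm(length(sl), sd = sd_n), dim = dim(sl))
  }
  out$noise_seed <- seed
  out$provenance <- paste0(field$provenance, sprintf(" + noise(snr=%s dB, seed=%d)",
                                                     paste(snr_db, collapse = "/"), seed))
  out
}
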