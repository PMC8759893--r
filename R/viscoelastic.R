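#' Voigt-model parameters
#'
#' The Voigt rheology — a spring (shear modulus) in parallel with a dashpot
#' (shear viscosity) — is the standard first-order model for soft-tissue
#' viscoelasticity: elastic stress in phase with strain, viscous stress 90
#' degrees out of phase. The interface unit for the modulus is kPa; it is
#' converted to Pa once, here.
#'
#' @param mu_kpa Shear modulus (kPa), > 0.
#' @param eta_pa_s Shear viscosity (Pa*s), >= 0.
#' @param rho Density (kg/m^3), > 0.
#' @return Object of class `voigt_params` with `mu` (Pa), `eta`, `rho`.
#' @export
voigt_params <- function(mu_kpa, eta_pa_s = 0, rho = 1000) {
  if (mu_kpa <= 0) stop("shear modulus must be > 0")
  if (eta_pa_s < 0) stop("viscosity must be >= 0")
  if (rho <= 0) stop("density must be > 0")
  structure(list(mu = mu_kpa * 1e3, eta = eta_pa_s, rho = rho),
            class = "voigt_params")
}

#' @export
print.voigt_params <- function(x, ...) {
  cat(sprintf("<voigt_params> mu %.4g kPa, eta %.4g Pa.s, rho %g kg/m^3\n",
              x$mu / 1e3, x$eta, x$rho))
  invisible(x)
}

#' Complex shear wavenumber of a Voigt medium
#'
#' `k(omega) = omega * sqrt(rho / (mu + i omega eta))` on the principal
#' branch, which has `Re k > 0` and `Im k <= 0`: an outgoing wave whose
#' magnitude of `Im k` is the attenuation per metre. With `eta = 0` the
#' wavenumber is real, `omega / sqrt(mu/rho)`.
#'
#' @param params A [voigt_params()].
#' @param omega Angular frequency (rad/s), > 0 (vectorised).
#' @return Complex wavenumber(s), 1/m.
#' @export
voigt_wavenumber <- function(params, omega) {
  stopifnot(inherits(params, "voigt_params"))
  if (any(omega <= 0)) stop("omega must be > 0")
  omega * sqrt(params$rho / complex(real = params$mu,
                                    imaginary = omega * params$eta))
}

#' Voigt phase velocity
#'
#' Closed form
#' `c(omega) = sqrt( 2 (mu^2 + omega^2 eta^2) / (rho (mu + sqrt(mu^2 + omega^2 eta^2))) )`
#' (mu in Pa), identical to `omega / Re(k)` from [voigt_wavenumber()]. With
#' `eta = 0` this is the non-dispersive `sqrt(mu/rho)` at every frequency;
#' with `eta > 0` the speed increases monotonically with frequency.
#'
#' @inheritParams voigt_wavenumber
#' @return Phase speed(s), m/s.
#' @export
voigt_phase_velocity <- function(params, omega) {
  stopifnot(inherits(params, "voigt_params"))
  if (any(omega <= 0)) stop("omega must be > 0")
  R <- sqrt(params$mu^2 + (omega * params$eta)^2)
  sqrt(2 * R^2 / (params$rho * (params$mu + R)))
}

#' Dispersion curve container
#' @param omega Strictly increasing positive angular frequencies (rad/s).
#' @param speed Positive phase speeds (m/s).
#' @param weights Optional fit weights (default 1).
#' @return Object of class `dispersion_curve`.
#' @export
dispersion_curve <- function(omega, speed, weights = NULL) {
  if (any(omega <= 0) || any(diff(omega) <= 0))
    stop("frequencies must be positive and strictly increasing")
  if (length(speed) != length(omega) || any(speed <= 0))
    stop("speeds must be positive, one per frequency")
  if (is.null(weights)) weights <- rep(1, length(omega))
  structure(list(omega = as.numeric(omega), speed = as.numeric(speed),
                 weights = as.numeric(weights)),
            class = "dispersion_curve")
}

#' Fit Voigt parameters to a phase-velocity dispersion curve
#'
#' Weighted nonlinear least squares of [voigt_phase_velocity()] against the
#' observed curve, with both parameters bounded below (mu > 0, eta >= 0),
#' solved by Levenberg-Marquardt (iteration cap 500). The default start takes
#' mu from the lowest-frequency speed (`rho c^2`) and eta = 0.5 Pa*s.
#'
#' @param curve A [dispersion_curve()] with >= 3 points spanning at least a
#'   factor of 2 in frequency.
#' @param density Density (kg/m^3).
#' @param initial Optional [voigt_params()] starting point.
#' @return A [voigt_params()] with attributes `residual_norm` (weighted
#'   2-norm) and `n_iterations`.
#' @export
fit_voigt <- function(curve, density = 1000, initial = NULL) {
  stopifnot(inherits(curve, "dispersion_curve"))
  if (length(curve$omega) < 3L) stop("need at least 3 frequency points")
  if (max(curve$omega) / min(curve$omega) < 2)
    stop("frequencies must span at least a factor of 2")
  if (is.null(initial)) {
    mu0 <- density * curve$speed[1]^2        # Pa, low-frequency limit
    start <- c(mu = mu0, eta = 0.5)
  } else {
    start <- c(mu = initial$mu, eta = initial$eta)
  }
  w <- sqrt(curve$weights)
  resid_fn <- function(p) {
    pr <- voigt_params(max(p[["mu"]], 1e-12) / 1e3, max(p[["eta"]], 0), density)
    w * (voigt_phase_velocity(pr, curve$omega) - curve$speed)
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            lower = c(mu = 1e-9, eta = 0),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  if (fit$info == 0 || fit$info == 9)
    stop("Voigt fit failed to converge within 500 iterations; last residual norm ",
         format(sqrt(fit$deviance)),
         " at mu = ", format(fit$par[["mu"]] / 1e3), " kPa, eta = ",
         format(fit$par[["eta"]]), " Pa.s")
  mu_hat <- fit$par[["mu"]]; eta_hat <- fit$par[["eta"]]; dev <- fit$deviance
  # the SSE gradient in eta vanishes at the eta = 0 boundary (the model
  # depends on eta only through (omega eta)^2), so LM can stall just off it;
  # compare against the elastic submodel and take the boundary when it is
  # at least as good
  mu_el <- density * (sum(curve$weights * curve$speed) / sum(curve$weights))^2
  dev_el <- sum((w * (sqrt(mu_el / density) - curve$speed))^2)
  if (dev_el <= dev * (1 + 1e-10)) {
    mu_hat <- mu_el; eta_hat <- 0; dev <- dev_el
  }
  out <- voigt_params(mu_hat / 1e3, eta_hat, density)
  attr(out, "residual_norm") <- sqrt(dev)
  attr(out, "n_iterations") <- fit$niter
  out
}

#' Young's modulus from shear-wave speed (and back)
#'
#' Clinical shear-wave elastography reports tissue stiffness as a Young's
#' modulus obtained from the group speed under the incompressibility
#' convention `E = 3 mu = 3 rho c^2` (Poisson ratio 0.5). Input speed in m/s,
#' output in kPa. `speed_from_young_modulus()` is the exact inverse.
#'
#' @param speed Shear-wave speed (m/s), > 0.
#' @param density Density (kg/m^3), > 0.
#' @return Young's modulus (kPa).
#' @export
young_modulus_from_speed <- function(speed, density = 1000) {
  if (any(speed <= 0)) stop("speed must be > 0")
  if (any(density <= 0)) stop("density must be > 0")
  3 * density * speed^2 / 1e3
}

#' @rdname young_modulus_from_speed
#' @param modulus_kpa Young's modulus (kPa), > 0.
#' @return Shear-wave speed (m/s).
#' @export
speed_from_young_modulus <- function(modulus_kpa, density = 1000) {
  if (any(modulus_kpa <= 0)) stop("modulus must be > 0")
  if (any(density <= 0)) stop("density must be > 0")
  sqrt(modulus_kpa * 1e3 / (3 * density))
}
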