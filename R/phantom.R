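#' Medium model: stiffness and viscosity maps on a lateral x depth grid
#'
#' Constructs the simulation ground truth: per-node shear modulus and shear
#' viscosity over a regular lateral x depth grid, plus a scalar density.
#' Moduli are accepted in kPa at the interface and stored in Pa internally
#' (all internal units are SI).
#'
#' @param lateral Strictly increasing, uniformly spaced lateral positions (m).
#' @param depth Strictly increasing, uniformly spaced depth positions (m).
#' @param shear_modulus_kpa Shear modulus in kPa: scalar or
#'   `length(lateral) x length(depth)` matrix.
#' @param viscosity_pa_s Shear viscosity in Pa*s: scalar or matrix as above.
#' @param density Density in kg/m^3 (scalar).
#' @return An object of class `swe_medium` with fields `lateral`, `depth`,
#'   `mu` (Pa, matrix), `eta` (Pa*s, matrix), `rho` (kg/m^3).
#' @export
medium_model <- function(lateral, depth = 0,
                         shear_modulus_kpa, viscosity_pa_s = 0,
                         density = 1000) {
  check_uniform_grid(lateral, "lateral")
  if (length(depth) > 1L) check_uniform_grid(depth, "depth")
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a positive scalar (kg/m^3)")
  nl <- length(lateral); nd <- length(depth)
  mu <- expand_node_field(shear_modulus_kpa, nl, nd, "shear_modulus_kpa") * 1e3
  eta <- expand_node_field(viscosity_pa_s, nl, nd, "viscosity_pa_s")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("shear modulus must be finite and > 0 everywhere")
  if (any(!is.finite(eta)) || any(eta < 0))
    stop("viscosity must be finite and >= 0 everywhere")
  structure(
    list(lateral = as.numeric(lateral), depth = as.numeric(depth),
         mu = mu, eta = eta, rho = as.numeric(density)),
    class = "swe_medium")
}

check_uniform_grid <- function(x, name) {
  if (length(x) < 2L) stop(name, " grid needs at least 2 points")
  d <- diff(x)
  if (any(d <= 0)) stop(name, " grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(abs(d)))
    stop(name, " grid must have constant spacing")
  invisible(x)
}

expand_node_field <- function(v, nl, nd, name) {
  if (length(v) == 1L) return(matrix(as.numeric(v), nl, nd))
  v <- as.matrix(v)
  if (nrow(v) != nl || ncol(v) != nd)
    stop(name, " must be scalar or a ", nl, " x ", nd, " matrix")
  storage.mode(v) <- "double"
  v
}

#' @export
print.swe_medium <- function(x, ...) {
  cat(sprintf("<swe_medium> %d lateral x %d depth nodes\n",
              length(x$lateral), length(x$depth)))
  cat(sprintf("  shear modulus: %.3g-%.3g kPa, viscosity: %.3g-%.3g Pa.s, rho %g kg/m^3\n",
              min(x$mu) / 1e3, max(x$mu) / 1e3, min(x$eta), max(x$eta), x$rho))
  invisible(x)
}

#' Build a tissue-mimicking phantom
#'
#' Constructs the virtual phantoms used throughout the toolkit: homogeneous
#' blocks, two-region layered media, a stiff circular inclusion in a soft
#' background, and a graded stiffness series emulating polyvinyl-alcohol
#' cryogel phantoms whose stiffness grows with each freeze-thaw cycle. The
#' graded-series presets (3, 9, 18, 30 kPa) are synthetic stand-ins chosen to
#' span the soft-tissue range; they are not measured values.
#'
#' @param kind One of `"homogeneous"`, `"layered"`, `"inclusion"`,
#'   `"graded_series"`.
#' @param lateral,depth Grid positions (m); see [medium_model()].
#' @param shear_modulus_kpa Homogeneous modulus (kPa).
#' @param viscosity_pa_s Viscosity (Pa*s), applied uniformly.
#' @param density Density (kg/m^3).
#' @param layers For `kind = "layered"`: list with `boundaries` (m, interior
#'   breakpoints along `axis`) and `moduli_kpa` (one per region, length
#'   `length(boundaries) + 1`).
#' @param axis Axis the layers stratify: `"lateral"` (default) or `"depth"`.
#' @param inclusion For `kind = "inclusion"`: list with `center` (c(x, z) m),
#'   `radius` (m), `modulus_kpa`; `shear_modulus_kpa` is the background.
#' @param presets_kpa For `kind = "graded_series"`: increasing stiffness
#'   presets (kPa), default `c(3, 9, 18, 30)`.
#' @return A `swe_medium`, or for `"graded_series"` a named list of them
#'   (one per preset, strictly increasing modulus).
#' @export
build_phantom <- function(kind = c("homogeneous", "layered", "inclusion", "graded_series"),
                          lateral = seq(0, 0.015, by = 2.5e-4),
                          depth = 0,
                          shear_modulus_kpa = 4,
                          viscosity_pa_s = 0,
                          density = 1000,
                          layers = NULL,
                          axis = c("lateral", "depth"),
                          inclusion = NULL,
                          presets_kpa = c(3, 9, 18, 30)) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (kind == "homogeneous") {
    return(medium_model(lateral, depth, shear_modulus_kpa, viscosity_pa_s, density))
  }
  if (kind == "graded_series") {
    if (any(diff(presets_kpa) <= 0))
      stop("graded_series presets must be strictly increasing")
    out <- lapply(presets_kpa, function(mu)
      medium_model(lateral, depth, mu, viscosity_pa_s, density))
    names(out) <- sprintf("mu_%g_kpa", presets_kpa)
    return(out)
  }
  if (kind == "layered") {
    if (is.null(layers) || is.null(layers$boundaries) || is.null(layers$moduli_kpa))
      stop("layered phantom needs layers = list(boundaries=, moduli_kpa=)")
    b <- sort(layers$boundaries)
    mus <- layers$moduli_kpa
    if (length(mus) != length(b) + 1L)
      stop("need one modulus per region: length(moduli_kpa) == length(boundaries) + 1")
    ax <- if (axis == "lateral") lateral else depth
    if (any(b <= min(ax)) || any(b >= max(ax)))
      stop("layer boundaries must lie strictly inside the ", axis, " grid")
    region <- findInterval(ax, b) + 1L
    prof <- mus[region]
    mu_mat <- if (axis == "lateral") {
      matrix(prof, length(lateral), length(depth))
    } else {
      matrix(rep(prof, each = length(lateral)), length(lateral), length(depth))
    }
    return(medium_model(lateral, depth, mu_mat, viscosity_pa_s, density))
  }
  # inclusion
  if (is.null(inclusion) || is.null(inclusion$center) ||
      is.null(inclusion$radius) || is.null(inclusion$modulus_kpa))
    stop("inclusion phantom needs inclusion = list(center=, radius=, modulus_kpa=)")
  ctr <- inclusion$center; r <- inclusion$radius
  if (length(depth) < 2L)
    stop("inclusion phantom needs a 2-D grid (length(depth) >= 2)")
  if (ctr[1] - r < min(lateral) || ctr[1] + r > max(lateral) ||
      ctr[2] - r < min(depth) || ctr[2] + r > max(depth))
    stop("inclusion disc (center +/- radius) must lie inside the grid")
  inside <- outer(lateral, depth,
                  function(x, z) (x - ctr[1])^2 + (z - ctr[2])^2 <= r^2)
  mu_mat <- matrix(shear_modulus_kpa, length(lateral), length(depth))
  mu_mat[inside] <- inclusion$modulus_kpa
  medium_model(lateral, depth, mu_mat, viscosity_pa_s, density)
}

#' Acoustic-radiation-force push pulse
#'
#' The push is idealised as a Gaussian displacement impulse in time centred at
#' `push_time` (t = 0 is the push centre by convention) applied at one lateral
#' position. In kinematic mode the peak displacement decays exponentially with
#' lateral distance from the push at rate `attenuation`.
#'
#' @param position Lateral push position (m).
#' @param width Gaussian temporal standard deviation (s), > 0.
#' @param amplitude Peak displacement (micrometres), >= 0.
#' @param push_time Time of the push centre (s).
#' @param attenuation Lateral amplitude decay rate (1/m), >= 0
#'   (kinematic mode only).
#' @return Object of class `swe_push`.
#' @export
push_pulse <- function(position = 0, width = 3e-4, amplitude = 10,
                       push_time = 0, attenuation = 0) {
  if (width <= 0) stop("push width must be > 0")
  if (amplitude < 0) stop("push amplitude must be >= 0")
  if (attenuation < 0) stop("push attenuation must be >= 0")
  structure(list(position = position, width = width, amplitude = amplitude,
                 push_time = push_time, attenuation = attenuation),
            class = "swe_push")
}

#' Tracking-beam acquisition grid
#'
#' Where and when the displacement is sampled: the tracked lateral channels,
#' tracked depths, temporal sampling interval (the inverse of the tracking
#' pulse-repetition frequency, PRF) and total observation duration.
#'
#' @param dt Temporal sampling interval (s) = 1 / PRF.
#' @param duration Observation duration (s); must cover the slowest arrival.
#' @param lateral Tracked lateral channel positions (m), strictly increasing.
#' @param depths Tracked depths (m).
#' @return Object of class `swe_grid`.
#' @export
acquisition_grid <- function(dt = 1e-4, duration = 1.5e-2,
                             lateral = seq(3e-3, 1e-2, by = 5e-4),
                             depths = 0) {
  if (dt <= 0) stop("sampling interval dt must be > 0")
  if (duration <= dt) stop("duration must exceed the sampling interval")
  if (any(diff(lateral) <= 0)) stop("tracked lateral positions must be strictly increasing")
  structure(list(dt = dt, duration = duration,
                 lateral = as.numeric(lateral), depths = as.numeric(depths)),
            class = "swe_grid")
}

#' Displacement field container
#'
#' @param values Numeric array `n_lateral x n_depth x n_time`, micrometres.
#' @param time_axis Time samples (s), starting at 0 with constant step.
#' @param lateral_axis,depth_axis Spatial axes (m).
#' @param noise_seed Integer seed of the stored noise realisation, or `NULL`
#'   for a noiseless field.
#' @param mode Simulation mode tag (`"kinematic"`, `"viscoelastic"`, or other
#'   provenance tag).
#' @param provenance Free-text provenance string.
#' @return Object of class `swe_field`.
#' @export
displacement_field <- function(values, time_axis, lateral_axis, depth_axis = 0,
                               noise_seed = NULL, mode = "unknown",
                               provenance = "") {
  values <- as_field_array(values, length(lateral_axis), length(depth_axis),
                           length(time_axis))
  if (abs(time_axis[1]) > 1e-15) stop("time axis must start at 0")
  check_uniform_grid(time_axis, "time")
  structure(list(values = values, time = as.numeric(time_axis),
                 lateral = as.numeric(lateral_axis),
                 depth = as.numeric(depth_axis),
                 noise_seed = noise_seed, mode = mode, provenance = provenance),
            class = "swe_field")
}

as_field_array <- function(values, nl, nd, nt) {
  if (is.matrix(values)) values <- array(values, dim = c(nrow(values), 1L, ncol(values)))
  d <- dim(values)
  if (length(d) != 3L || d[1] != nl || d[2] != nd || d[3] != nt)
    stop(sprintf("values must be a %d x %d x %d array (lateral x depth x time)",
                 nl, nd, nt))
  storage.mode(values) <- "double"
  values
}

#' @export
print.swe_field <- function(x, ...) {
  cat(sprintf("<swe_field> %d channels x %d depths x %d time samples (dt %.3g ms)\n",
              length(x$lateral), length(x$depth), length(x$time),
              diff(x$time[1:2]) * 1e3))
  cat(sprintf("  mode: %s; noise seed: %s\n", x$mode,
              if (is.null(x$noise_seed)) "none (noiseless)" else x$noise_seed))
  invisible(x)
}

#' Extract one depth row of a field as a channels x time matrix
#' @param field A `swe_field`.
#' @param depth_index 1-based depth index.
#' @return Numeric matrix `n_lateral x n_time`.
#' @export
field_slice <- function(field, depth_index = 1L) {
  nd <- length(field$depth)
  if (depth_index < 1L || depth_index > nd)
    stop("depth_index out of range 1..", nd)
  matrix(field$values[, depth_index, ], nrow = length(field$lateral))
}
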