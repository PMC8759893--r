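#' Scenario configuration
#'
#' A declarative description of one simulation study: phantom, push,
#' acquisition and noise. Round-trips losslessly through JSON
#' ([read_scenario()] / [write_scenario()]); unknown keys are rejected.
#'
#' @param phantom List passed to [build_phantom()] (must contain `kind`;
#'   geometry/moduli fields as that function documents, with grids given as
#'   `lateral = list(from, to, by)` style vectors or explicit numeric vectors).
#' @param push List of [push_pulse()] arguments.
#' @param acquisition List of [acquisition_grid()] arguments.
#' @param noise List with either `snr_db` (scalar) or `depth_snr_db` (one
#'   value per tracked depth); omit for a noiseless scenario.
#' @param seed Base integer seed for the scenario.
#' @return Object of class `swe_scenario` (a validated named list).
#' @export
scenario_config <- function(phantom = list(kind = "homogeneous"),
                            push = list(), acquisition = list(),
                            noise = NULL, seed = 1L) {
  sc <- list(phantom = phantom, push = push, acquisition = acquisition,
             noise = noise, seed = as.integer(seed),
             schema_version = "1.0")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  allowed <- c("phantom", "push", "acquisition", "noise", "seed", "schema_version")
  extra <- setdiff(names(sc), allowed)
  if (length(extra)) stop("unknown scenario keys: ", paste(extra, collapse = ", "))
  if (is.null(sc$phantom$kind)) stop("scenario phantom must name a kind")
  if (!is.null(sc$noise)) {
    nk <- setdiff(names(sc$noise), c("snr_db", "depth_snr_db"))
    if (length(nk)) stop("unknown noise keys: ", paste(nk, collapse = ", "))
  }
  structure(sc, class = "swe_scenario")
}

#' Resolve a scenario into simulation objects
#'
#' @param scenario A [scenario_config()] (or plain list in the same shape).
#' @return List with `medium`, `push`, `grid`, `snr_db` (per-depth vector or
#'   `NULL`), `true_speed` (m/s at each tracked depth, when derivable from a
#'   laterally homogeneous phantom, else `NA`).
#' @export
resolve_scenario <- function(scenario) {
  if (!inherits(scenario, "swe_scenario")) scenario <- validate_scenario(scenario)
  medium <- do.call(build_phantom, scenario$phantom)
  if (!inherits(medium, "swe_medium"))
    stop("benchmark scenarios must resolve to a single medium (not graded_series)")
  push <- do.call(push_pulse, scenario$push)
  grid <- do.call(acquisition_grid, scenario$acquisition)
  di <- match_depths(medium, grid)
  true_speed <- vapply(di, function(j) {
    mu <- medium$mu[, j]
    if (diff(range(mu)) <= 1e-9 * max(mu)) sqrt(mu[1] / medium$rho) else NA_real_
  }, numeric(1))
  snr <- NULL
  if (!is.null(scenario$noise)) {
    snr <- if (!is.null(scenario$noise$depth_snr_db))
      as.numeric(scenario$noise$depth_snr_db) else as.numeric(scenario$noise$snr_db)
  }
  list(medium = medium, push = push, grid = grid, snr_db = snr,
       true_speed = true_speed, seed = scenario$seed)
}

#' Monte-Carlo benchmark of the speed estimators
#'
#' Runs simulate -> add noise -> estimate for `n_trials` independent noise
#' realisations (the noiseless field is simulated once; each trial draws a
#' fresh noise realisation with a per-trial seed derived from `seed`) and
#' summarises each method's accuracy against the scenario's known true speed:
#' bias (mean error), random error (std), RMSE and mean goodness of fit. With
#' multiple tracked depths, estimates are produced per depth and the
#' across-depth spread (max - min of per-depth mean estimates) quantifies
#' depth robustness.
#'
#' @param scenario A [scenario_config()] resolvable to a homogeneous-per-depth
#'   medium with known true speed.
#' @param methods Character subset of `c("spm", "tdpm", "tspm", "radon")`.
#' @param n_trials Number of Monte-Carlo trials (>= 2).
#' @param seed Base seed; the full table is reproducible from
#'   (scenario, seed).
#' @param ... Extra arguments forwarded to the estimators; each argument is
#'   passed only to the methods whose interface accepts it (e.g.
#'   `speed_range` reaches only `radon`, `upsample_factor` only `tdpm`).
#' @return Data frame of class `swe_bench` with one row per method: `method`,
#'   `true_speed`, `bias`, `std`, `rmse`, `mean_r_squared`, `n_trials`,
#'   `n_failures`, `failed`, `per_depth_spread`. `std` is the population
#'   standard deviation so that `rmse^2 = bias^2 + std^2` holds exactly.
#'   A method failing on more than half the trials is marked `failed = TRUE`
#'   (with its failure count) rather than dropped.
#' @export
benchmark_methods <- function(scenario, methods = c("spm", "tdpm"),
                              n_trials = 100L, seed = 1L, ...) {
  methods <- match.arg(methods, c("spm", "tdpm", "tspm", "radon"),
                       several.ok = TRUE)
  if (n_trials < 2L) stop("n_trials must be >= 2")
  rs <- resolve_scenario(scenario)
  if (any(is.na(rs$true_speed)))
    stop("benchmark requires a known true speed at every tracked depth")
  base_field <- simulate_displacement(rs$medium, rs$push, rs$grid)
  nd <- length(rs$grid$depths)
  est <- array(NA_real_, dim = c(n_trials, nd, length(methods)),
               dimnames = list(NULL, NULL, methods))
  r2 <- est
  for (tr in seq_len(n_trials)) {
    f <- if (is.null(rs$snr_db)) base_field else
      add_noise(base_field, rs$snr_db, seed = derive_seed(seed, tr))
    for (mi in seq_along(methods)) for (j in seq_len(nd)) {
      extra <- method_args(methods[mi], list(...))
      e <- tryCatch(do.call(estimate_sws,
                            c(list(f, methods[mi], depth_index = j), extra)),
                    error = function(err) NULL)
      if (!is.null(e)) {
        est[tr, j, mi] <- e$speed
        r2[tr, j, mi] <- e$r_squared
      }
    }
  }
  rows <- lapply(seq_along(methods), function(mi) {
    e <- est[, , mi, drop = FALSE]
    ok <- is.finite(e)
    n_fail <- sum(!ok)
    errs <- e[ok] - rep(rs$true_speed, each = n_trials)[ok]
    bias <- mean(errs)
    stdev <- sqrt(mean((errs - bias)^2))
    spread <- if (nd > 1L) {
      dm <- colMeans(matrix(e, n_trials, nd), na.rm = TRUE)
      max(dm) - min(dm)
    } else NA_real_
    data.frame(method = toupper(methods[mi]),
               true_speed = mean(rs$true_speed),
               bias = bias, std = stdev,
               rmse = sqrt(bias^2 + stdev^2),
               mean_r_squared = mean(r2[, , mi][is.finite(r2[, , mi])]),
               n_trials = n_trials,
               n_failures = n_fail,
               failed = n_fail > n_trials * nd / 2,
               per_depth_spread = spread)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("swe_bench", class(out))
  out
}

# Keep only the arguments the method's detector/estimator accepts.
method_args <- function(method, args) {
  fun <- switch(method, spm = detect_arrivals_spm, tdpm = detect_arrivals_tdpm,
                tspm = estimate_tspm, radon = estimate_radon)
  args[names(args) %in% names(formals(fun))]
}

# Per-trial seed derivation; kept well below 2^31.
derive_seed <- function(base, trial) {
  as.integer((as.numeric(base) * 1000003 + trial * 7919) %% 2147483629)
}
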