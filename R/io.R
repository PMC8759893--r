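SCHEMA_VERSION <- "1.0"

#' Write a displacement field to an HDF5 container
#'
#' Layout: datasets `displacement` (lateral x depth x time, micrometres),
#' `lateral_axis`, `depth_axis`, `time_axis`; root attributes `noise_seed`
#' (-1 when noiseless), `mode`, `schema_version`. Write-then-read reproduces
#' the array bit-exactly.
#'
#' @param field A [displacement_field()].
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "swe_field"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(field$values, path, "displacement")
  rhdf5::h5write(field$lateral, path, "lateral_axis")
  rhdf5::h5write(field$depth, path, "depth_axis")
  rhdf5::h5write(field$time, path, "time_axis")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(if (is.null(field$noise_seed)) -1L else
    as.integer(field$noise_seed), fid, "noise_seed")
  rhdf5::h5writeAttribute(field$mode, fid, "mode")
  rhdf5::h5writeAttribute(SCHEMA_VERSION, fid, "schema_version")
  rhdf5::h5writeAttribute(field$provenance, fid, "provenance")
  invisible(path)
}

#' Read a displacement field from an HDF5 container
#'
#' @param path Path written by [write_field()] (or conforming to its schema).
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  need <- c("displacement", "lateral_axis", "depth_axis", "time_axis")
  missing <- setdiff(need, ls$name)
  if (length(missing))
    stop("field container is missing dataset(s): ", paste(missing, collapse = ", "))
  vals <- rhdf5::h5read(path, "displacement")
  lat <- as.numeric(rhdf5::h5read(path, "lateral_axis"))
  dep <- as.numeric(rhdf5::h5read(path, "depth_axis"))
  tim <- as.numeric(rhdf5::h5read(path, "time_axis"))
  d <- dim(vals)
  if (length(d) != 3L || d[1] != length(lat) || d[2] != length(dep) || d[3] != length(tim))
    stop("displacement dimensions do not match the axis lengths (",
         paste(d, collapse = "x"), " vs ", length(lat), "/", length(dep), "/",
         length(tim), ")")
  att <- rhdf5::h5readAttributes(path, "/")
  sv <- as.character(att$schema_version)
  if (!identical(sv, SCHEMA_VERSION))
    stop("unsupported schema_version: ", sv)
  seed <- as.integer(att$noise_seed)
  displacement_field(vals, tim, lat, dep,
                     noise_seed = if (isTRUE(seed >= 0)) seed else NULL,
                     mode = as.character(att$mode),
                     provenance = as.character(att$provenance %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a scenario configuration as JSON
#'
#' @param scenario A [scenario_config()].
#' @param path JSON file path.
#' @return `write_scenario()`: `path` invisibly; `read_scenario()`: a
#'   validated `swe_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  if (!inherits(scenario, "swe_scenario")) scenario <- validate_scenario(scenario)
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_scenario(sc)
}

#' Hash of a scenario configuration
#'
#' MD5 of the canonical (compact, unboxed) JSON serialisation; used by the
#' run log so that identical configurations hash identically.
#'
#' @param scenario A [scenario_config()].
#' @return Hex digest string.
#' @export
scenario_hash <- function(scenario) {
  if (!inherits(scenario, "swe_scenario")) scenario <- validate_scenario(scenario)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(scenario), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

#' Generate the standard offline fixture set
#'
#' Emits, reproducibly from `seed`: the graded stiffness series (4 presets,
#' noiseless and 20 dB variants), one stiff-inclusion field, one
#' depth-degraded (depth-indexed SNR) field, a two-rater reading matrix CSV
#' and a labelled scored-cohort CSV, plus `manifest.json` with per-file MD5
#' checksums. All tabular fixtures are synthetic draws, not study data.
#'
#' @param out_dir Output directory (created if absent). A non-empty existing
#'   directory is refused unless `force = TRUE`.
#' @param seed Integer seed controlling every random fixture.
#' @param force Overwrite into a non-empty directory.
#' @return The manifest (named list: file -> md5), invisibly written to
#'   `manifest.json`.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  push <- push_pulse(attenuation = 50)
  grid <- acquisition_grid()
  files <- character(0)

  presets <- c(3, 9, 18, 30)
  series <- build_phantom("graded_series", presets_kpa = presets)
  for (i in seq_along(series)) {
    f <- simulate_displacement(series[[i]], push, grid)
    p0 <- file.path(out_dir, sprintf("graded_mu%02g_noiseless.h5", presets[i]))
    write_field(f, p0)
    pn <- file.path(out_dir, sprintf("graded_mu%02g_snr20.h5", presets[i]))
    write_field(add_noise(f, 20, seed = derive_seed(seed, i)), pn)
    files <- c(files, p0, pn)
  }

  inc <- build_phantom("inclusion",
                       lateral = seq(0, 0.015, by = 2.5e-4),
                       depth = seq(0, 0.01, by = 5e-4),
                       shear_modulus_kpa = 3,
                       inclusion = list(center = c(7.5e-3, 5e-3), radius = 3e-3,
                                        modulus_kpa = 12))
  grid_inc <- acquisition_grid(depths = 5e-3)
  f_inc <- simulate_displacement(inc, push, grid_inc)
  p_inc <- file.path(out_dir, "inclusion_field.h5")
  write_field(f_inc, p_inc); files <- c(files, p_inc)

  depth_med <- build_phantom("homogeneous",
                             lateral = seq(0, 0.015, by = 2.5e-4),
                             depth = seq(0.01, 0.05, by = 0.01),
                             shear_modulus_kpa = 9)
  grid_dep <- acquisition_grid(depths = seq(0.01, 0.05, by = 0.01))
  f_dep <- simulate_displacement(depth_med, push, grid_dep)
  f_dep <- add_noise(f_dep, seq(25, 10, length.out = 5),
                     seed = derive_seed(seed, 100L))
  p_dep <- file.path(out_dir, "depth_snr_field.h5")
  write_field(f_dep, p_dep); files <- c(files, p_dep)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, 200L))
  true_e <- stats::runif(30, 5, 120)
  raters <- data.frame(rater1 = round(true_e + stats::rnorm(30, sd = 4), 2),
                       rater2 = round(true_e + stats::rnorm(30, sd = 4), 2))
  p_rat <- file.path(out_dir, "rater_matrix.csv")
  utils::write.csv(raters, p_rat, row.names = FALSE); files <- c(files, p_rat)

  lab <- rep(c(0L, 1L), times = c(35, 25))
  sc <- round(ifelse(lab == 1L, stats::rnorm(60, 90, 25), stats::rnorm(60, 40, 18)), 2)
  cohort <- data.frame(label = lab, score = sc)
  p_coh <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, p_coh, row.names = FALSE); files <- c(files, p_coh)

  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Pathology composition of the reference lesion cohort
#'
#' Per-type lesion counts of the study cohort the statistics module is sized
#' for (six malignant and six benign histological types), shipped as a CSV in
#' `inst/extdata`. Group totals are recomputed from the per-type rows, not
#' stored.
#'
#' @return Data frame with columns `group` ("malignant"/"benign"), `type`,
#'   `n_cases`.
#' @export
pathology_counts <- function() {
  path <- system.file("extdata", "pathology_counts.csv", package = "swetools",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a rater matrix or scored cohort from CSV
#'
#' `read_rater_matrix()` expects one row per lesion and one numeric column per
#' rater; `read_cohort()` expects columns `label` (0/1) and `score`.
#'
#' @param path CSV file path.
#' @param metric_name Metric label for the rater matrix.
#' @return A [rater_matrix()] or [scored_cohort()].
#' @export
read_rater_matrix <- function(path, metric_name = "Emax") {
  df <- utils::read.csv(path)
  rater_matrix(as.matrix(df), metric_name = metric_name)
}

#' @rdname read_rater_matrix
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("label", "score") %in% names(df)))
    stop("cohort CSV needs columns 'label' and 'score'")
  scored_cohort(df$label, df$score)
}
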