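#' Configuration for a pipeline run
#'
#' Collects every knob of the two pipelines (granularity selection and
#' kriging) in one list so runs are reproducible: a config plus a seed
#' fully determines the numeric outputs, and each run serialises its
#' manifest (config, seed, package version) next to its outputs.
#'
#' @param input optional daily CSV path (EPA layout); `NULL` when a dataset
#'   is passed directly to the runner.
#' @param sites optional site-coordinates sidecar CSV.
#' @param pollutant pollutant name.
#' @param value `"aqi"` or `"mean"`.
#' @param date_range optional `c(from, to)`.
#' @param scales candidate hexagon side lengths (km).
#' @param weights_style `"row"` or `"binary"`.
#' @param permutations permutation count for pseudo-significance.
#' @param seed integer seed for all randomness.
#' @param variogram_model `"exponential"`, `"spherical"` or `"gaussian"`.
#' @param grid_n prediction-grid resolution per axis.
#' @param threshold optional exceedance threshold (enables indicator
#'   kriging).
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, sites = NULL, pollutant = "O3",
                       value = "aqi", date_range = NULL,
                       scales = c(100, 200, 300, 400, 500),
                       weights_style = "row", permutations = 999,
                       seed = 1L, variogram_model = "exponential",
                       grid_n = 25, threshold = NULL, out_dir = ".") {
  structure(list(input = input, sites = sites, pollutant = pollutant,
                 value = value, date_range = date_range, scales = scales,
                 weights_style = weights_style, permutations = permutations,
                 seed = as.integer(seed), variogram_model = variogram_model,
                 grid_n = grid_n, threshold = threshold, out_dir = out_dir),
            class = "run_config")
}

load_config_data <- function(config, data = NULL) {
  if (!is.null(data)) {
    pd <- data
  } else {
    if (is.null(config$input) || is.null(config$sites))
      stop("config must name input and sites files when no dataset is given",
           call. = FALSE)
    pd <- read_epa_daily(config$input, config$sites,
                         pollutant = config$pollutant, value = config$value,
                         date_range = config$date_range)
    pd <- temporal_reduce(pd, period = "year")
  }
  if (pd$crs == "lonlat") pd <- project_to_planar(pd)
  pd
}

write_manifest <- function(config, out_dir) {
  cfg <- unclass(config)
  cfg$package_version <- as.character(utils::packageVersion("spatgran"))
  cfg$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(cfg, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the granularity-selection pipeline
#'
#' Reads (or accepts) a point dataset, evaluates the configured candidate
#' scales with [evaluate_scales()] and writes `candidates.csv`
#' (`scale, GM, LMCV, n_cells, frontier_rank`) plus `manifest.json` to the
#' output directory.
#'
#' @param config a [run_config()].
#' @param data optional [point_data()] bypassing file input.
#' @return The `granularity_eval`, invisibly.
#' @export
run_granularity <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  pd <- load_config_data(config, data)
  ev <- evaluate_scales(pd, config$scales, style = config$weights_style,
                        permutations = config$permutations,
                        seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(scale = ev$scale, GM = ev$GM, LMCV = ev$LMCV,
               n_cells = ev$n_cells, frontier_rank = ev$frontier_rank),
    file.path(config$out_dir, "candidates.csv"), row.names = FALSE)
  write_manifest(config, config$out_dir)
  invisible(ev)
}

#' Run the interpolation pipeline
#'
#' The kriging workflow: normalise the values, fit the variogram, krige a
#' regular grid, back-transform the estimates, and (when a threshold is
#' configured) add an indicator-kriging exceedance surface. Writes
#' `prediction.csv` (`x, y, estimate, variance`), `variogram.json`,
#' optionally `exceedance.csv`, and `manifest.json`.
#'
#' @inheritParams run_granularity
#' @return List with `prediction`, `variogram`, `normalizer` and (optional)
#'   `exceedance`, invisibly.
#' @export
run_krige <- function(config, data = NULL) {
  stopifnot(inherits(config, "run_config"))
  pd <- load_config_data(config, data)
  nz <- normalize_values(pd$values)
  work <- point_data(pd$x, pd$y, nz$values, crs = "planar-km")
  vg <- fit_variogram(empirical_variogram(work),
                      model = config$variogram_model)
  pr <- ordinary_kriging(work, vg, grid_n = config$grid_n)
  pr$estimate <- inverse_normalize(pr$estimate, nz$transform)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_prediction(pr, file.path(config$out_dir, "prediction.csv"))
  write_variogram(vg, file.path(config$out_dir, "variogram.json"))
  exc <- NULL
  if (!is.null(config$threshold)) {
    exc <- indicator_kriging(pd, config$threshold, grid_n = config$grid_n,
                             model = config$variogram_model)
    write_prediction(exc, file.path(config$out_dir, "exceedance.csv"))
  }
  write_manifest(config, config$out_dir)
  invisible(list(prediction = pr, variogram = vg, normalizer = nz,
                 exceedance = exc))
}
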