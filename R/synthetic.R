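#' Specification of a synthetic spatially autocorrelated sensor field
#'
#' Describes the study conditions a simulated monitoring network emulates:
#' sensor locations scattered uniformly over a planar km rectangle, with
#' values drawn jointly from a stationary Gaussian random field with an
#' exponential (or Gaussian) covariance `C(h) = sill * exp(-h/a)` plus
#' independent nugget noise, shifted by a constant mean. Defaults emulate a
#' regional pollutant surface: a 1000x800 km region, 200 sensors,
#' correlation range 150 km, unit sill, 10% nugget, mean 60 (an AQI-like
#' level).
#'
#' @param bbox planar km rectangle `c(xmin, ymin, xmax, ymax)`.
#' @param n_points number of sensors (capped at 3000; values are sampled by
#'   dense covariance factorisation).
#' @param covariance `"exponential"`, `"gaussian"` or `"nugget-only"`.
#' @param range_km correlation range `a` (km); ignored for nugget-only.
#' @param sill structured variance (value^2).
#' @param nugget micro-scale noise variance (value^2).
#' @param mean constant mean level.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return Object of class `field_spec` (a list of the above).
#' @export
field_spec <- function(bbox = c(0, 0, 1000, 800), n_points = 200,
                       covariance = c("exponential", "gaussian", "nugget-only"),
                       range_km = 150, sill = 1, nugget = 0.1, mean = 60,
                       seed = 1L) {
  covariance <- match.arg(covariance)
  stopifnot(n_points >= 1, sill >= 0, nugget >= 0)
  if (covariance != "nugget-only" && range_km <= 0)
    stop("range_km must be positive", call. = FALSE)
  if (n_points > 3000)
    stop("n_points capped at 3000 (dense covariance factorisation)",
         call. = FALSE)
  structure(list(bbox = as.numeric(bbox), n_points = as.integer(n_points),
                 covariance = covariance, range_km = range_km, sill = sill,
                 nugget = nugget, mean = mean, seed = as.integer(seed)),
            class = "field_spec")
}

#' Simulate a sensor network over a stationary random field
#'
#' Draws `n_points` uniform locations in the spec's bbox and one joint
#' sample of the field at those locations: covariance matrix
#' `C(h) = sill * rho(h/a)` (+ nugget on the diagonal), Cholesky factor,
#' standard normal draw. Identical specs (including seed) give bit-identical
#' datasets.
#'
#' @param spec a [field_spec()].
#' @return A planar-km [point_data()]; `meta$spec` keeps the generating spec.
#' @examples
#' pd <- simulate_field(field_spec(n_points = 50, seed = 7))
#' pd
#' @export
simulate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- spec$n_points
  x <- stats::runif(n, spec$bbox[1], spec$bbox[3])
  y <- stats::runif(n, spec$bbox[2], spec$bbox[4])
  h <- as.matrix(stats::dist(cbind(x, y)))
  C <- switch(spec$covariance,
              "exponential" = spec$sill * exp(-h / spec$range_km),
              "gaussian"    = spec$sill * exp(-(h / spec$range_km)^2),
              "nugget-only" = matrix(0, n, n))
  diag(C) <- spec$sill * (spec$covariance != "nugget-only") + spec$nugget
  if (spec$nugget == 0) diag(C) <- diag(C) + 1e-10  # factorisation jitter
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix not positive definite after jitter", call. = FALSE))
  z <- spec$mean + drop(crossprod(L, stats::rnorm(n)))
  point_data(x, y, z, crs = "planar-km", meta = list(spec = spec))
}

#' Checkerboard lattice fixture with alternating values
#'
#' A degenerate ground-truth layer for negative spatial autocorrelation:
#' a rectangular lattice of cells with values alternating +1/-1, so every
#' neighbour pair disagrees. Returned in the same shape as an aggregated
#' [hex_aggregate()] layer (square cells on a rook lattice stand in for the
#' hexagon graph) so the Moran machinery runs on it unchanged.
#'
#' @param n_cells_x,n_cells_y lattice dimensions (each >= 2).
#' @param side cell spacing in km.
#' @return List with `values` (alternating, by row-major lattice order) and
#'   `weights` (a rook-lattice `spatial_weights`, binary style).
#' @examples
#' cb <- fixture_checkerboard(4, 4)
#' moran <- global_moran(cb$values, cb$weights, permutations = 0)
#' moran$I  # strongly negative
#' @export
fixture_checkerboard <- function(n_cells_x, n_cells_y, side = 1) {
  stopifnot(n_cells_x >= 2, n_cells_y >= 2)
  idx <- expand.grid(ix = seq_len(n_cells_x), iy = seq_len(n_cells_y))
  values <- ifelse((idx$ix + idx$iy) %% 2 == 0, 1, -1)
  n <- nrow(idx)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    nb[[i]] <- which((abs(idx$ix - idx$ix[i]) + abs(idx$iy - idx$iy[i])) == 1)
  }
  w <- lapply(nb, function(j) rep(1, length(j)))
  weights <- structure(list(n = n, ids = seq_len(n), neighbors = nb,
                            weights = w, style = "binary",
                            isolated = lengths(nb) == 0L),
                       class = "spatial_weights")
  list(values = values, weights = weights,
       centers = data.frame(x = (idx$ix - 1) * side, y = (idx$iy - 1) * side))
}

#' Write a simulated dataset as the canonical points CSV plus site sidecar
#'
#' Emits the two files the EPA-layout reader path consumes: a daily table
#' with `State Code, County Code, Site Num, Date Local` and the pollutant's
#' AQI column, and a sidecar CSV mapping each synthetic site key to
#' longitude/latitude. Coordinates are produced by inverting the default
#' planar projection about (`lon0`, `lat0`), so reading the pair back
#' through [read_epa_daily()] round-trips the values.
#'
#' @param data a planar-km [point_data()].
#' @param dir output directory.
#' @param pollutant pollutant name for the AQI column (default `"O3"`).
#' @param date ISO date stamped on every row.
#' @param lon0,lat0 centre of the synthetic geography.
#' @return Named character vector with elements `daily` and `sites`.
#' @export
write_synthetic_epa <- function(data, dir, pollutant = "O3",
                                date = "2015-06-01", lon0 = -98, lat0 = 38) {
  stopifnot(inherits(data, "point_data"), data$crs == "planar-km")
  proj <- list(method = "equirectangular", lon0 = lon0, lat0 = lat0,
               radius_km = EARTH_RADIUS_KM)
  ll <- planar_to_lonlat(data$x, data$y, proj)
  n <- length(data$x)
  daily <- data.frame(check.names = FALSE,
    "State Code" = 1L, "County Code" = 1L, "Site Num" = seq_len(n),
    "Date Local" = date)
  daily[[paste(pollutant, "AQI")]] <- data$values
  sites <- data.frame(check.names = FALSE,
    "State Code" = 1L, "County Code" = 1L, "Site Num" = seq_len(n),
    Longitude = ll$lon, Latitude = ll$lat)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  daily_path <- file.path(dir, "daily_synthetic.csv")
  sites_path <- file.path(dir, "sites_synthetic.csv")
  utils::write.csv(daily, daily_path, row.names = FALSE)
  utils::write.csv(sites, sites_path, row.names = FALSE)
  c(daily = daily_path, sites = sites_path)
}
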