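# Earth radius (km) used by the default equirectangular projection: WGS84
# equatorial radius, so one degree of longitude at the equator maps to
# ~111.32 km.
EARTH_RADIUS_KM <- 6378.137

#' Point-referenced sensor observations
#'
#' Container for a set of point observations: coordinates plus one numeric
#' value per point (a pollutant concentration or an AQI value). Coordinates
#' are either geographic longitude/latitude in degrees (`crs = "lonlat"`) or
#' planar kilometres (`crs = "planar-km"`), typically obtained from
#' [project_to_planar()].
#'
#' @param x,y numeric coordinate vectors (longitude/latitude in degrees, or
#'   planar km, according to `crs`).
#' @param values numeric vector of observed values, one per point.
#' @param crs coordinate tag, `"lonlat"` or `"planar-km"`.
#' @param meta optional list of extra per-dataset metadata (kept as-is).
#'
#' @return An object of class `point_data`: a list with elements `x`, `y`,
#'   `values`, `crs` and `meta`.
#' @examples
#' pd <- point_data(c(0, 1), c(0, 0), values = c(10, 20), crs = "lonlat")
#' pd
#' @export
point_data <- function(x, y, values, crs = c("lonlat", "planar-km"),
                       meta = list()) {
  crs <- match.arg(crs)
  x <- as.numeric(x)
  y <- as.numeric(y)
  values <- as.numeric(values)
  if (length(x) != length(y) || length(x) != length(values))
    stop("x, y and values must have equal length", call. = FALSE)
  if (length(x) < 1L)
    stop("a point dataset needs at least one point", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite coordinates", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite values in point dataset", call. = FALSE)
  if (crs == "lonlat" && (any(y < -90) || any(y > 90)))
    stop("invalid coordinate: latitude outside [-90, 90]", call. = FALSE)
  structure(list(x = x, y = y, values = values, crs = crs, meta = meta),
            class = "point_data")
}

#' @export
print.point_data <- function(x, ...) {
  cat(sprintf("<point_data> %d points [%s]\n", length(x$x), x$crs))
  cat(sprintf("  x: [%.4g, %.4g]  y: [%.4g, %.4g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  values: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.point_data <- function(x) length(x$x)

#' @export
as.data.frame.point_data <- function(x, ...) {
  data.frame(x = x$x, y = x$y, value = x$values)
}

#' Project geographic coordinates to a planar km frame
#'
#' Maps longitude/latitude to planar kilometres with an equirectangular
#' projection about a reference point (by default the data centroid):
#' `x = R cos(lat0) (lon - lon0) pi/180`, `y = R (lat - lat0) pi/180` with
#' `R` the WGS84 equatorial radius. Adequate at the regional scales the
#' areal-unit analysis works at; cell areas are approximate, and an inverse
#' mapping is attached so prediction grids can be written back in lon/lat.
#'
#' @param data a [point_data()] with `crs = "lonlat"`.
#' @param lon0,lat0 projection centre in degrees; defaults to the data
#'   centroid.
#'
#' @return A `point_data` with `crs = "planar-km"`. The projection centre is
#'   stored in `meta$proj` and [planar_to_lonlat()] inverts the mapping.
#' @examples
#' pd <- point_data(c(0, 1), c(0, 0), c(1, 2), crs = "lonlat")
#' pl <- project_to_planar(pd, lon0 = 0, lat0 = 0)
#' pl$x  # second point at ~111.32 km
#' @export
project_to_planar <- function(data, lon0 = NULL, lat0 = NULL) {
  stopifnot(inherits(data, "point_data"))
  if (data$crs != "lonlat")
    stop("project_to_planar() expects lonlat coordinates", call. = FALSE)
  if (is.null(lon0)) lon0 <- mean(data$x)
  if (is.null(lat0)) lat0 <- mean(data$y)
  if (lat0 < -90 || lat0 > 90)
    stop("invalid coordinate: latitude outside [-90, 90]", call. = FALSE)
  deg <- pi / 180
  px <- EARTH_RADIUS_KM * cos(lat0 * deg) * (data$x - lon0) * deg
  py <- EARTH_RADIUS_KM * (data$y - lat0) * deg
  meta <- data$meta
  meta$proj <- list(method = "equirectangular", lon0 = lon0, lat0 = lat0,
                    radius_km = EARTH_RADIUS_KM)
  point_data(px, py, data$values, crs = "planar-km", meta = meta)
}

#' Invert the planar projection back to longitude/latitude
#'
#' @param x,y planar coordinates in km.
#' @param proj the projection descriptor stored by [project_to_planar()]
#'   (`meta$proj` of the projected dataset).
#' @return A data frame with columns `lon` and `lat` in degrees.
#' @export
planar_to_lonlat <- function(x, y, proj) {
  stopifnot(is.list(proj), proj$method == "equirectangular")
  deg <- pi / 180
  lon <- proj$lon0 + x / (proj$radius_km * cos(proj$lat0 * deg) * deg)
  lat <- proj$lat0 + y / (proj$radius_km * deg)
  data.frame(lon = lon, lat = lat)
}

#' Bounding box of a point dataset
#'
#' @param data a `point_data`.
#' @param pad fraction of the larger side added on each edge (default 0).
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
bbox_of <- function(data, pad = 0) {
  stopifnot(inherits(data, "point_data"))
  b <- c(xmin = min(data$x), ymin = min(data$y),
         xmax = max(data$x), ymax = max(data$y))
  if (pad > 0) {
    m <- pad * max(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"], 1e-9)
    b <- b + c(-m, -m, m, m)
  }
  b
}
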