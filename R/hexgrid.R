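# Flat-top hexagon geometry in axial (q, r) coordinates.
# Centre of cell (q, r):  x = 1.5 s q,  y = sqrt(3) s (r + q/2).
# All six neighbour centres sit at distance sqrt(3) s.

hex_center <- function(q, r, side) {
  list(x = 1.5 * side * q, y = sqrt(3) * side * (r + q / 2))
}

# fractional axial coordinates of a point, then cube rounding
hex_axial_of <- function(x, y, side) {
  qf <- (2 / 3) * x / side
  rf <- (-x / 3 + sqrt(3) / 3 * y) / side
  cube_round(qf, rf)
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

# axial offsets of the six neighbours of a flat-top hexagon
HEX_NEIGHBOR_OFFSETS <- cbind(q = c(1L, 1L, 0L, -1L, -1L, 0L),
                              r = c(0L, -1L, -1L, 0L, 1L, 1L))

#' Build a regular hexagonal areal-unit layer over a bounding box
#'
#' Tiles `bbox` with flat-top regular hexagons of the requested side length.
#' The grid is anchored so that a cell centre sits at the lower-left corner
#' of the box (plus an optional `origin` offset — an analyst-visible choice,
#' since grid placement is itself a modifiable-areal-unit decision). Every
#' point of the box falls in exactly one cell.
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` in planar km.
#' @param side hexagon side length in km (e.g. the 100--500 km candidate
#'   scales of a continental analysis).
#' @param origin length-2 offset (km) added to the grid anchor; default
#'   `c(0, 0)`.
#'
#' @return An object of class `hex_layer`: list with `side`, `origin`,
#'   `centers` (data frame `cell_id, q, r, x, y`), `bbox`, and empty
#'   aggregation slots filled by [hex_aggregate()].
#' @examples
#' layer <- make_hex_grid(c(0, 0, 300, 200), side = 50)
#' layer
#' @export
make_hex_grid <- function(bbox, side, origin = c(0, 0)) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("bbox must be c(xmin, ymin, xmax, ymax) with positive extent",
         call. = FALSE)
  if (!is.finite(side) || side <= 0)
    stop("side length must be positive", call. = FALSE)
  if (side > (bbox[3] - bbox[1]) && side > (bbox[4] - bbox[2]))
    warning("side length exceeds both bbox dimensions; layer may be a single cell")
  ox <- bbox[1] + origin[1]
  oy <- bbox[2] + origin[2]
  # candidate axial range: any cell whose centre lies within one cell
  # diameter of the box can receive a box point
  m <- 2 * side
  qmin <- floor((bbox[1] - ox - m) / (1.5 * side))
  qmax <- ceiling((bbox[3] - ox + m) / (1.5 * side))
  cells <- list()
  k <- 0L
  for (q in qmin:qmax) {
    # y = sqrt(3) s (r + q/2)
    rmin <- floor((bbox[2] - oy - m) / (sqrt(3) * side) - q / 2)
    rmax <- ceiling((bbox[4] - oy + m) / (sqrt(3) * side) - q / 2)
    r <- rmin:rmax
    ctr <- hex_center(rep(q, length(r)), r, side)
    keep <- ctr$x + ox >= bbox[1] - sqrt(3) * side &
            ctr$x + ox <= bbox[3] + sqrt(3) * side &
            ctr$y + oy >= bbox[2] - sqrt(3) * side &
            ctr$y + oy <= bbox[4] + sqrt(3) * side
    if (any(keep)) {
      k <- k + 1L
      cells[[k]] <- data.frame(q = q, r = r[keep],
                               x = ctr$x[keep] + ox, y = ctr$y[keep] + oy)
    }
  }
  centers <- do.call(rbind, cells)
  centers <- centers[order(centers$x, centers$y), , drop = FALSE]
  centers <- data.frame(cell_id = seq_len(nrow(centers)),
                        q = centers$q, r = centers$r,
                        x = centers$x, y = centers$y)
  structure(list(side = side, origin = c(ox, oy), orientation = "flat-top",
                 centers = centers, bbox = bbox,
                 cell_values = NULL, cell_counts = NULL,
                 statistic = NULL, min_count = NULL),
            class = "hex_layer")
}

#' @export
print.hex_layer <- function(x, ...) {
  cat(sprintf("<hex_layer> %d cells, side %.4g km (%s)\n",
              nrow(x$centers), x$side, x$orientation))
  if (!is.null(x$cell_values)) {
    ne <- sum(!is.na(x$cell_values))
    cat(sprintf("  aggregated: %d non-empty cells (statistic = %s, min_count = %d)\n",
                ne, x$statistic, x$min_count))
  }
  invisible(x)
}

#' Vertices of one hexagon cell
#'
#' @param layer a `hex_layer`.
#' @param cell_id cell identifier.
#' @return 6x2 matrix of polygon vertices (closed implicitly).
#' @export
hex_vertices <- function(layer, cell_id) {
  i <- match(cell_id, layer$centers$cell_id)
  if (is.na(i)) stop("unknown cell_id", call. = FALSE)
  ang <- (0:5) * pi / 3
  cbind(x = layer$centers$x[i] + layer$side * cos(ang),
        y = layer$centers$y[i] + layer$side * sin(ang))
}

#' Assign points to hexagon cells
#'
#' Each point is assigned to the cell containing it; a point exactly on a
#' shared boundary goes to the equidistant cell whose centre is
#' lexicographically smallest in (x, y), so the assignment is a
#' deterministic partition.
#'
#' @param layer a `hex_layer`.
#' @param x,y planar km coordinates.
#' @return Integer vector of `cell_id`s (`NA` for points outside the layer).
#' @export
hex_assign <- function(layer, x, y) {
  side <- layer$side
  ox <- layer$origin[1]; oy <- layer$origin[2]
  ax <- hex_axial_of(x - ox, y - oy, side)
  key <- paste(layer$centers$q, layer$centers$r)
  idx <- match(paste(ax$q, ax$r), key)
  out <- layer$centers$cell_id[idx]
  # boundary ties: compare against the six neighbours of the rounded cell
  tol <- 1e-9 * max(side, 1)
  for (i in seq_along(x)) {
    cand_q <- c(ax$q[i], ax$q[i] + HEX_NEIGHBOR_OFFSETS[, "q"])
    cand_r <- c(ax$r[i], ax$r[i] + HEX_NEIGHBOR_OFFSETS[, "r"])
    j <- match(paste(cand_q, cand_r), key)
    ok <- !is.na(j)
    if (!any(ok)) { out[i] <- NA_integer_; next }
    cx <- layer$centers$x[j[ok]]; cy <- layer$centers$y[j[ok]]
    d2 <- (cx - x[i])^2 + (cy - y[i])^2
    near <- which(d2 <= min(d2) + tol^2)
    if (length(near) > 1L)      # exact boundary: lexicographic (x, then y)
      near <- near[order(cx[near], cy[near])][1L]
    out[i] <- layer$centers$cell_id[j[ok][near]]
  }
  out
}

#' Aggregate point observations into hexagon cells
#'
#' Computes one summary value per non-empty cell; cells with fewer than
#' `min_count` points carry `NA` and are excluded from the downstream
#' spatial-weights graph, matching an analysis that computes autocorrelation
#' only over aggregated areal units.
#'
#' @param data a planar-km [point_data()].
#' @param layer a `hex_layer` from [make_hex_grid()].
#' @param statistic `"mean"`, `"median"` or `"max"`.
#' @param min_count minimum number of points for a cell to carry a value.
#' @return The layer with `cell_values` and `cell_counts` filled in.
#' @examples
#' pd <- point_data(c(1, 2, 3), c(1, 1, 2), c(10, 20, 30), crs = "planar-km")
#' layer <- make_hex_grid(c(0, 0, 10, 10), side = 20)
#' hex_aggregate(pd, layer)$cell_values
#' @export
hex_aggregate <- function(data, layer, statistic = c("mean", "median", "max"),
                          min_count = 1L) {
  stopifnot(inherits(data, "point_data"), inherits(layer, "hex_layer"))
  if (data$crs != "planar-km")
    stop("aggregation expects planar-km coordinates; see project_to_planar()",
         call. = FALSE)
  statistic <- match.arg(statistic)
  fun <- switch(statistic, mean = mean, median = stats::median, max = max)
  cid <- hex_assign(layer, data$x, data$y)
  inside <- !is.na(cid)
  n_cells <- nrow(layer$centers)
  counts <- integer(n_cells)
  tab <- table(factor(cid[inside], levels = layer$centers$cell_id))
  counts <- as.integer(tab)
  vals <- rep(NA_real_, n_cells)
  if (any(inside)) {
    agg <- tapply(data$values[inside], cid[inside], fun)
    vals[match(as.integer(names(agg)), layer$centers$cell_id)] <- as.numeric(agg)
  }
  vals[counts < min_count] <- NA_real_
  if (all(is.na(vals)))
    stop("empty layer: no cell reaches min_count points", call. = FALSE)
  layer$cell_values <- vals
  layer$cell_counts <- counts
  layer$statistic <- statistic
  layer$min_count <- as.integer(min_count)
  layer
}

#' Non-empty cells of an aggregated layer
#'
#' @param layer an aggregated `hex_layer`.
#' @return Data frame `cell_id, q, r, x, y, value, count` restricted to
#'   cells that carry a value.
#' @export
hex_cells <- function(layer) {
  if (is.null(layer$cell_values))
    stop("layer has not been aggregated; see hex_aggregate()", call. = FALSE)
  keep <- !is.na(layer$cell_values)
  data.frame(layer$centers[keep, , drop = FALSE],
             value = layer$cell_values[keep],
             count = layer$cell_counts[keep],
             row.names = NULL)
}

#' @export
as.data.frame.hex_layer <- function(x, ...) {
  df <- x$centers
  if (!is.null(x$cell_values)) {
    df$value <- x$cell_values
    df$count <- x$cell_counts
  }
  df
}

#' Write an aggregated layer to CSV or GeoJSON
#'
#' CSV columns are `cell_id, center_x, center_y, value, count`; GeoJSON
#' output is a FeatureCollection of hexagon polygons with `value` and
#' `count` properties (in lon/lat if a projection descriptor is given).
#'
#' @param layer an aggregated `hex_layer`.
#' @param path output file; format chosen by extension (`.csv`/`.geojson`/`.json`).
#' @param proj optional projection descriptor ([project_to_planar()]) used to
#'   write GeoJSON coordinates in lon/lat.
#' @return `path`, invisibly.
#' @export
write_hex_layer <- function(layer, path, proj = NULL) {
  cells <- hex_cells(layer)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(
      data.frame(cell_id = cells$cell_id, center_x = cells$x,
                 center_y = cells$y, value = cells$value, count = cells$count),
      path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(cells)), function(i) {
      v <- hex_vertices(layer, cells$cell_id[i])
      v <- rbind(v, v[1, ])
      if (!is.null(proj)) {
        ll <- planar_to_lonlat(v[, 1], v[, 2], proj)
        v <- cbind(ll$lon, ll$lat)
      }
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(v)),
                                                     function(k) c(v[k, 1], v[k, 2])))),
           properties = list(cell_id = cells$cell_id[i],
                             value = cells$value[i], count = cells$count[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
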