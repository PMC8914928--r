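#' Ordinary Kriging of a point dataset
#'
#' Predicts the field at target locations as the weighted sum
#' \eqn{\hat Z(s_0) = \sum_i \lambda_i Z(s_i)} with weights solving the
#' ordinary-Kriging system: the pairwise semivariance matrix augmented with
#' the unbiasedness constraint \eqn{\sum_i \lambda_i = 1} via a Lagrange
#' multiplier. The mean is unknown but constant. With zero nugget the
#' predictor interpolates the data exactly. Kriging variance is reported on
#' the working (possibly transformed) scale.
#'
#' @param data a planar-km [point_data()] (duplicate locations are an
#'   error: deduplicate or jitter first).
#' @param vg a fitted [fit_variogram()] model.
#' @param targets data frame or matrix with columns/x-y pairs of target
#'   locations; defaults to a regular grid over the data bounding box.
#' @param grid_n grid resolution per axis when `targets` is `NULL`.
#' @param neighbors optional integer: use only the `k` nearest data points
#'   per target (local-neighbourhood mode); `NULL` uses all points.
#' @return Object of class `kriging_prediction`: data frame `x, y,
#'   estimate, variance` with attribute `weight_sums` (the per-target
#'   \eqn{\sum\lambda}, each 1 up to solver precision).
#' @examples
#' pd <- simulate_field(field_spec(n_points = 60, nugget = 0, seed = 5))
#' vg <- fit_variogram(empirical_variogram(pd))
#' pr <- ordinary_kriging(pd, vg, targets = cbind(pd$x[1:3], pd$y[1:3]))
#' pr$estimate - pd$values[1:3]  # ~0: exact interpolation
#' @export
ordinary_kriging <- function(data, vg, targets = NULL, grid_n = 25,
                             neighbors = NULL) {
  stopifnot(inherits(data, "point_data"), inherits(vg, "variogram_model"))
  n <- length(data$x)
  if (n < 2) stop("need at least 2 data points", call. = FALSE)
  xy <- cbind(data$x, data$y)
  dd <- as.matrix(stats::dist(xy))
  if (any(dd[upper.tri(dd)] < 1e-9))
    stop(paste("duplicate point locations make the kriging system singular;",
               "deduplicate (e.g. average repeated sites) or jitter them"),
         call. = FALSE)
  if (is.null(targets)) {
    b <- bbox_of(data)
    targets <- as.matrix(expand.grid(
      x = seq(b["xmin"], b["xmax"], length.out = grid_n),
      y = seq(b["ymin"], b["ymax"], length.out = grid_n)))
  }
  targets <- as.matrix(targets)
  if (ncol(targets) != 2) stop("targets must have two columns", call. = FALSE)
  G <- variogram_gamma(dd, vg$model, vg$nugget, vg$psill, vg$range)
  z <- data$values
  est <- var_ <- wsum <- numeric(nrow(targets))
  use_local <- !is.null(neighbors) && neighbors < n
  if (!use_local) {
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    Ainv <- solve(A)
  }
  for (t in seq_len(nrow(targets))) {
    dx <- xy[, 1] - targets[t, 1]
    dy <- xy[, 2] - targets[t, 2]
    d0 <- sqrt(dx * dx + dy * dy)
    if (use_local) {
      sel <- order(d0)[seq_len(neighbors)]
      g0 <- variogram_gamma(d0[sel], vg$model, vg$nugget, vg$psill, vg$range)
      A <- rbind(cbind(G[sel, sel, drop = FALSE], 1),
                 c(rep(1, length(sel)), 0))
      sol <- solve(A, c(g0, 1))
      lam <- sol[seq_along(sel)]
      est[t] <- sum(lam * z[sel])
      var_[t] <- max(sum(lam * g0) + sol[length(sol)], 0)
      wsum[t] <- sum(lam)
    } else {
      g0 <- variogram_gamma(d0, vg$model, vg$nugget, vg$psill, vg$range)
      sol <- Ainv %*% c(g0, 1)
      lam <- sol[seq_len(n)]
      est[t] <- sum(lam * z)
      var_[t] <- max(sum(lam * g0) + sol[n + 1], 0)
      wsum[t] <- sum(lam)
    }
  }
  out <- data.frame(x = targets[, 1], y = targets[, 2],
                    estimate = est, variance = var_)
  structure(out, class = c("kriging_prediction", "data.frame"),
            weight_sums = wsum, variogram = vg)
}

#' @export
print.kriging_prediction <- function(x, ...) {
  cat(sprintf("<kriging_prediction> %d targets; estimate range [%.4g, %.4g]\n",
              nrow(x), min(x$estimate), max(x$estimate)))
  invisible(x)
}

#' Indicator Kriging: exceedance-probability surface
#'
#' Transforms observations to threshold indicators `1{z > threshold}`, fits
#' an indicator variogram, kriges the indicators by [ordinary_kriging()]
#' and clips the estimates into `[0, 1]`. The result estimates, per target,
#' the probability that the field exceeds the threshold — e.g. the
#' probability that a pollutant's AQI passes the Good/Moderate boundary
#' of 50.
#'
#' @param data a planar-km [point_data()].
#' @param threshold exceedance threshold on the value scale.
#' @param targets,grid_n,neighbors as in [ordinary_kriging()].
#' @param model theoretical variogram family for the indicators.
#' @return Object of class `kriging_prediction` with `estimate` a
#'   probability in `[0, 1]` (attribute `threshold` records the cut).
#'   When every indicator is identical the surface is constant 0 or 1 with
#'   a warning.
#' @export
indicator_kriging <- function(data, threshold, targets = NULL, grid_n = 25,
                              neighbors = NULL, model = "exponential") {
  stopifnot(inherits(data, "point_data"))
  ind <- as.numeric(data$values > threshold)
  n_above <- sum(ind); n_below <- sum(1 - ind)
  if (n_above == 0 || n_below == 0) {
    warning(sprintf("all observations on one side of threshold %g; constant probability surface",
                    threshold))
    if (is.null(targets)) {
      b <- bbox_of(data)
      targets <- as.matrix(expand.grid(
        x = seq(b["xmin"], b["xmax"], length.out = grid_n),
        y = seq(b["ymin"], b["ymax"], length.out = grid_n)))
    }
    targets <- as.matrix(targets)
    out <- data.frame(x = targets[, 1], y = targets[, 2],
                      estimate = as.numeric(n_above > 0), variance = 0)
    return(structure(out, class = c("kriging_prediction", "data.frame"),
                     weight_sums = rep(1, nrow(out)), threshold = threshold))
  }
  if (n_above < 2 || n_below < 2)
    warning("fewer than 2 observations on one side of the threshold; indicator variogram poorly informed")
  idata <- point_data(data$x, data$y, ind, crs = "planar-km")
  vg <- fit_variogram(empirical_variogram(idata), model = model)
  pr <- ordinary_kriging(idata, vg, targets = targets, grid_n = grid_n,
                         neighbors = neighbors)
  pr$estimate <- pmin(pmax(pr$estimate, 0), 1)
  attr(pr, "threshold") <- threshold
  attr(pr, "variogram") <- vg
  pr
}

#' Write a prediction surface as CSV or GeoJSON points
#'
#' @param pred a `kriging_prediction`.
#' @param path output path (`.csv` or `.geojson`/`.json`).
#' @param proj optional projection descriptor for lon/lat GeoJSON output.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path, proj = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(pred), path, row.names = FALSE)
  } else {
    coords <- cbind(pred$x, pred$y)
    if (!is.null(proj)) {
      ll <- planar_to_lonlat(pred$x, pred$y, proj)
      coords <- cbind(ll$lon, ll$lat)
    }
    feats <- lapply(seq_len(nrow(pred)), function(i)
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(coords[i, 1], coords[i, 2])),
           properties = list(estimate = pred$estimate[i],
                             variance = pred$variance[i])))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
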