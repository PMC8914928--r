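#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation distance and computes per bin
#' \deqn{\hat\gamma(h) = \frac{1}{2|N(h)|}\sum_{(i,j)\in N(h)} (z_i-z_j)^2}
#' The default uses 15 lags to half the maximum pairwise distance. Bins
#' with no pairs are dropped with a warning; bins with fewer than
#' `min_pairs` are kept but flagged.
#'
#' @param data a planar-km [point_data()].
#' @param n_lags number of distance bins.
#' @param max_dist largest separation considered (km); default half the
#'   maximum pairwise distance.
#' @param min_pairs flag threshold for thin bins.
#' @return Object of class `empirical_variogram`: data frame `lag, gamma,
#'   n_pairs, flagged` (lag = bin centre).
#' @export
empirical_variogram <- function(data, n_lags = 15, max_dist = NULL,
                                min_pairs = 5L) {
  stopifnot(inherits(data, "point_data"))
  n <- length(data$x)
  if (n < 10) stop("need at least 10 points for a variogram", call. = FALSE)
  d <- stats::dist(cbind(data$x, data$y))
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop("max_dist must be positive", call. = FALSE)
  dv <- as.numeric(d)
  gv <- as.numeric(stats::dist(data$values))^2  # (z_i - z_j)^2
  keep <- dv <= max_dist & dv > 0
  dv <- dv[keep]; gv <- gv[keep]
  if (!length(dv)) stop("no point pairs within max_dist", call. = FALSE)
  breaks <- seq(0, max_dist, length.out = n_lags + 1)
  bin <- cut(dv, breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(gv, bin, function(v) sum(v) / (2 * length(v)))
  npairs <- tapply(gv, bin, length)
  lag <- (breaks[-1] + breaks[-length(breaks)]) / 2
  present <- sort(unique(bin))
  if (length(present) < n_lags)
    warning(sprintf("%d empty lag bin(s) dropped", n_lags - length(present)))
  out <- data.frame(lag = lag[present], gamma = as.numeric(gamma),
                    n_pairs = as.integer(npairs),
                    flagged = as.integer(npairs) < min_pairs)
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_dist = max_dist)
}

# theoretical semivariance gamma(h); gamma(0) = 0 by convention
variogram_gamma <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    exponential = nugget + psill * (1 - exp(-h / range)),
    spherical   = ifelse(h >= range, nugget + psill,
                         nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    gaussian    = nugget + psill * (1 - exp(-(h / range)^2)),
    stop("unknown variogram model"))
  g[h == 0] <- 0
  g
}

#' Fit a theoretical variogram model by weighted least squares
#'
#' Fits nugget `c0`, partial sill `c` and range `a` of an exponential
#' (`gamma(h) = c0 + c (1 - exp(-h/a))`), spherical or Gaussian model to an
#' empirical variogram, minimising the pair-count-weighted squared error
#' with box constraints `c0, c >= 0`, `a > 0`. A flat (pure-nugget)
#' empirical variogram yields `c ~ 0` with a warning: the range is then
#' unidentifiable.
#'
#' @param emp an [empirical_variogram()].
#' @param model `"exponential"` (default), `"spherical"` or `"gaussian"`.
#' @param init optional named start values `c(nugget, psill, range)`.
#' @return Object of class `variogram_model`: list with `model`, `nugget`,
#'   `psill`, `range`, `sse`, `converged`, `emp`.
#' @examples
#' pd <- simulate_field(field_spec(n_points = 150, range_km = 100, seed = 3))
#' vg <- fit_variogram(empirical_variogram(pd))
#' vg
#' @export
fit_variogram <- function(emp, model = c("exponential", "spherical",
                                         "gaussian"), init = NULL) {
  stopifnot(inherits(emp, "empirical_variogram"))
  model <- match.arg(model)
  usable <- emp[is.finite(emp$gamma), , drop = FALSE]
  if (nrow(usable) < 3)
    stop("need at least 3 usable variogram bins", call. = FALSE)
  h <- usable$lag; g <- usable$gamma; wt <- usable$n_pairs
  obj <- function(p)
    sum(wt * (g - variogram_gamma(h, model, p[1], p[2], p[3]))^2)
  # the range is not identifiable beyond the sampled lags; bound it there
  lower <- c(0, 1e-10, 1e-6)
  upper <- c(Inf, Inf, 3 * max(h))
  starts <- if (!is.null(init)) list(init) else {
    span <- max(max(g) - min(g), 1e-8)
    lapply(c(1 / 6, 1 / 3, 2 / 3), function(f)
      c(nugget = max(min(g), 1e-8), psill = span, range = f * max(h)))
  }
  best <- NULL
  for (st in starts) {
    f1 <- tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                                lower = lower, upper = upper),
                   error = function(e) NULL)
    # polish (or rescue) with a bounded Nelder-Mead on clamped parameters
    st2 <- if (!is.null(f1)) f1$par else st
    f2 <- tryCatch(stats::optim(st2, function(p)
      obj(pmin(pmax(p, lower), upper)), method = "Nelder-Mead",
      control = list(maxit = 2000)), error = function(e) NULL)
    if (!is.null(f2)) f2$par <- pmin(pmax(f2$par, lower), upper)
    for (f in list(f1, f2))
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    stop("variogram fit did not converge from any starting value",
         call. = FALSE)
  fit <- best
  p <- fit$par
  sill_span <- max(g) - min(g)
  if (p[2] < 1e-6 * max(max(g), 1) || sill_span < 1e-3 * max(g))
    warning("empirical variogram is flat: partial sill ~ 0, range unidentifiable")
  structure(list(model = model, nugget = unname(p[1]), psill = unname(p[2]),
                 range = unname(p[3]), sse = fit$value, converged = TRUE,
                 emp = emp),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget = %.4g, partial sill = %.4g, range = %.4g km\n",
              x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Semivariance of a fitted variogram at given distances
#'
#' @param object a `variogram_model`.
#' @param h distances (km).
#' @param ... unused.
#' @return Semivariance values; `gamma(0) = 0`.
#' @export
predict.variogram_model <- function(object, h, ...) {
  variogram_gamma(h, object$model, object$nugget, object$psill, object$range)
}

#' @export
plot.variogram_model <- function(x, ...) {
  emp <- x$emp
  graphics::plot(emp$lag, emp$gamma, pch = 19,
                 xlab = "distance (km)", ylab = "semivariance", ...)
  hh <- seq(0, max(emp$lag), length.out = 200)
  graphics::lines(hh, predict(x, hh), col = "red")
  invisible(x)
}

#' Write a variogram report as JSON
#'
#' @param vg a `variogram_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variogram <- function(vg, path) {
  jsonlite::write_json(list(model = vg$model, nugget = vg$nugget,
                            psill = vg$psill, range = vg$range,
                            sse = vg$sse,
                            empirical = vg$emp[, c("lag", "gamma", "n_pairs")]),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
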