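# Candidate normalising transforms, each with an exact inverse on the
# observed range. Selection maximises the Shapiro-Wilk W statistic of the
# transformed sample.

tf_apply <- function(tf, x) {
  switch(tf$type,
    identity = x,
    log      = log(x + tf$shift),
    sqrt     = sqrt(x + tf$shift),
    boxcox   = bc_fwd(x + tf$shift, tf$lambda),
    yeojohnson = yj_fwd(x, tf$lambda),
    orderquant = stats::approx(tf$x_knots, tf$z_knots, xout = x,
                               rule = 2)$y,
    stop("unknown transform type"))
}

tf_invert <- function(tf, z) {
  switch(tf$type,
    identity = z,
    log      = exp(z) - tf$shift,
    sqrt     = z^2 - tf$shift,
    boxcox   = bc_inv(z, tf$lambda) - tf$shift,
    yeojohnson = yj_inv(z, tf$lambda),
    orderquant = stats::approx(tf$z_knots, tf$x_knots, xout = z,
                               rule = 2)$y,
    stop("unknown transform type"))
}

bc_fwd <- function(x, lambda)
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
bc_inv <- function(z, lambda)
  if (abs(lambda) < 1e-8) exp(z) else (lambda * z + 1)^(1 / lambda)

yj_fwd <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- if (abs(lambda) < 1e-8) log(x[pos] + 1)
              else ((x[pos] + 1)^lambda - 1) / lambda
  out[!pos] <- if (abs(lambda - 2) < 1e-8) -log(1 - x[!pos])
               else -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  out
}
yj_inv <- function(z, lambda) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- if (abs(lambda) < 1e-8) exp(z[pos]) - 1
              else (lambda * z[pos] + 1)^(1 / lambda) - 1
  out[!pos] <- if (abs(lambda - 2) < 1e-8) 1 - exp(-z[!pos])
               else 1 - (1 - (2 - lambda) * z[!pos])^(1 / (2 - lambda))
  out
}

bc_lambda <- function(x) {
  ll <- function(l) {
    z <- bc_fwd(x, l)
    -length(x) / 2 * log(stats::var(z) * (length(x) - 1) / length(x)) +
      (l - 1) * sum(log(x))
  }
  stats::optimize(ll, c(-2, 2), maximum = TRUE)$maximum
}

yj_lambda <- function(x) {
  ll <- function(l) {
    z <- yj_fwd(x, l)
    -length(x) / 2 * log(stats::var(z) * (length(x) - 1) / length(x)) +
      (l - 1) * sum(sign(x) * log(abs(x) + 1))
  }
  stats::optimize(ll, c(-2, 3), maximum = TRUE)$maximum
}

shapiro_w <- function(z) {
  if (length(unique(z)) < 3) return(-Inf)
  if (length(z) > 4500) {
    z <- sort(z)[round(seq(1, length(z), length.out = 4500))]
  }
  tryCatch(stats::shapiro.test(z)$statistic, error = function(e) -Inf)
}

#' Select and apply a normalising transform
#'
#' The first step of the interpolation workflow: pick, among identity,
#' shifted log, shifted square root, Box-Cox, Yeo-Johnson and a rank-based
#' ordered-quantile map, the transform whose output is closest to Gaussian
#' as measured by the Shapiro-Wilk W statistic, and return the transformed
#' values with an invertible descriptor. Kriging then operates on the
#' transformed scale and point predictions are back-transformed for maps.
#'
#' @param values numeric vector (>= 10 finite values for selection; fewer
#'   fall back to identity with a warning, as does constant input).
#' @param candidates subset of
#'   `c("identity", "log", "sqrt", "boxcox", "yeojohnson", "orderquant")`.
#' @return Object of class `normalizer`: list with `values` (transformed),
#'   `transform` (descriptor with `type` and parameters) and `w`
#'   (the selection statistic per candidate).
#' @examples
#' nz <- normalize_values(exp(rnorm(50)))
#' nz$transform$type
#' max(abs(inverse_normalize(nz$values, nz$transform) - exp(rnorm(0))))
#' @export
normalize_values <- function(values,
                             candidates = c("identity", "log", "sqrt",
                                            "boxcox", "yeojohnson",
                                            "orderquant")) {
  x <- as.numeric(values)
  if (any(!is.finite(x)))
    stop("invalid value: non-finite entries", call. = FALSE)
  fallback <- function(msg) {
    warning(msg)
    structure(list(values = x, transform = list(type = "identity"),
                   w = c(identity = NA_real_)), class = "normalizer")
  }
  if (length(x) < 10)
    return(fallback("fewer than 10 values; using identity transform"))
  if (stats::var(x) == 0)
    return(fallback("constant input; using identity transform"))
  shift_for <- function(need_pos) {
    lo <- min(x)
    if (need_pos && lo <= 0) 1e-6 - lo else if (!need_pos && lo < 0) -lo else 0
  }
  tfs <- list()
  for (cand in candidates) {
    tf <- switch(cand,
      identity = list(type = "identity"),
      log  = list(type = "log",  shift = shift_for(TRUE)),
      sqrt = list(type = "sqrt", shift = shift_for(FALSE)),
      boxcox = {
        s <- shift_for(TRUE)
        list(type = "boxcox", shift = s, lambda = bc_lambda(x + s))
      },
      yeojohnson = list(type = "yeojohnson", lambda = yj_lambda(x)),
      orderquant = {
        ux <- sort(unique(x))
        zz <- stats::qnorm((rank(x, ties.method = "average") - 0.5) /
                             length(x))
        # one knot per distinct value (mean normal score across ties)
        zk <- tapply(zz, match(x, ux), mean)
        list(type = "orderquant", x_knots = ux, z_knots = as.numeric(zk))
      })
    tfs[[cand]] <- tf
  }
  w <- vapply(tfs, function(tf) shapiro_w(tf_apply(tf, x)), numeric(1))
  best <- names(which.max(w))
  structure(list(values = tf_apply(tfs[[best]], x), transform = tfs[[best]],
                 w = w), class = "normalizer")
}

#' @export
print.normalizer <- function(x, ...) {
  cat(sprintf("<normalizer> transform = %s\n", x$transform$type))
  if (!all(is.na(x$w))) {
    cat("  Shapiro-Wilk W by candidate:\n")
    print(round(x$w, 4))
  }
  invisible(x)
}

#' Invert a normalising transform
#'
#' Exact inverse of the descriptor returned by [normalize_values()]
#' (interpolation-based for the ordered-quantile map, exact at observed
#' values).
#'
#' @param z transformed values.
#' @param transform descriptor (`$transform` of a `normalizer`).
#' @return Values on the original scale.
#' @export
inverse_normalize <- function(z, transform) {
  tf_invert(transform, as.numeric(z))
}
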