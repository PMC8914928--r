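#' Global Moran's I with permutation pseudo-significance
#'
#' Computes the global spatial-autocorrelation index
#' \deqn{I = \frac{n}{\sum_i\sum_j w_{ij}}\;
#'       \frac{\sum_i\sum_j w_{ij}(y_i-\bar y)(y_j-\bar y)}
#'            {\sum_i (y_i-\bar y)^2}}
#' over the areal units of a spatial weights graph. With row-standardised
#' weights the index lies in approximately \eqn{[-1, 1]}: positive for
#' clustered (similar neighbours), negative for alternating values, near 0
#' under spatial independence. Significance is assessed by a permutation
#' (pseudo-significance) test: the values are randomly reassigned to units
#' and the two-sided Monte-Carlo p-value is
#' `(1 + #{|I_perm| >= |I_obs|}) / (1 + permutations)`.
#'
#' @param y numeric values per areal unit (no missing values).
#' @param w a [contiguity_weights()] object with `w$n == length(y)`.
#' @param permutations number of random permutations (0 skips the test).
#' @param seed integer seed for the permutation RNG.
#' @return An object of class `moran_test`: list with `I`, `n`, `expected`
#'   (\eqn{-1/(n-1)}), `p_pseudo`, `permutations`, `seed`.
#' @examples
#' pd <- simulate_field(field_spec(n_points = 120, range_km = 150, seed = 2))
#' layer <- hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = 60))
#' global_moran(hex_cells(layer)$value, contiguity_weights(layer), seed = 1)
#' @export
global_moran <- function(y, w, permutations = 999, seed = 1L) {
  stopifnot(inherits(w, "spatial_weights"))
  y <- as.numeric(y)
  n <- length(y)
  if (n != w$n) stop("length(y) must equal the number of weighted cells",
                     call. = FALSE)
  if (n < 3) stop("need at least 3 areal units", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate input: constant values have zero spatial variance",
         call. = FALSE)
  I_obs <- moran_stat(y, w)
  p <- NA_real_
  if (permutations > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    I_perm <- vapply(seq_len(permutations),
                     function(k) moran_stat(sample(y), w), numeric(1))
    p <- (1 + sum(abs(I_perm) >= abs(I_obs))) / (1 + permutations)
  }
  structure(list(I = I_obs, n = n, expected = -1 / (n - 1), p_pseudo = p,
                 permutations = permutations, seed = seed),
            class = "moran_test")
}

# Moran's I statistic for a value vector over a weights graph
moran_stat <- function(y, w) {
  z <- y - mean(y)
  num <- sum(z * spatial_lag(w, z))
  (length(y) / weights_s0(w)) * num / sum(z^2)
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (n = %d, E[I] = %.4f)\n",
              x$I, x$n, x$expected))
  if (!is.na(x$p_pseudo))
    cat(sprintf("  pseudo p-value = %.4g (%d permutations, two-sided)\n",
                x$p_pseudo, x$permutations))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Computes, for each areal unit,
#' \deqn{I_i = \frac{(y_i-\bar y)\sum_j w_{ij}(y_j-\bar y)}
#'                  {\sum_i (y_i-\bar y)^2 / n}}
#' the per-unit decomposition of the global index: under row-standardised
#' weights `mean(Ii)` equals the global Moran's I. Positive \eqn{I_i} marks a
#' unit similar to its neighbours (cluster core), negative a local outlier.
#' Pseudo-significance is conditional: each unit's value is held fixed while
#' the remaining values are permuted among the other units. Units are
#' labelled by Moran-scatter quadrant (`HH`, `LL`, `HL`, `LH`) when their
#' pseudo p-value passes `alpha`, else `not-significant`.
#'
#' @inheritParams global_moran
#' @param alpha significance level for quadrant labelling (default 0.05).
#' @return Object of class `lisa`: data frame `cell_index, Ii, p_pseudo,
#'   quadrant` plus attributes `global_I` and `n`.
#' @export
local_moran <- function(y, w, permutations = 999, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(w, "spatial_weights"))
  y <- as.numeric(y)
  n <- length(y)
  if (n != w$n) stop("length(y) must equal the number of weighted cells",
                     call. = FALSE)
  if (n < 3) stop("need at least 3 areal units", call. = FALSE)
  if (stats::var(y) == 0)
    stop("degenerate input: constant values have zero spatial variance",
         call. = FALSE)
  z <- y - mean(y)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(w, z)
  Ii <- z * lag / m2
  p <- rep(NA_real_, n)
  if (permutations > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (i in seq_len(n)) {
      nbi <- w$neighbors[[i]]
      if (!length(nbi)) { p[i] <- 1; next }
      wi <- w$weights[[i]]
      zi <- z[-i]
      k <- length(nbi)
      # draw k neighbour values without replacement, permutations times
      perm_lag <- vapply(seq_len(permutations), function(b)
        sum(wi * zi[sample.int(n - 1L, k)]), numeric(1))
      Ii_perm <- z[i] * perm_lag / m2
      p[i] <- (1 + sum(abs(Ii_perm) >= abs(Ii[i]))) / (1 + permutations)
    }
  }
  quad <- rep("not-significant", n)
  sig <- !is.na(p) & p <= alpha
  quad[sig & z > 0 & lag > 0] <- "HH"
  quad[sig & z < 0 & lag < 0] <- "LL"
  quad[sig & z > 0 & lag < 0] <- "HL"
  quad[sig & z < 0 & lag > 0] <- "LH"
  out <- data.frame(cell_index = seq_len(n), Ii = Ii, p_pseudo = p,
                    quadrant = quad)
  structure(out, class = c("lisa", "data.frame"),
            global_I = moran_stat(y, w), n = n,
            permutations = permutations, seed = seed)
}

#' @export
print.lisa <- function(x, ...) {
  cat(sprintf("Local Moran's I over %d units; mean(Ii) = %.4f, global I = %.4f\n",
              attr(x, "n"), mean(x$Ii), attr(x, "global_I")))
  print(table(x$quadrant))
  invisible(x)
}

#' Coefficient of variation of the local Moran values
#'
#' The instability measure used as the second granularity criterion:
#' sample standard deviation of the \eqn{I_i} divided by the absolute value
#' of their mean. Large values flag scales at which the local structure is
#' heterogeneous or unstable; the granularity search minimises it.
#'
#' @param lisa a [local_moran()] result (or a bare numeric vector of Ii).
#' @return Non-negative scalar; `+Inf` with a warning when `mean(Ii)` is 0.
#' @export
cv_local <- function(lisa) {
  Ii <- if (inherits(lisa, "lisa")) lisa$Ii else as.numeric(lisa)
  if (length(Ii) < 3) stop("need at least 3 local values", call. = FALSE)
  m <- mean(Ii)
  if (m == 0) {
    warning("mean of local Moran values is zero; CV is infinite")
    return(Inf)
  }
  stats::sd(Ii) / abs(m)
}

#' Write LISA results to CSV
#'
#' @param lisa a [local_moran()] result.
#' @param layer the aggregated `hex_layer` the values came from.
#' @param path output CSV path.
#' @return `path`, invisibly. Columns: `cell_id, Ii, p, quadrant`.
#' @export
write_lisa <- function(lisa, layer, path) {
  cells <- hex_cells(layer)
  utils::write.csv(data.frame(cell_id = cells$cell_id, Ii = lisa$Ii,
                              p = lisa$p_pseudo, quadrant = lisa$quadrant),
                   path, row.names = FALSE)
  invisible(path)
}

# Seed handling: set a local RNG state and restore the caller's afterwards,
# so seeded routines do not disturb the session RNG.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
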