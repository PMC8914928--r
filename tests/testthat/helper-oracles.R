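# Independent oracles used across the suite. Each reimplements the quantity
# from first principles by a different route than the package (dense
# matrices, brute force, covariance-form systems) so agreement is a real
# cross-check, not a tautology.

# Dense-matrix global Moran's I directly from the defining formula.
oracle_global_moran <- function(y, W) {
  n <- length(y)
  z <- y - mean(y)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

# Dense-matrix local Moran's I: Ii = zi * (W z)_i / (sum z^2 / n).
oracle_local_moran <- function(y, W) {
  n <- length(y)
  z <- y - mean(y)
  as.numeric(z * (W %*% z)) / (sum(z^2) / n)
}

# Brute-force non-dominated sorting by exhaustive all-pairs dominance.
oracle_pareto_rank <- function(m, senses = c("max", "min")) {
  s <- ifelse(senses == "max", 1, -1)
  mm <- sweep(m, 2, s, `*`)
  dom <- function(i, j) all(mm[i, ] >= mm[j, ]) && any(mm[i, ] > mm[j, ])
  n <- nrow(m)
  rank <- rep(NA_integer_, n)
  left <- seq_len(n)
  r <- 0L
  while (length(left)) {
    r <- r + 1L
    nd <- vapply(left, function(i)
      !any(vapply(left, function(j) j != i && dom(j, i), logical(1))),
      logical(1))
    rank[left[nd]] <- r
    left <- left[!nd]
  }
  rank
}

# Covariance-form ordinary kriging: an independent route to the same
# predictor (the package solves the semivariance-form system).
oracle_kriging <- function(x, y, z, sill, range_km, nugget, tx, ty) {
  n <- length(x)
  h <- as.matrix(stats::dist(cbind(x, y)))
  C <- sill * exp(-h / range_km)
  diag(C) <- sill + nugget
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  est <- numeric(length(tx))
  for (t in seq_along(tx)) {
    d0 <- sqrt((x - tx[t])^2 + (y - ty[t])^2)
    c0 <- sill * exp(-d0 / range_km)
    c0[d0 == 0] <- sill + nugget
    sol <- solve(A, c(c0, 1))
    est[t] <- sum(sol[seq_len(n)] * z)
  }
  est
}

# Point-in-convex-polygon by the half-plane test (boundary counts as in).
oracle_point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  cross <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
  }, numeric(1))
  all(cross >= -1e-9) || all(cross <= 1e-9)
}

# Moment skewness g1 = m3 / m2^(3/2).
oracle_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

# Small hand-built weights graphs.
path_weights <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L, if (i < n) i + 1L)))
  structure(list(n = n, ids = seq_len(n), neighbors = nb,
                 weights = lapply(nb, function(j) rep(1, length(j))),
                 style = "binary", isolated = rep(FALSE, n)),
            class = "spatial_weights")
}

cycle_weights <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L else n, if (i < n) i + 1L else 1L)))
  structure(list(n = n, ids = seq_len(n), neighbors = nb,
                 weights = lapply(nb, function(j) rep(1, length(j))),
                 style = "binary", isolated = rep(FALSE, n)),
            class = "spatial_weights")
}

# Random small aggregated layer + weights for property suites. Isolated
# cells are pruned (their row of a row-standardised matrix sums to 0, so
# the exact decomposition identity is stated over connected cells).
random_layer_case <- function(seed, n_points = 80, side = 70) {
  pd <- simulate_field(field_spec(n_points = n_points, range_km = 120,
                                  nugget = 0.2, seed = seed))
  layer <- hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = side))
  repeat {
    w <- suppressWarnings(contiguity_weights(layer, style = "row"))
    if (!any(w$isolated)) break
    drop_ids <- hex_cells(layer)$cell_id[w$isolated]
    layer$cell_values[match(drop_ids, layer$centers$cell_id)] <- NA_real_
  }
  list(y = hex_cells(layer)$value, w = w, layer = layer)
}
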