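test_that("hexagon contiguity matches the O(n^2) geometric oracle", {
  case <- random_layer_case(seed = 21)
  cells <- hex_cells(case$layer)
  side <- case$layer$side
  # neighbours iff centres sit at distance sqrt(3) * side
  d <- as.matrix(dist(cbind(cells$x, cells$y)))
  for (i in seq_len(nrow(cells))) {
    geo <- which(abs(d[i, ] - sqrt(3) * side) < 1e-6 * side)
    expect_identical(case$w$neighbors[[i]], sort(as.integer(geo)))
  }
})

test_that("interior cells of a dense grid have six neighbours of weight 1/6", {
  set.seed(31)
  pd <- point_data(runif(4000, 0, 200), runif(4000, 0, 200),
                   rnorm(4000), crs = "planar-km")
  layer <- hex_aggregate(pd, make_hex_grid(c(0, 0, 200, 200), side = 15))
  w <- contiguity_weights(layer, style = "row")
  deg <- lengths(w$neighbors)
  expect_true(any(deg == 6))
  i <- which(deg == 6)[1]
  expect_equal(w$weights[[i]], rep(1 / 6, 6))
  expect_equal(vapply(w$weights, sum, numeric(1)),
               rep(1, w$n), tolerance = 1e-12)
})

test_that("all-isolated layers raise a no-neighbors error", {
  pd <- point_data(c(0, 500, 1000), c(0, 500, 0), c(1, 2, 3),
                   crs = "planar-km")
  layer <- hex_aggregate(pd, make_hex_grid(c(0, 0, 1000, 500), side = 30))
  expect_error(contiguity_weights(layer), "no neighbors")
})

test_that("global Moran's I reproduces hand-evaluated graph cases", {
  # 4-cycle with alternating +-1: cross-product sum -8, S0 = 8, ss = 4
  expect_equal(global_moran(c(1, -1, 1, -1), cycle_weights(4),
                            permutations = 0)$I, -1)
  # 4-node path with (1, 1, -1, -1)
  expect_equal(global_moran(c(1, 1, -1, -1), path_weights(4),
                            permutations = 0)$I, 1 / 3)
  expect_error(global_moran(c(2, 2, 2, 2), cycle_weights(4)), "degenerate")
})

test_that("global and local Moran agree with dense-matrix oracles", {
  for (seed in 1:50) {
    case <- random_layer_case(seed)
    W <- weights_matrix(case$w)
    expect_equal(global_moran(case$y, case$w, permutations = 0)$I,
                 oracle_global_moran(case$y, W), tolerance = 1e-10)
    li <- local_moran(case$y, case$w, permutations = 0)
    expect_equal(li$Ii, oracle_local_moran(case$y, W), tolerance = 1e-10)
  }
})

test_that("mean of LISA values equals global I under row standardisation", {
  for (seed in 1:50) {
    case <- random_layer_case(seed)
    li <- local_moran(case$y, case$w, permutations = 0)
    expect_equal(mean(li$Ii),
                 global_moran(case$y, case$w, permutations = 0)$I,
                 tolerance = 1e-10)
  }
})

test_that("permutation p-values are bounded, seeded and reproducible", {
  case <- random_layer_case(5)
  g1 <- global_moran(case$y, case$w, permutations = 199, seed = 77)
  g2 <- global_moran(case$y, case$w, permutations = 199, seed = 77)
  expect_identical(g1$p_pseudo, g2$p_pseudo)
  expect_gte(g1$p_pseudo, 1 / 200)
  expect_lte(g1$p_pseudo, 1)
  l1 <- local_moran(case$y, case$w, permutations = 99, seed = 3)
  l2 <- local_moran(case$y, case$w, permutations = 99, seed = 3)
  expect_identical(l1$p_pseudo, l2$p_pseudo)
  expect_true(all(l1$p_pseudo >= 1 / 100 & l1$p_pseudo <= 1))
})

test_that("a cell whose neighbours all sit at the mean has zero local I", {
  # path of 5; values chosen so node 3's neighbours equal the overall mean
  y <- c(1, 4, 9, 4, 2)            # mean 4: nodes 2 and 4 sit at the mean
  w <- path_weights(5)
  li <- local_moran(y, w, permutations = 0)
  expect_equal(li$Ii[3], 0)
  # like-signed neighbourhoods give positive Ii
  y2 <- c(10, 9, 10, 1, 0)
  li2 <- local_moran(y2, path_weights(5), permutations = 0)
  expect_gt(li2$Ii[1], 0)
})

test_that("LISA quadrants follow the signs of value and lag", {
  case <- random_layer_case(13)
  li <- local_moran(case$y, case$w, permutations = 199, seed = 1)
  z <- case$y - mean(case$y)
  lag <- vapply(seq_len(case$w$n), function(i)
    sum(case$w$weights[[i]] * z[case$w$neighbors[[i]]]), numeric(1))
  sig <- li$quadrant != "not-significant"
  expect_true(all(li$quadrant[sig & z > 0 & lag > 0] == "HH"))
  expect_true(all(li$quadrant[sig & z < 0 & lag < 0] == "LL"))
})

test_that("cv_local follows the sd/|mean| definition and its identities", {
  expect_equal(cv_local(c(3, 3, 3)), 0)
  expect_equal(cv_local(c(1, 3, 1, 3)), sd(c(1, 3, 1, 3)) / 2)
  # sample-sd convention on two values 1, 3: sd = sqrt(2), mean = 2
  expect_equal(sd(c(1, 3)) / 2, sqrt(2) / 2)
  # scale invariance
  x <- c(0.2, 0.5, 1.4, 0.9)
  expect_equal(cv_local(x), cv_local(10 * x), tolerance = 1e-12)
  expect_warning(v <- cv_local(c(-1, 0, 1)), "infinite")
  expect_identical(v, Inf)
})

test_that("global Moran's I increases with the field correlation range", {
  med_I <- vapply(c(30, 150, 600), function(a) {
    Is <- vapply(1:20, function(s) {
      pd <- simulate_field(field_spec(n_points = 120, range_km = a,
                                      nugget = 0.05, seed = 1000 + s))
      layer <- hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = 100))
      w <- suppressWarnings(contiguity_weights(layer))
      global_moran(hex_cells(layer)$value, w, permutations = 0)$I
    }, numeric(1))
    median(Is)
  }, numeric(1))
  expect_true(all(diff(med_I) > 0))
})

test_that("weights export as symmetric sparse triplets", {
  case <- random_layer_case(3)
  tr <- weights_triplets(case$w)
  # neighbour relation is symmetric regardless of weight style
  key <- paste(tr$i, tr$j)
  rev <- paste(tr$j, tr$i)
  expect_true(all(rev %in% key))
  expect_false(any(tr$i == tr$j))
})
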