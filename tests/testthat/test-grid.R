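test_that("equirectangular projection maps known arcs correctly", {
  pd <- point_data(c(0, 1), c(0, 0), c(1, 2), crs = "lonlat")
  pl <- project_to_planar(pd, lon0 = 0, lat0 = 0)
  expect_equal(pl$x[1], 0)
  expect_equal(pl$y[1], 0)
  # one degree of longitude at the equator: R * pi/180
  expect_equal(pl$x[2], 6378.137 * pi / 180, tolerance = 1e-10)

  # at 60N a degree of longitude spans half its equatorial length
  pd60 <- point_data(c(10, 11), c(60, 60), c(1, 2), crs = "lonlat")
  pl60 <- project_to_planar(pd60, lon0 = 10, lat0 = 60)
  expect_equal(diff(pl60$x) / pl$x[2], cos(pi / 3), tolerance = 1e-12)
})

test_that("projection round trip returns the input coordinates", {
  set.seed(11)
  pd <- point_data(runif(50, -120, -70), runif(50, 25, 48),
                   rnorm(50), crs = "lonlat")
  pl <- project_to_planar(pd)
  ll <- planar_to_lonlat(pl$x, pl$y, pl$meta$proj)
  expect_lt(max(abs(ll$lon - pd$x)), 1e-9)
  expect_lt(max(abs(ll$lat - pd$y)), 1e-9)
})

test_that("latitude outside [-90, 90] is rejected", {
  expect_error(point_data(0, 91, 1, crs = "lonlat"), "latitude")
})

test_that("hexagons are regular with the requested side and area", {
  layer <- make_hex_grid(c(0, 0, 500, 400), side = 80)
  v <- hex_vertices(layer, layer$centers$cell_id[5])
  edges <- sqrt(diff(c(v[, 1], v[1, 1]))^2 + diff(c(v[, 2], v[1, 2]))^2)
  expect_equal(unname(edges), rep(80, 6), tolerance = 1e-12)
  # shoelace area equals (3 sqrt(3) / 2) s^2
  area <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                  c(v[-1, 1], v[1, 1]) * v[, 2])) / 2
  expect_equal(area, 3 * sqrt(3) / 2 * 80^2, tolerance = 1e-9)
})

test_that("oversized side length yields a single covering cell with a warning", {
  expect_warning(layer <- make_hex_grid(c(0, 0, 1, 1), side = 100),
                 "single cell")
  pts <- cbind(runif(20), runif(20))
  cid <- hex_assign(layer, pts[, 1], pts[, 2])
  expect_length(unique(cid), 1L)
})

test_that("every bbox point lands in exactly one hexagon (geometric oracle)", {
  layer <- make_hex_grid(c(0, 0, 300, 200), side = 35)
  set.seed(42)
  px <- runif(1000, 0, 300)
  py <- runif(1000, 0, 200)
  cid <- hex_assign(layer, px, py)
  expect_false(any(is.na(cid)))
  # brute force: count containing hexagons over all cells
  for (k in sample(1000, 60)) {
    inside <- vapply(layer$centers$cell_id, function(id) {
      v <- hex_vertices(layer, id)
      oracle_point_in_poly(px[k], py[k], v[, 1], v[, 2])
    }, logical(1))
    # boundary points may sit in 2-3 closed hexagons; the assigned cell
    # must always be among the containing ones, and interior points in one
    expect_true(sum(inside) >= 1)
    expect_true(inside[match(cid[k], layer$centers$cell_id)])
  }
})

test_that("edge points are assigned deterministically to one cell", {
  layer <- make_hex_grid(c(0, 0, 100, 100), side = 10)
  # midpoint between two adjacent cell centres lies on the shared edge
  c1 <- layer$centers[1, ]
  nb_q <- c1$q + 1L; nb_r <- c1$r
  i2 <- which(layer$centers$q == nb_q & layer$centers$r == nb_r)
  ex <- (c1$x + layer$centers$x[i2]) / 2
  ey <- (c1$y + layer$centers$y[i2]) / 2
  a <- hex_assign(layer, ex, ey)
  b <- hex_assign(layer, ex, ey)
  expect_identical(a, b)
  expect_length(a, 1L)
  expect_false(is.na(a))
  # tie resolves to the lexicographically smaller centre
  cand <- layer$centers[layer$centers$cell_id %in% c(c1$cell_id, layer$centers$cell_id[i2]), ]
  lex <- cand$cell_id[order(cand$x, cand$y)][1]
  expect_equal(a, lex)
})

test_that("aggregation reproduces brute-force group-by statistics", {
  set.seed(7)
  pd <- point_data(runif(400, 0, 300), runif(400, 0, 200),
                   rnorm(400, 50, 10), crs = "planar-km")
  layer <- make_hex_grid(c(0, 0, 300, 200), side = 40)
  for (stat in c("mean", "median", "max")) {
    agg <- hex_aggregate(pd, layer, statistic = stat)
    cid <- hex_assign(layer, pd$x, pd$y)
    fun <- switch(stat, mean = mean, median = median, max = max)
    ref <- tapply(pd$values, cid, fun)
    cells <- hex_cells(agg)
    expect_equal(cells$value[match(as.integer(names(ref)), cells$cell_id)],
                 unname(as.numeric(ref)), tolerance = 1e-12)
  }
})

test_that("cell counts conserve the number of input points", {
  set.seed(8)
  pd <- point_data(runif(500, 0, 300), runif(500, 0, 200),
                   rnorm(500), crs = "planar-km")
  for (side in c(30, 60, 120)) {
    agg <- hex_aggregate(pd, make_hex_grid(c(0, 0, 300, 200), side = side))
    expect_identical(sum(agg$cell_counts), 500L)
  }
})

test_that("non-empty cell count is non-increasing in side length", {
  pd <- simulate_field(field_spec(n_points = 300, seed = 9))
  counts <- vapply(c(30, 60, 120, 240, 480), function(s) {
    agg <- suppressWarnings(
      hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = s)))
    sum(!is.na(agg$cell_values))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("min_count filters thin cells and empty layers error", {
  pd <- point_data(c(1, 2, 100), c(1, 2, 100), c(10, 20, 30),
                   crs = "planar-km")
  layer <- make_hex_grid(c(0, 0, 120, 120), side = 10)
  agg <- hex_aggregate(pd, layer, min_count = 2)
  cells <- hex_cells(agg)
  expect_equal(nrow(cells), 1L)       # only the two-point cell survives
  expect_equal(cells$value, 15)
  expect_error(hex_aggregate(pd, layer, min_count = 5), "empty layer")
})

test_that("aggregated layers round-trip through CSV and GeoJSON", {
  pd <- simulate_field(field_spec(n_points = 60, seed = 10))
  agg <- hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = 150))
  csv <- tempfile(fileext = ".csv")
  write_hex_layer(agg, csv)
  back <- read.csv(csv)
  expect_equal(back$value, hex_cells(agg)$value)
  gj <- tempfile(fileext = ".geojson")
  write_hex_layer(agg, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, nrow(hex_cells(agg)))
})
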