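test_that("normalisation picks a sensible transform and inverts exactly", {
  set.seed(17)
  x <- rnorm(200, 50, 5)
  nz <- normalize_values(x)
  expect_lt(max(abs(inverse_normalize(nz$values, nz$transform) - x)), 1e-9)

  xl <- exp(rnorm(200, 0, 1))
  nzl <- normalize_values(xl)
  expect_false(nzl$transform$type == "identity")
  expect_lt(abs(oracle_skewness(nzl$values)), abs(oracle_skewness(xl)))
  expect_lt(max(abs(inverse_normalize(nzl$values, nzl$transform) - xl)), 1e-7)
})

test_that("degenerate inputs fall back to identity with a warning", {
  expect_warning(nz <- normalize_values(rep(3, 20)), "constant")
  expect_identical(nz$transform$type, "identity")
  expect_warning(nz2 <- normalize_values(c(1, 2, 3)), "fewer than 10")
  expect_identical(nz2$values, c(1, 2, 3))
  expect_error(normalize_values(c(1, NA, 3)), "invalid value")
})

test_that("each candidate transform round-trips on random data", {
  set.seed(18)
  x <- rgamma(100, 2, 1) + 0.5
  for (cand in c("identity", "log", "sqrt", "boxcox", "yeojohnson",
                 "orderquant")) {
    nz <- normalize_values(x, candidates = cand)
    expect_lt(max(abs(inverse_normalize(nz$values, nz$transform) - x)),
              1e-7)
  }
})

test_that("the Matheron estimator matches hand and brute-force computation", {
  # a bin holding a single pair: gamma = (z1 - z2)^2 / 2
  pd <- point_data(0:9, rep(0, 10), c(5, rep(1, 8), 2), crs = "planar-km")
  emp1 <- suppressWarnings(   # sparse fixture leaves some bins empty
    empirical_variogram(pd, n_lags = 19, max_dist = 9.5))
  last <- nrow(emp1)
  expect_equal(emp1$n_pairs[last], 1L)       # only the (0, 9) pair
  expect_equal(emp1$gamma[last], (5 - 2)^2 / 2)

  # direct brute force over all pairs
  set.seed(19)
  pd2 <- point_data(runif(40, 0, 100), runif(40, 0, 100), rnorm(40),
                    crs = "planar-km")
  emp <- empirical_variogram(pd2, n_lags = 8)
  d <- as.matrix(dist(cbind(pd2$x, pd2$y)))
  g <- outer(pd2$values, pd2$values, `-`)^2
  maxd <- attr(emp, "max_dist")
  breaks <- seq(0, maxd, length.out = 9)
  for (k in seq_len(nrow(emp))) {
    bin <- which(breaks - emp$lag[k] > 0)[1] - 1L
    sel <- d > breaks[bin] & d <= breaks[bin + 1] & upper.tri(d)
    if (bin == 1) sel <- d <= breaks[2] & d > 0 & upper.tri(d)
    expect_equal(emp$gamma[k], sum(g[sel]) / (2 * sum(sel)),
                 tolerance = 1e-10)
    expect_equal(emp$n_pairs[k], sum(sel))
  }
})

test_that("a white-noise field gives a flat variogram near the variance", {
  pd <- simulate_field(field_spec(n_points = 300, covariance = "nugget-only",
                                  sill = 0, nugget = 4, mean = 0, seed = 20))
  emp <- empirical_variogram(pd, n_lags = 10)
  # every well-filled bin should sit near nugget variance 4
  big <- emp$n_pairs > 200
  expect_true(all(abs(emp$gamma[big] - 4) / 4 < 0.35))
})

test_that("variogram fitting recovers noise-free exponential parameters", {
  h <- seq(5, 150, by = 5)
  gamma <- 0 + 1 * (1 - exp(-h / 50))
  emp <- structure(data.frame(lag = h, gamma = gamma,
                              n_pairs = rep(100L, length(h)),
                              flagged = FALSE),
                   class = c("empirical_variogram", "data.frame"),
                   max_dist = 150)
  vg <- fit_variogram(emp, "exponential")
  expect_equal(vg$nugget, 0, tolerance = 0.01)
  expect_equal(vg$psill, 1, tolerance = 0.01)
  expect_equal(vg$range, 50, tolerance = 0.5)
})

test_that("a flat empirical variogram warns that the range is unidentifiable", {
  h <- seq(5, 100, by = 5)
  emp <- structure(data.frame(lag = h, gamma = rep(2, length(h)),
                              n_pairs = rep(50L, length(h)), flagged = FALSE),
                   class = c("empirical_variogram", "data.frame"),
                   max_dist = 100)
  expect_warning(vg <- fit_variogram(emp, "exponential"), "flat")
  expect_lt(vg$psill, 0.05)
})

test_that("fitted ranges recover the simulated truth within a factor of two", {
  # domain several effective ranges across so the range is identifiable
  ok <- vapply(1:20, function(s) {
    pd <- simulate_field(field_spec(bbox = c(0, 0, 2000, 1600),
                                    n_points = 400, range_km = 100,
                                    sill = 1, nugget = 0, seed = 600 + s))
    vg <- suppressWarnings(fit_variogram(empirical_variogram(pd)))
    vg$range >= 50 && vg$range <= 200
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("ordinary kriging is exact, unbiased and matches the symmetry case", {
  pd <- simulate_field(field_spec(n_points = 50, nugget = 0, seed = 23))
  vg <- fit_variogram(empirical_variogram(pd))
  pr <- ordinary_kriging(pd, vg, targets = cbind(pd$x, pd$y))
  expect_lt(max(abs(pr$estimate - pd$values)), 1e-8)
  expect_lt(max(abs(attr(pr, "weight_sums") - 1)), 1e-10)
  expect_true(all(pr$variance >= 0))

  # two equal-valued points symmetric about the target: weights (1/2, 1/2)
  p2 <- point_data(c(-10, 10), c(0, 0), c(7, 7), crs = "planar-km")
  vg2 <- structure(list(model = "exponential", nugget = 0, psill = 1,
                        range = 30, sse = 0, converged = TRUE, emp = NULL),
                   class = "variogram_model")
  pr2 <- ordinary_kriging(p2, vg2, targets = cbind(0, 0))
  expect_equal(pr2$estimate, 7, tolerance = 1e-12)
  expect_equal(attr(pr2, "weight_sums"), 1, tolerance = 1e-12)
})

test_that("kriging agrees with an independent covariance-form implementation", {
  for (s in 1:20) {
    set.seed(3000 + s)
    n <- sample(10:50, 1)
    x <- runif(n, 0, 200); y <- runif(n, 0, 200)
    z <- rnorm(n, 50, 10)
    sill <- runif(1, 0.5, 2); a <- runif(1, 30, 120)
    nug <- sample(c(0, 0.2), 1)
    pd <- point_data(x, y, z, crs = "planar-km")
    vg <- structure(list(model = "exponential", nugget = nug, psill = sill,
                         range = a, sse = 0, converged = TRUE, emp = NULL),
                    class = "variogram_model")
    tx <- runif(5, 0, 200); ty <- runif(5, 0, 200)
    pr <- ordinary_kriging(pd, vg, targets = cbind(tx, ty))
    ref <- oracle_kriging(x, y, z, sill, a, nug, tx, ty)
    expect_equal(pr$estimate, ref, tolerance = 1e-6)
  }
})

test_that("duplicate locations raise a singular-system error with guidance", {
  pd <- point_data(c(0, 0, 5), c(1, 1, 2), c(1, 2, 3), crs = "planar-km")
  vg <- structure(list(model = "exponential", nugget = 0, psill = 1,
                       range = 10, sse = 0, converged = TRUE, emp = NULL),
                  class = "variogram_model")
  expect_error(ordinary_kriging(pd, vg, targets = cbind(1, 1)),
               "deduplicate")
})

test_that("local-neighbourhood kriging stays unbiased and near the global fit", {
  pd <- simulate_field(field_spec(n_points = 80, nugget = 0, seed = 29))
  vg <- fit_variogram(empirical_variogram(pd))
  tg <- cbind(c(200, 500), c(300, 100))
  loc <- ordinary_kriging(pd, vg, targets = tg, neighbors = 20)
  expect_lt(max(abs(attr(loc, "weight_sums") - 1)), 1e-10)
})

test_that("normalize -> krige -> back-transform round-trips at data points", {
  pd <- simulate_field(field_spec(n_points = 60, nugget = 0, mean = 40,
                                  sill = 4, seed = 31))
  nz <- normalize_values(pd$values)
  work <- point_data(pd$x, pd$y, nz$values, crs = "planar-km")
  vg <- fit_variogram(empirical_variogram(work))
  pr <- ordinary_kriging(work, vg, targets = cbind(pd$x[1:10], pd$y[1:10]))
  back <- inverse_normalize(pr$estimate, nz$transform)
  expect_lt(max(abs(back - pd$values[1:10])), 1e-6)
})

test_that("indicator kriging yields probabilities with the right extremes", {
  pd <- simulate_field(field_spec(n_points = 80, nugget = 0, seed = 25))
  thr <- median(pd$values)
  ik <- indicator_kriging(pd, thr, grid_n = 12)
  expect_true(all(ik$estimate >= 0 & ik$estimate <= 1))
  # exact at data-coincident targets
  ik2 <- indicator_kriging(pd, thr, targets = cbind(pd$x, pd$y))
  ind <- as.numeric(pd$values > thr)
  expect_lt(max(abs(ik2$estimate - ind)), 1e-6)
  # all data above threshold: constant 1 with a warning
  expect_warning(ik3 <- indicator_kriging(pd, min(pd$values) - 1,
                                          grid_n = 5), "one side")
  expect_true(all(ik3$estimate == 1))
})

test_that("the exceedance surface crosses 0.5 between separated clusters", {
  set.seed(26)
  x <- c(runif(20, 0, 50), runif(20, 250, 300))
  y <- runif(40, 0, 50)
  z <- c(rnorm(20, 10, 1), rnorm(20, 90, 1))
  pd <- point_data(x, y, z, crs = "planar-km")
  tr <- seq(10, 290, by = 10)
  ik <- suppressWarnings(   # cluster gap empties mid-range lag bins
    indicator_kriging(pd, 50, targets = cbind(tr, 25)))
  expect_lt(ik$estimate[1], 0.2)
  expect_gt(ik$estimate[length(tr)], 0.8)
  expect_true(any(diff(sign(ik$estimate - 0.5)) != 0))
})
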