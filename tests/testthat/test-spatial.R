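# IDW interpolation, buffer clipping and fold ratios, checked against
# brute-force oracles.

test_that("a single sample gives a constant field", {
  g <- grid_spec(c(0, 0), 1, 5, 5)
  f <- idw_interpolate(2.5, 2.5, 7.3, grid = g)
  expect_equal(as.vector(f$values), rep(7.3, 25))
})

test_that("the midpoint of two samples is their average", {
  # 9-column grid: the center cell (x = 4.5) is the exact midpoint of
  # samples at x = 0.5 and 8.5
  g <- grid_spec(c(0, 0), 1, 1, 9)
  f <- idw_interpolate(c(0.5, 8.5), c(0.5, 0.5), c(0, 10), grid = g)
  expect_equal(f$values[1, 5], 5)
  expect_equal(f$values[1, 4], 10 - f$values[1, 6])  # symmetry
})

test_that("IDW matches the brute-force oracle cell for cell", {
  set.seed(42)
  x <- runif(5, 0, 10); y <- runif(5, 0, 10); v <- runif(5, 0, 100)
  g <- grid_spec(c(0, 0), 1, 10, 10)
  for (p in c(1, 2, 3.5)) {
    f <- idw_interpolate(x, y, v, grid = g, power = p)
    expect_equal(f$values, idw_brute_force(x, y, v, g, power = p),
                 tolerance = 1e-12)
  }
  # and with a restricted neighborhood
  f3 <- idw_interpolate(x, y, v, grid = g, power = 2, max_neighbors = 3)
  expect_equal(f3$values, idw_brute_force(x, y, v, g, max_neighbors = 3),
               tolerance = 1e-12)
})

test_that("predictions are bounded by the data and exact at sample points", {
  set.seed(43)
  x <- runif(8, 0, 10); y <- runif(8, 0, 10); v <- runif(8, -5, 50)
  f <- idw_interpolate(x, y, v, grid = grid_spec(c(0, 0), 0.5, 20, 20))
  expect_gte(min(f$values), min(v))
  expect_lte(max(f$values), max(v))
  # put samples exactly on cell centers: interpolator must reproduce them
  g <- grid_spec(c(0, 0), 1, 10, 10)
  xs <- c(2.5, 7.5); ys <- c(3.5, 8.5); vs <- c(1, 9)
  fe <- idw_interpolate(xs, ys, vs, grid = g)
  expect_equal(fe$values[4, 3], 1)   # row 4 = y 3.5, col 3 = x 2.5
  expect_equal(fe$values[9, 8], 9)
})

test_that("large powers reduce IDW to nearest-neighbor", {
  g <- grid_spec(c(0, 0), 1, 1, 10)
  f <- idw_interpolate(c(0.5, 9.5), c(0.5, 0.5), c(0, 10), grid = g,
                       power = 50)
  expect_equal(f$values[1, 1:5], rep(0, 5), tolerance = 1e-3)
  expect_equal(f$values[1, 6:10], rep(10, 5), tolerance = 1e-3)
})

test_that("IDW is translation invariant and scaling equivariant", {
  set.seed(44)
  x <- runif(6, 0, 10); y <- runif(6, 0, 10); v <- runif(6)
  g <- grid_spec(c(0, 0), 1, 10, 10)
  f0 <- idw_interpolate(x, y, v, grid = g)
  gt <- grid_spec(c(0, 0) + c(100, -50), 1, 10, 10)
  ft <- idw_interpolate(x + 100, y - 50, v, grid = gt)
  expect_equal(ft$values, f0$values, tolerance = 1e-10)
  gs <- grid_spec(c(0, 0), 3, 10, 10)
  fs <- idw_interpolate(3 * x, 3 * y, v, grid = gs)
  expect_equal(fs$values, f0$values, tolerance = 1e-10)
})

test_that("duplicate coordinates are collapsed or rejected", {
  g <- grid_spec(c(0, 0), 1, 3, 3)
  expect_error(idw_interpolate(c(1, 1), c(2, 2), c(5, 6), grid = g),
               "conflicting")
  f <- idw_interpolate(c(1, 1, 2), c(2, 2, 2), c(5, 5, 7), grid = g)
  expect_true(all(is.finite(f$values)))
  expect_error(idw_interpolate(numeric(0), numeric(0), numeric(0)),
               "at least one")
})

test_that("buffer clipping masks exactly the cells beyond the radius", {
  g <- grid_spec(c(0, 0), 1, 10, 10)
  f <- idw_interpolate(5.5, 5.5, 1, grid = g)
  fc <- clip_to_buffer(f, 5.5, 5.5, radius = 3)
  cc <- grid_centers(fc)
  d <- sqrt((cc$X - 5.5)^2 + (cc$Y - 5.5)^2)
  expect_equal(fc$mask, d <= 3)              # all-pairs oracle
  expect_true(fc$mask[6, 6])                 # at distance 0
  expect_true(fc$mask[6, 9])                 # distance 3 - eps retained
  expect_false(fc$mask[6, 10])               # beyond the radius
  expect_true(all(is.na(fc$values[!fc$mask])))
  # growing the radius never shrinks the unmasked area
  masks <- sapply(c(1, 2, 4, 8), function(r) {
    sum(clip_to_buffer(f, 5.5, 5.5, radius = r)$mask)
  })
  expect_true(all(diff(masks) >= 0))
})

test_that("fold_ratio contrasts hot and cold quantile means", {
  expect_equal(fold_ratio(uniform_field(3)), 1)
  ramp <- uniform_field(0)
  ramp$values <- matrix(0:99, 10, 10)
  expect_equal(fold_ratio(ramp), mean(90:99) / mean(0:9))  # 94.5/4.5 = 21
  hot <- uniform_field(1)
  hot$values[5, 5] <- 100
  expect_gt(fold_ratio(hot), 1)
  zero_cold <- uniform_field(0)
  zero_cold$values[1, 1] <- 5
  expect_warning(r <- fold_ratio(zero_cold), "zero")
  expect_equal(r, Inf)
  small <- uniform_field(1, n = 3)
  expect_error(fold_ratio(small), ">= 10")
})

test_that("ESRI ASCII rasters round trip", {
  set.seed(45)
  f <- idw_interpolate(runif(4, 0, 10), runif(4, 0, 10), runif(4),
                       grid = grid_spec(c(-2, 3), 0.5, 8, 12))
  f <- clip_to_buffer(f, c(2, 8), c(5, 5), radius = 4)
  p <- tempfile(fileext = ".asc")
  write_esri_ascii(f, p)
  f2 <- read_esri_ascii(p)
  expect_equal(f2$grid$nrows, f$grid$nrows)
  expect_equal(f2$grid$origin, f$grid$origin)
  expect_equal(f2$mask, f$mask)
  expect_equal(f2$values, f$values, tolerance = 1e-8)
})
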