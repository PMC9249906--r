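test_that("ASCII grid round-trip preserves values, mask and transform", {
  v <- matrix(c(1, 2, 3, -9999), 2, 2, byrow = TRUE)
  r <- rasterLayer(v, xll = 5, yll = 40, cellsize = 0.25,
                   kind = "continuous")
  expect_equal(sum(is.na(rasterValues(r))), 1)

  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(r, f)
  r2 <- readAsciiGrid(f)
  expect_identical(rasterValues(r2), rasterValues(r))
  expect_equal(r2@xll, 5)
  expect_equal(r2@yll, 40)
  expect_equal(r2@cellsize, 0.25)
  expect_equal(rasterCRS(r2), "EPSG:4326")

  # integer grids round-trip bit-exactly
  ri <- rasterLayer(matrix(sample(0:1000, 64), 8), kind = "categorical")
  fi <- tempfile(fileext = ".asc")
  writeAsciiGrid(ri, fi)
  expect_identical(rasterValues(readAsciiGrid(fi, kind = "categorical")),
                   rasterValues(ri))
})

test_that("reading a non-grid text file fails with a format error", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("this is", "not a raster"), f)
  expect_error(readAsciiGrid(f), "ASCII grid")
  expect_error(readAsciiGrid(tempfile()), "not found")
})

test_that("alignToGrid is identity on an already-aligned layer", {
  r <- rasterLayer(matrix(runif(36), 6), cellsize = 0.1)
  expect_identical(rasterValues(alignToGrid(r, r)), rasterValues(r))
})

test_that("constant continuous layer stays constant under resampling", {
  src <- rasterLayer(matrix(7, 8, 8), cellsize = 0.5)
  ref <- rasterLayer(matrix(0, 4, 4), cellsize = 1)
  out <- alignToGrid(src, ref)
  expect_true(all(rasterValues(out) == 7))
  expect_equal(dim(out), c(4L, 4L))
})

test_that("categorical downsampling picks the nearest parent cell", {
  set.seed(11)
  v <- matrix(sample(1:9, 100, replace = TRUE), 10, 10)
  src <- rasterLayer(v, cellsize = 0.1, kind = "categorical")
  ref <- rasterLayer(matrix(0, 5, 5), cellsize = 0.2)
  out <- alignToGrid(src, ref)

  # brute-force oracle: every output cell must equal one of the source
  # cells whose center is nearest to the target center (its 2x2 parents)
  for (i in 1:5) for (j in 1:5) {
    parents <- v[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    expect_true(rasterValues(out)[i, j] %in% parents)
  }

  # off-center 3->1 downsampling has a unique nearest source cell
  src3 <- rasterLayer(matrix(1:36, 6, 6), cellsize = 0.1,
                      kind = "categorical")
  ref3 <- rasterLayer(matrix(0, 2, 2), cellsize = 0.3)
  out3 <- alignToGrid(src3, ref3)
  for (i in 1:2) for (j in 1:2) {
    x <- ref3@xll + (j - 0.5) * 0.3
    y <- ref3@yll + (2 - i + 0.5) * 0.3
    sx <- src3@xll + (seq_len(6) - 0.5) * 0.1
    sy <- src3@yll + (6 - seq_len(6) + 0.5) * 0.1
    expect_equal(rasterValues(out3)[i, j],
                 rasterValues(src3)[which.min(abs(sy - y)),
                                    which.min(abs(sx - x))])
  }
})

test_that("CRS handling: mismatch errors, alignment requires a CRS", {
  a <- rasterLayer(matrix(1, 2, 2), crs = "EPSG:4326")
  b <- rasterLayer(matrix(1, 2, 2), crs = "EPSG:3035")
  expect_error(alignToGrid(a, b), "CRS mismatch")
})

test_that("zonal aggregation: mean, missing exclusion, weighted sum, mode", {
  zones <- rasterLayer(matrix(c(1, 1, 2, 2), 2), kind = "categorical")

  vals <- rasterLayer(matrix(c(10, 30, 5, 7), 2))
  zt <- zonalAggregate(vals, zones, "mean")
  expect_equal(zt$value[zt$zone_id == 1], 20)

  vals2 <- rasterLayer(matrix(c(10, NA, 5, 7), 2))
  zt2 <- zonalAggregate(vals2, zones, "mean")
  expect_equal(zt2$value[zt2$zone_id == 1], 10)

  # per-cell areas of 100 ha: zone sums recover planted totals
  w <- matrix(100, 2, 2)
  zt3 <- zonalAggregate(rasterLayer(matrix(1, 2, 2)), zones, "sum",
                        weights = w)
  expect_equal(zt3$value, c(200, 200))

  # mode with a tie resolves to the smallest category code
  vals4 <- rasterLayer(matrix(c(3, 1, 2, 2), 2), kind = "categorical")
  zt4 <- zonalAggregate(vals4, zones, "mode")
  expect_equal(zt4$value[zt4$zone_id == 1], 1)

  expect_error(zonalAggregate(vals, rasterLayer(matrix(1, 3, 3))),
               "share a grid")
})

test_that("zonal mean of a constant layer is that constant in every zone", {
  set.seed(3)
  zones <- rasterLayer(matrix(sample(1:4, 64, replace = TRUE), 8),
                       kind = "categorical")
  const <- rasterLayer(matrix(4.2, 8, 8))
  zt <- zonalAggregate(const, zones, "mean", weights = cellAreaHa(const))
  expect_equal(zt$value, rep(4.2, nrow(zt)))
})

test_that("per-zone area sums conserve the total unmasked area", {
  w <- smallWorld()
  soc <- w$rasters$soc
  area <- cellAreaHa(soc)
  ones <- rasterLayer(matrix(1, nrow(area), ncol(area)),
                      xll = soc@xll, yll = soc@yll,
                      cellsize = soc@cellsize)
  zt <- zonalAggregate(ones, w$rasters$regions, "sum", weights = area)
  expect_equal(sum(zt$value), sum(area))
})

test_that("geodesic cell area scales with the cosine of latitude", {
  r <- rasterLayer(matrix(0, 3, 1), xll = 0, yll = 45, cellsize = 1)
  a <- cellAreaHa(r)
  lat <- 45 + (3 - (1:3) + 0.5)  # row 1 = northernmost
  expect_equal(a[, 1], (111320)^2 * cos(lat * pi / 180) / 1e4)
  # projected grids: flat cellsize^2
  rp <- rasterLayer(matrix(0, 2, 2), cellsize = 100, crs = "EPSG:3035")
  expect_equal(cellAreaHa(rp)[1, 1], 1)
})
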