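mkMask <- function(mask, grid, soc_class = NULL, prov = NULL) {
  p <- matrix(NA_character_, nrow(mask), ncol(mask))
  p[mask] <- if (is.null(prov)) "bare" else prov
  s <- matrix(NA_integer_, nrow(mask), ncol(mask))
  s[mask] <- if (is.null(soc_class)) 3L else soc_class
  new("MarginalLandMask", mask = mask, provenance = p, socClass = s,
      grid = grid)
}

test_that("zone assignment labels cells and drops missing zones", {
  grid <- rasterLayer(matrix(0, 2, 2), cellsize = 0.05)
  mask <- mkMask(matrix(TRUE, 2, 2), grid)
  regions <- rasterLayer(matrix(c(1, 1, 2, NA), 2, 2),
                         kind = "categorical")
  gez <- rasterLayer(matrix(c(13, 22, 13, 22), 2, 2),
                     kind = "categorical")
  expect_message(z <- assignZones(mask, regions, gez), "dropped")
  expect_equal(z$dropped, 1)
  expect_equal(z$region[1, 1], 1)
  expect_equal(z$gez[1, 1], "TBSh")
  expect_true(is.na(z$region[2, 2]))

  # two regions x two zones -> exactly 4 distinct labels
  labs <- unique(paste(z$region[z$mask], z$gez[z$mask]))
  expect_equal(length(labs), 3)  # one cell dropped from the 2x2 cross
  regions2 <- rasterLayer(matrix(c(1, 1, 2, 2), 2, 2),
                          kind = "categorical")
  z2 <- assignZones(mask, regions2, gez)
  expect_equal(length(unique(paste(z2$region[z2$mask],
                                   z2$gez[z2$mask]))), 4)
})

test_that("water and polar ecological zones are excluded by default", {
  grid <- rasterLayer(matrix(0, 1, 2), cellsize = 0.05)
  mask <- mkMask(matrix(TRUE, 1, 2), grid)
  regions <- rasterLayer(matrix(1, 1, 2), kind = "categorical")
  gez <- rasterLayer(matrix(c(90, 50), 1, 2), kind = "categorical")
  expect_message(z <- assignZones(mask, regions, gez))
  expect_equal(z$dropped, 2)
})

clim1 <- function(grid, t = 20, p = 60, e = 70) {
  mk <- function(v) rasterLayer(matrix(v, nrow(grid@values),
                                       ncol(grid@values)),
                                xll = grid@xll, yll = grid@yll,
                                cellsize = grid@cellsize)
  list(temp = lapply(rep(t, 12), mk), prec = lapply(rep(p, 12), mk),
       pet = lapply(rep(e, 12), mk))
}

test_that("single-cell and two-cell consolidation reproduce attributes", {
  grid <- rasterLayer(matrix(0, 1, 2), cellsize = 0.05)
  mask <- mkMask(matrix(c(TRUE, TRUE), 1, 2), grid)
  regions <- rasterLayer(matrix(1, 1, 2), kind = "categorical")
  gez <- rasterLayer(matrix(13, 1, 2), kind = "categorical")
  z <- assignZones(mask, regions, gez)

  mk <- function(v) rasterLayer(matrix(v, 1, 2), cellsize = 0.05)
  # equal-area cells at one latitude: clay 10 and 30 average to 20
  areas <- consolidateTargetAreas(
    mask, z, soc = mk(c(20, 30)),
    soil = list(clay = mk(c(10, 30)), ph = mk(c(6, 7)),
                texture = rasterLayer(matrix(c(2, 2), 1, 2),
                                      kind = "categorical"),
                bulk_density = mk(1.4), soil_depth = mk(30)),
    terrain = list(elevation = mk(c(100, 300)), slope = mk(5)),
    soil_loss = mk(4), climate = clim1(grid))
  expect_length(areas, 1)
  a <- areas[[1]]
  expect_equal(a@clayPct, 20)
  expect_equal(a@socInit, 25)
  expect_equal(a@ph, 6.5)
  expect_equal(a@elevationM, 200)
  expect_equal(a@texture, "medium")
  expect_equal(a@tempMonthly, rep(20, 12))
  expect_equal(a@areaHa, sum(cellAreaHa(grid)))
})

test_that("consolidation conserves area and is permutation-invariant", {
  w <- smallWorld()
  pl <- runPipeline(w, horizon_years = 1)
  tot_mask <- sum(cellAreaHa(w$rasters$soc)[pl$zones$mask])
  tot_areas <- sum(vapply(pl$areas, function(a) a@areaHa, numeric(1)))
  expect_equal(tot_areas, tot_mask)

  # expected pair count from the generator's ground truth
  expect_length(pl$areas, w$ground_truth$n_target_areas)
})

test_that("area summaries convert units and normalise percentages", {
  a1 <- makeArea(area_ha = 1000)
  s <- summarizeAreas(list(a1))
  expect_equal(s$total_mha, 0.001)

  # the percentage arithmetic used for reference shares
  s2 <- summarizeAreas(list(a1), reference_mha = 0.1)
  expect_equal(s2$pct_of_reference, 1)
  expect_equal(percentShare(27.2, 2714), 1)

  a2 <- makeArea(region = "2", area_ha = 3000)
  s3 <- summarizeAreas(list(a1, a2))
  expect_equal(sum(s3$by_region$pct), 100)
  expect_equal(sum(s3$by_gez$pct), 100)
})
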