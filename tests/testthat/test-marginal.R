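legend <- readLandCoverLegend()

mkLC <- function(codes, nr = 2, nc = 2)
  rasterLayer(matrix(codes, nr, nc), kind = "categorical")

test_that("candidate cover keeps bare and sparse with provenance", {
  lc <- mkLC(c(200, 150, 10, 50))
  sel <- selectCandidateCover(lc, legend)
  expect_equal(sel$mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(sel$provenance[1, 1], "bare")
  expect_equal(sel$provenance[2, 1], "sparse")
  expect_true(all(is.na(sel$provenance[, 2])))

  # all-other grid yields an empty mask
  expect_false(any(selectCandidateCover(mkLC(rep(50, 4)), legend)$mask))
  # unmapped code is an error
  expect_error(selectCandidateCover(mkLC(c(999, 10, 10, 10)), legend),
               "not in legend")
})

test_that("abandonment requires cropland at t0 and a listed target at t1", {
  t0 <- mkLC(c(10, 10, 130, 10), 2, 2)
  t1 <- mkLC(c(130, 190, 200, 30), 2, 2)
  ab <- detectAbandonment(t0, t1, legend)
  expect_equal(ab, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  expect_error(detectAbandonment(t0, mkLC(rep(10, 9), 3, 3), legend),
               "share a grid")
})

test_that("SOC filter bins into 10 Mg/ha classes with inclusive cutoff", {
  soc <- rasterLayer(matrix(c(27, 50, 50.1, 0), 2, 2))
  f <- filterSOC(matrix(TRUE, 2, 2), soc, threshold = 50)
  expect_equal(f$mask, matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(f$soc_class[1, 1], 3L)   # 27 -> (20, 30]
  expect_equal(f$soc_class[2, 1], 5L)   # 50 retained, class 5
  expect_true(is.na(f$soc_class[1, 2])) # 50.1 excluded
  expect_true(is.na(f$soc_class[2, 2])) # SOC 0 treated as no-soil

  # class edges: 10 is class 1, 10.01 is class 2
  f2 <- filterSOC(matrix(TRUE, 1, 2),
                  rasterLayer(matrix(c(10, 10.01), 1, 2)))
  expect_equal(as.integer(f2$soc_class), c(1L, 2L))

  expect_warning(filterSOC(matrix(TRUE, 1, 1),
                           rasterLayer(matrix(-3, 1, 1))), "negative")
})

test_that("protected and problem-land exclusions behave as set differences", {
  m <- matrix(TRUE, 4, 4)
  all_prot <- rasterLayer(matrix(1, 4, 4), kind = "categorical")
  none_prot <- rasterLayer(matrix(0, 4, 4), kind = "categorical")
  expect_false(any(excludeProtected(m, all_prot)))
  expect_equal(excludeProtected(m, none_prot), m)

  set.seed(5)
  pm <- matrix(as.numeric(runif(16) < 0.5), 4, 4)
  part <- rasterLayer(pm, kind = "categorical")
  out <- excludeProtected(m, part)
  expect_equal(sum(out), sum(m) - sum(pm))  # boolean-algebra identity

  sev <- defaultSeverityCodes()
  prob <- rasterLayer(matrix(c(sev[1], 0, 10, sev[2]), 2, 2),
                      kind = "categorical")
  out2 <- excludeProblemLand(matrix(TRUE, 2, 2), prob)
  expect_equal(out2, matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  expect_error(
    excludeProblemLand(matrix(TRUE, 1, 1),
                       rasterLayer(matrix(999, 1, 1),
                                   kind = "categorical")),
    "unmapped")
})

test_that("full identification recovers planted counts and shares sum", {
  w <- smallWorld()
  r <- w$rasters
  out <- identifyMarginalLand(r$lc_t0, r$lc_t1, r$soc, r$protected,
                              r$problem)
  gt <- w$ground_truth$marginal_cells
  comp <- out$composition
  for (p in c("bare", "sparse", "abandoned"))
    expect_equal(comp$cells[comp$provenance == p], gt[[p]])
  expect_equal(sum(comp$share_pct), 100)

  # empty world: no candidates, no change -> empty mask
  lc <- rasterLayer(matrix(50, 4, 4), kind = "categorical")
  soc <- rasterLayer(matrix(30, 4, 4))
  zero <- rasterLayer(matrix(0, 4, 4), kind = "categorical")
  out0 <- identifyMarginalLand(lc, lc, soc, zero, zero)
  expect_false(any(out0$mask@mask))
})

test_that("steps 1.3-1.5 commute and SOC threshold is monotone", {
  w <- smallWorld()
  r <- w$rasters
  cand <- selectCandidateCover(r$lc_t1)$mask |
    detectAbandonment(r$lc_t0, r$lc_t1)

  ord1 <- excludeProblemLand(
    excludeProtected(filterSOC(cand, r$soc)$mask, r$protected),
    r$problem)
  ord2 <- filterSOC(
    excludeProtected(excludeProblemLand(cand, r$problem), r$protected),
    r$soc)$mask
  expect_identical(ord1, ord2)

  m30 <- filterSOC(cand, r$soc, threshold = 30)$mask
  m50 <- filterSOC(cand, r$soc, threshold = 50)$mask
  expect_true(all(m50[m30]))  # raising the threshold never shrinks
})

test_that("abandoned provenance takes precedence on doubly-qualified cells", {
  # cropland -> bare transition: qualifies via both 1.1 and 1.2
  t0 <- mkLC(c(10, 200, 50, 50))
  t1 <- mkLC(c(200, 200, 50, 50))
  soc <- rasterLayer(matrix(25, 2, 2))
  zero <- rasterLayer(matrix(0, 2, 2), kind = "categorical")
  out <- identifyMarginalLand(t0, t1, soc, zero, zero)
  expect_equal(out$mask@provenance[1, 1], "abandoned")
  expect_equal(out$mask@provenance[2, 1], "bare")
})
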