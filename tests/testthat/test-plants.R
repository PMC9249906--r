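speciesCSV <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

baseRow <- function(...) {
  row <- data.frame(
    name = "test", taxon = "Testum sp", life_form = "grass",
    lifecycle = "annual", lifetime_yr = 1,
    temp_min = 5, temp_max = 30, prec_min = 200, prec_max = 1500,
    ph_min = 5, ph_max = 8, texture_ok = "medium|fine",
    alt_min = 0, alt_max = 2000, gez_ok = "TBSh|SBSh",
    yield_dm = 5, dm_product = 2, dm_stem = 4, dm_leaf = 1, dm_root = 1,
    c_product = 45, c_stem = 45, c_leaf = 42, c_root = 40,
    ret_product = 0, ret_stem = 1, ret_leaf = 1, ret_root = 1,
    deciduous = FALSE, cover_factor = 0.3, cover_months = "",
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}

test_that("species loading validates rows and reports rejections", {
  df <- rbind(baseRow(), baseRow(taxon = "Testum alter"),
              baseRow(taxon = "Testum tertius"))
  sp <- loadSpecies(speciesCSV(df))
  expect_length(sp, 3)
  expect_s4_class(sp[[1]], "SpeciesRecord")
  expect_equal(nrow(attr(sp, "rejected")), 0)

  # a min above its max is rejected with a diagnostic naming the field
  bad <- rbind(baseRow(), baseRow(taxon = "Badum sp", temp_min = 30,
                                  temp_max = 5))
  expect_warning(sp2 <- loadSpecies(speciesCSV(bad)), "rejected")
  expect_length(sp2, 1)
  rej <- attr(sp2, "rejected")
  expect_equal(rej$taxon, "Badum sp")
  expect_match(rej$message, "tempAbs")

  expect_error(loadSpecies(speciesCSV(baseRow()[, 1:5])), "lacks column")
})

test_that("an empty alt_min defaults to the -500 m floor", {
  sp <- loadSpecies(speciesCSV(baseRow(alt_min = NA)))
  expect_equal(sp[[1]]@altAbs[1], -500)
})

test_that("climate-zone harmonisation takes unions and flags unmapped", {
  expect_equal(harmonizeClimateZones(character(0)), character(0))
  map <- readKoppenGEZMap()
  # BSh maps to both a tropical and a subtropical shrub/steppe zone
  out <- harmonizeClimateZones("BSh", map)
  expect_true(all(c("TBSh", "SBSh") %in% out))
  expect_error(harmonizeClimateZones("XX"), "XX")

  # every GEZ present in the table is reachable from some Koeppen code
  reachable <- harmonizeClimateZones(unique(map$koppen), map)
  expect_setequal(reachable, unique(map$gez))
})

test_that("life forms map deterministically to grass/crop/tree", {
  expect_equal(classifyLifeForm("herbaceous"), "grass")
  expect_equal(classifyLifeForm("cereal"), "crop")
  expect_equal(classifyLifeForm("short rotation coppice"), "tree")
  expect_equal(classifyLifeForm("woody shrub"), "tree")
  expect_equal(classifyLifeForm("small shrub"), "grass")
  expect_error(classifyLifeForm("algae"), "unknown")
})

test_that("annual C input follows fractioning and partitioning", {
  # annual crop: stem 4 Mg DM at 45% C returned, roots 1 Mg at 45% C,
  # product removed -> aboveground 1.80, root 0.45, total 2.25
  s <- makeSpecies(lifecycle = "annual", lifetime = 1,
                   dm = c(product = 3, stem = 4, leaf = 0, root = 1),
                   c_pct = c(product = 45, stem = 45, leaf = 45,
                             root = 45),
                   ret = c(product = 0, stem = 1, leaf = 1, root = 1))
  ci <- annualCInput(s)
  expect_equal(ci$aboveground, 1.80)
  expect_equal(ci$root, 0.45)
  expect_equal(ci$annual, 2.25)

  # perennial: total root C 4.0 over a 20-year lifetime -> 0.20 per year
  s2 <- makeSpecies(lifecycle = "perennial", lifetime = 20,
                    dm = c(product = 0, stem = 0, leaf = 0, root = 10),
                    c_pct = c(product = 45, stem = 45, leaf = 45,
                              root = 40),
                    ret = c(product = 0, stem = 0, leaf = 0, root = 1))
  expect_equal(annualCInput(s2)$root, 0.20)

  # all return shares zero -> nothing enters the soil
  s3 <- makeSpecies(ret = c(product = 0, stem = 0, leaf = 0, root = 0))
  expect_equal(annualCInput(s3)$annual, 0)
})

test_that("deciduous leaves are returned yearly, evergreen spread", {
  dm <- c(product = 0, stem = 0, leaf = 6, root = 0)
  cc <- c(product = 45, stem = 45, leaf = 50, root = 40)
  rt <- c(product = 0, stem = 0, leaf = 1, root = 0)
  dec <- makeSpecies(lifecycle = "perennial", lifetime = 10, dm = dm,
                     c_pct = cc, ret = rt, deciduous = TRUE)
  eve <- makeSpecies(lifecycle = "perennial", lifetime = 10, dm = dm,
                     c_pct = cc, ret = rt, deciduous = FALSE)
  expect_equal(annualCInput(dec)$aboveground, 6 * 0.5)
  expect_equal(annualCInput(eve)$aboveground, 6 * 0.5 / 10)
})

test_that("C input is linear in dry matter and conserves over a rotation", {
  base <- makeSpecies()
  doubled <- makeSpecies(dm = 2 * base@dmFractions)
  expect_equal(annualCInput(doubled)$annual,
               2 * annualCInput(base)$annual)

  # annualised evergreen perennial input x lifetime = per-rotation total
  per <- makeSpecies(lifecycle = "perennial", lifetime = 7,
                     deciduous = FALSE)
  ci <- annualCInput(per)
  total_rotation <- sum(per@dmFractions * per@cContentPct / 100 *
                          per@soilReturn)
  expect_equal(ci$annual * 7, total_rotation)
})
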