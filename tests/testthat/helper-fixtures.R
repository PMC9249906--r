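# Shared in-code fixtures; everything is generated, nothing read from disk
# except the shipped configuration tables.

smallConfig <- function(nrow = 20, ncol = 20, ...) {
  syntheticWorldConfig(nrow = nrow, ncol = ncol, ...)
}

# memoise the default small world: several files exercise it read-only
.fixture_env <- new.env(parent = emptyenv())
smallWorld <- function(seed = 7) {
  key <- paste0("w", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- makeSyntheticWorld(smallConfig(), seed = seed)
  .fixture_env[[key]]
}

# a plain target area with well-behaved attributes
makeArea <- function(region = "1", gez = "TBSh", soc = 25, clay = 20,
                     ph = 6.5, texture = "medium", elev = 300,
                     temp = rep(20, 12), prec = rep(60, 12),
                     pet = rep(70, 12), soil_loss = 5, bd = 1.4,
                     depth = 30, area_ha = 1000, slope = 5) {
  new("TargetArea", regionId = region, gezId = gez, areaHa = area_ha,
      tempMonthly = temp, precMonthly = prec, petMonthly = pet,
      clayPct = clay, ph = ph, texture = texture, bulkDensity = bd,
      soilDepthCm = depth, elevationM = elev, slopePct = slope,
      soilLoss = soil_loss, socInit = soc)
}

# a species tolerant of makeArea()'s defaults
makeSpecies <- function(taxon = "Testum vulgare", life_form = "grass",
                        lifecycle = "perennial", lifetime = 5,
                        temp = c(0, 35), prec = c(100, 2000),
                        ph = c(4, 9), textures = c("coarse", "medium",
                                                   "fine"),
                        alt = c(-500, 4000), gez = c("TBSh", "SBSh",
                                                     "TeBSk"),
                        dm = c(product = 2, stem = 4, leaf = 2,
                               root = 1.5),
                        c_pct = c(product = 45, stem = 45, leaf = 42,
                                  root = 40),
                        ret = c(product = 0, stem = 1, leaf = 1,
                                root = 1),
                        deciduous = FALSE, cover_factor = 0.2,
                        cover_months = integer(0)) {
  speciesRecord(taxon, taxon, life_form, lifecycle, lifetime,
                temp_abs = temp, prec_abs = prec, ph_abs = ph,
                texture_ok = textures, alt_abs = alt, gez_ok = gez,
                dm = dm, c_pct = c_pct, soil_return = ret,
                deciduous = deciduous, cover_factor = cover_factor,
                cover_months = cover_months)
}

# random panels for the matching brute-force equivalence checks
randomArea <- function() {
  makeArea(region = as.character(sample(1:3, 1)),
           gez = sample(c("TBSh", "SBSh", "TeBSk"), 1),
           soc = runif(1, 5, 50), clay = runif(1, 0, 60),
           ph = runif(1, 4, 9),
           texture = sample(c("coarse", "medium", "fine"), 1),
           elev = runif(1, 0, 2000),
           temp = runif(12, -5, 30), prec = runif(12, 0, 200),
           pet = runif(12, 10, 150))
}

randomSpecies <- function(i) {
  lo <- function(a, b) sort(runif(2, a, b))
  makeSpecies(taxon = paste0("Randomus sp", i),
              temp = lo(-10, 35), prec = lo(0, 2500), ph = lo(3.5, 9.5),
              textures = sample(c("coarse", "medium", "fine"),
                                sample(1:3, 1)),
              alt = lo(-500, 3000),
              gez = sample(c("TBSh", "SBSh", "TeBSk"),
                           sample(1:3, 1)))
}

# scalar six-criterion evaluation, independent of isMatch()
bruteMatch <- function(s, a) {
  mat <- mean(a@tempMonthly)
  map <- sum(a@precMonthly)
  mat >= s@tempAbs[1] && mat <= s@tempAbs[2] &&
    map >= s@precAbs[1] && map <= s@precAbs[2] &&
    a@ph >= s@phAbs[1] && a@ph <= s@phAbs[2] &&
    a@texture %in% s@textureOk &&
    a@elevationM >= s@altAbs[1] && a@elevationM <= s@altAbs[2] &&
    a@gezId %in% s@gezOk
}
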