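#' Synthetic-world configuration
#'
#' Defaults describe the toy study conditions: a 100 x 100 geographic grid
#' at 0.05 degree cells spanning three world regions (vertical bands) and
#' three ecological zones (horizontal bands: tropical shrubland,
#' subtropical steppe, temperate steppe), with roughly 40% of cells bare
#' or sparsely vegetated, a planted set of cropland-abandonment
#' transitions, SOC stocks spanning the deficiency cutoff, and protected /
#' severe-problem-land exclusions.
#'
#' @param nrow,ncol grid size (`>= 4`).
#' @param xll,yll,cellsize geographic grid origin and cell size (degrees).
#' @param n_regions number of world-region bands (`>= 1`).
#' @param gez_codes GEZ codes (shipped table mnemonics) of the horizontal
#'   bands.
#' @param p_cover named probabilities of the land-cover roles at the later
#'   epoch (must sum to 1).
#' @param n_abandoned number of planted cropland-abandonment transitions.
#' @param soc_range uniform range of SOC stocks, Mg C ha-1.
#' @param p_protected,p_problem_severe cell probabilities of exclusions.
#' @param clay_range,ph_range,bd_range,slope_range,soil_loss_range uniform
#'   attribute ranges.
#' @param soil_depth_cm constant topsoil depth, cm.
#' @param elev_base,elev_noise per-region base elevations (recycled) and
#'   uniform jitter half-width, m.
#' @param climate per-GEZ named list of
#'   `list(t_mean, t_amp, p_mean, p_amp, pet_mean, pet_amp)`; defaults are
#'   generated for the chosen `gez_codes`.
#' @param climate_noise_sd standard deviation of seeded monthly climate
#'   noise (default 0 = smooth sinusoids).
#' @return Named configuration list.
#' @export
syntheticWorldConfig <- function(
    nrow = 100, ncol = 100, xll = 10, yll = 30, cellsize = 0.05,
    n_regions = 3, gez_codes = c("TBSh", "SBSh", "TeBSk"),
    p_cover = c(bare = 0.22, sparse = 0.16, cropland = 0.12,
                grassland = 0.18, shrubland = 0.08,
                herbaceous_mosaic = 0.06, mosaic_cropland = 0.06,
                other = 0.12),
    n_abandoned = 25,
    soc_range = c(2, 70),
    p_protected = 0.08, p_problem_severe = 0.10,
    clay_range = c(5, 45), ph_range = c(4.5, 8.8),
    bd_range = c(1.2, 1.6), slope_range = c(1, 12),
    soil_loss_range = c(1, 80), soil_depth_cm = 30,
    elev_base = c(200, 500, 900), elev_noise = 80,
    climate = NULL, climate_noise_sd = 0) {
  if (nrow < 4 || ncol < 4) stop("grid must be at least 4 x 4")
  if (n_regions < 1 || !length(gez_codes)) stop("need >= 1 region and GEZ")
  if (abs(sum(p_cover) - 1) > 1e-9) stop("p_cover must sum to 1")
  if (is.null(climate)) {
    climate <- local({
      presets <- list(
        TBSh = list(t_mean = 26, t_amp = 3, p_mean = 45, p_amp = 30,
                    pet_mean = 110, pet_amp = 25),
        SBSh = list(t_mean = 18, t_amp = 8, p_mean = 35, p_amp = 18,
                    pet_mean = 90, pet_amp = 35),
        TeBSk = list(t_mean = 8, t_amp = 13, p_mean = 38, p_amp = 14,
                     pet_mean = 55, pet_amp = 30)
      )
      out <- lapply(seq_along(gez_codes), function(i)
        presets[[gez_codes[i]]] %||%
          list(t_mean = 15, t_amp = 8, p_mean = 40, p_amp = 20,
               pet_mean = 80, pet_amp = 30))
      names(out) <- gez_codes
      out
    })
  }
  as.list(environment())
}

#' Sinusoidal monthly climate normals per zone
#'
#' Twelve-month temperature, precipitation and evapotranspiration normals
#' per ecological zone: `mean + amp * cos(2 pi (m - 7) / 12)` (July peak)
#' plus optional seeded Gaussian noise; precipitation and
#' evapotranspiration are floored at 0.
#'
#' @param config from [syntheticWorldConfig()].
#' @param seed optional integer; when given, seeds the generator (otherwise
#'   the current RNG stream is used).
#' @return Named list per GEZ code of `list(temp, prec, pet)` length-12
#'   vectors.
#' @export
makeClimate <- function(config = syntheticWorldConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- 1:12
  shape <- cos(2 * pi * (m - 7) / 12)
  out <- lapply(config$climate, function(cz) {
    noise <- function() if (config$climate_noise_sd > 0)
      stats::rnorm(12, 0, config$climate_noise_sd) else numeric(12)
    list(
      temp = cz$t_mean + cz$t_amp * shape + noise(),
      prec = pmax(0, cz$p_mean + cz$p_amp * shape + noise()),
      pet = pmax(0, cz$pet_mean + cz$pet_amp * shape + noise())
    )
  })
  names(out) <- names(config$climate)
  out
}

# representative ESA-CCI style codes per role (used when planting covers)
.roleCodes <- c(cropland = 10, mosaic_cropland = 30, grassland = 130,
                sparse = 150, bare = 200, shrubland = 120,
                herbaceous_mosaic = 110, other = 50)

#' Generate a deterministic synthetic world (fixtures)
#'
#' Pure function of `(config, seed)`: draws all rasters, climate and the
#' planted land-cover transitions from one seeded generator stream, then
#' derives the ground truth (marginal cells by provenance, consolidated
#' target-area attributes) by independent per-cell brute force, so the
#' pipeline can be verified against it exactly.
#'
#' @param config from [syntheticWorldConfig()].
#' @param seed integer seed.
#' @return List with elements `rasters` (named [RasterLayer-class]s:
#'   `lc_t0`, `lc_t1`, `soc`, `protected`, `problem`, `clay`, `ph`,
#'   `texture`, `bulk_density`, `soil_depth`, `elevation`, `slope`,
#'   `soil_loss`, `regions`, `gez`), `climate_zone` (per-GEZ normals),
#'   `climate` (lists of 12 monthly rasters for temp/prec/pet),
#'   `ground_truth`, `config`, `seed`.
#' @export
makeSyntheticWorld <- function(config = syntheticWorldConfig(), seed = 1) {
  set.seed(seed)
  nr <- config$nrow; nc <- config$ncol
  n <- nr * nc
  mkr <- function(v, kind = "continuous", nodata = -9999)
    rasterLayer(matrix(v, nr, nc), xll = config$xll, yll = config$yll,
                cellsize = config$cellsize, nodata = nodata, kind = kind)

  # zones: regions as vertical bands, GEZ as horizontal bands
  gezTab <- readGEZTable()
  gez_num <- gezTab$num[match(config$gez_codes, gezTab$code)]
  if (anyNA(gez_num)) stop("unknown GEZ code in config")
  region_m <- matrix(rep(ceiling(seq_len(nc) / (nc / config$n_regions)),
                         each = nr), nr, nc)
  region_m[region_m > config$n_regions] <- config$n_regions
  band <- ceiling(seq_len(nr) / (nr / length(gez_num)))
  band[band > length(gez_num)] <- length(gez_num)
  gez_m <- matrix(gez_num[band], nr, nc)

  # land cover at the later epoch, then plant abandonment transitions
  roles1 <- sample(names(config$p_cover), n, replace = TRUE,
                   prob = config$p_cover)
  lc1 <- matrix(.roleCodes[roles1], nr, nc)
  lc0 <- lc1
  eligible <- which(roles1 %in% c("grassland", "sparse", "bare",
                                  "mosaic_cropland", "herbaceous_mosaic",
                                  "shrubland"))
  n_ab <- min(config$n_abandoned, length(eligible))
  ab_idx <- if (n_ab > 0) sample(eligible, n_ab) else integer(0)
  lc0[ab_idx] <- .roleCodes[["cropland"]]

  soc <- matrix(stats::runif(n, config$soc_range[1], config$soc_range[2]),
                nr, nc)
  protected <- matrix(as.numeric(stats::runif(n) < config$p_protected),
                      nr, nc)
  sev <- defaultSeverityCodes()
  probTab <- readProblemLandTable()
  nonsev <- setdiff(probTab$code, sev)
  problem <- matrix(0, nr, nc)
  hit <- stats::runif(n) < config$p_problem_severe
  problem[hit] <- sample(sev, sum(hit), replace = TRUE)
  mild <- !hit & stats::runif(n) < 0.1
  problem[mild] <- sample(nonsev, sum(mild), replace = TRUE)

  clay <- matrix(stats::runif(n, config$clay_range[1],
                              config$clay_range[2]), nr, nc)
  ph <- matrix(stats::runif(n, config$ph_range[1], config$ph_range[2]),
               nr, nc)
  texture <- matrix(ifelse(clay < 18, 1, ifelse(clay < 35, 2, 3)), nr, nc)
  bd <- matrix(stats::runif(n, config$bd_range[1], config$bd_range[2]),
               nr, nc)
  depth <- matrix(config$soil_depth_cm, nr, nc)
  elev <- matrix(rep_len(config$elev_base,
                         config$n_regions)[region_m] +
                   stats::runif(n, -config$elev_noise, config$elev_noise),
                 nr, nc)
  slope <- matrix(stats::runif(n, config$slope_range[1],
                               config$slope_range[2]), nr, nc)
  soil_loss <- matrix(stats::runif(n, config$soil_loss_range[1],
                                   config$soil_loss_range[2]), nr, nc)

  climate_zone <- makeClimate(config, seed = NULL)
  # per-cell monthly rasters, value = the cell's zone normal
  zi <- match(gez_m, gez_num)  # 1..n_gez per cell
  mkclim <- function(var) lapply(1:12, function(m) {
    v <- vapply(seq_along(climate_zone), function(z)
      climate_zone[[z]][[var]][m], numeric(1))
    mkr(matrix(v[zi], nr, nc))
  })

  rasters <- list(
    lc_t0 = mkr(lc0, "categorical"), lc_t1 = mkr(lc1, "categorical"),
    soc = mkr(soc), protected = mkr(protected, "categorical"),
    problem = mkr(problem, "categorical"),
    clay = mkr(clay), ph = mkr(ph), texture = mkr(texture, "categorical"),
    bulk_density = mkr(bd), soil_depth = mkr(depth),
    elevation = mkr(elev), slope = mkr(slope), soil_loss = mkr(soil_loss),
    regions = mkr(region_m, "categorical"), gez = mkr(gez_m, "categorical")
  )
  climate <- list(temp = mkclim("temp"), prec = mkclim("prec"),
                  pet = mkclim("pet"))

  gt <- .bruteForceGroundTruth(config, lc0, lc1, soc, protected, problem,
                               clay, ph, texture, bd, depth, elev, slope,
                               soil_loss, region_m, gez_m, gez_num,
                               gezTab, sev, climate_zone)

  list(rasters = rasters, climate_zone = climate_zone, climate = climate,
       ground_truth = gt, config = config, seed = seed)
}

# Independent scalar derivation of the expected pipeline outputs: plain
# per-cell loops, no calls into the vectorised pipeline operations.
.bruteForceGroundTruth <- function(config, lc0, lc1, soc, protected,
                                   problem, clay, ph, texture, bd, depth,
                                   elev, slope, soil_loss, region_m, gez_m,
                                   gez_num, gezTab, sev, climate_zone) {
  legend <- readLandCoverLegend()
  nr <- nrow(lc1); nc <- ncol(lc1)
  counts <- c(bare = 0L, sparse = 0L, abandoned = 0L)
  acc <- new.env(parent = emptyenv())
  m_per_deg <- 111320
  abandon_targets <- c("mosaic_cropland", "grassland", "sparse", "bare",
                       "herbaceous_mosaic", "shrubland")

  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r1 <- legend[[as.character(lc1[i, j])]]
    r0 <- legend[[as.character(lc0[i, j])]]
    abandoned <- r0 == "cropland" && r1 %in% abandon_targets
    candidate <- r1 %in% c("bare", "sparse") || abandoned
    if (!candidate) next
    s <- soc[i, j]
    if (!(s > 0 && s <= 50)) next
    if (protected[i, j] != 0) next
    if (problem[i, j] %in% sev) next
    prov <- if (abandoned) "abandoned" else r1
    counts[prov] <- counts[prov] + 1L

    lat <- config$yll + (nr - i + 0.5) * config$cellsize
    a_ha <- (config$cellsize * m_per_deg)^2 * cos(lat * pi / 180) / 1e4
    key <- paste(region_m[i, j],
                 gezTab$code[match(gez_m[i, j], gezTab$num)], sep = "\r")
    rec <- if (is.null(acc[[key]])) {
      list(w = 0, soc = 0, clay = 0, ph = 0, bd = 0, depth = 0, elev = 0,
           slope = 0, loss = 0, tex = c(0, 0, 0))
    } else acc[[key]]
    rec$w <- rec$w + a_ha
    rec$soc <- rec$soc + s * a_ha
    rec$clay <- rec$clay + clay[i, j] * a_ha
    rec$ph <- rec$ph + ph[i, j] * a_ha
    rec$bd <- rec$bd + bd[i, j] * a_ha
    rec$depth <- rec$depth + depth[i, j] * a_ha
    rec$elev <- rec$elev + elev[i, j] * a_ha
    rec$slope <- rec$slope + slope[i, j] * a_ha
    rec$loss <- rec$loss + soil_loss[i, j] * a_ha
    rec$tex[texture[i, j]] <- rec$tex[texture[i, j]] + a_ha
    acc[[key]] <- rec
  }

  keys <- sort(ls(acc))
  tex_lab <- c("coarse", "medium", "fine")
  areas <- do.call(rbind, lapply(keys, function(k) {
    rec <- acc[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    best_tex <- which(rec$tex == max(rec$tex))[1]
    data.frame(
      region_id = parts[1], gez_id = parts[2], area_ha = rec$w,
      soc_init = rec$soc / rec$w, clay_pct = rec$clay / rec$w,
      ph = rec$ph / rec$w, texture = tex_lab[best_tex],
      bulk_density = rec$bd / rec$w, soil_depth_cm = rec$depth / rec$w,
      elevation_m = rec$elev / rec$w, slope_pct = rec$slope / rec$w,
      soil_loss = rec$loss / rec$w, stringsAsFactors = FALSE)
  }))
  list(
    marginal_cells = as.list(counts),
    marginal_total = sum(counts),
    n_target_areas = length(keys),
    areas = areas
  )
}

#' Engineered species panel with a known match matrix
#'
#' Builds a small panel of trait records whose tolerance windows are
#' placed relative to the synthetic world's consolidated target-area
#' attributes (with safety margins, so no criterion sits on a numerical
#' boundary), then derives the expected area-by-species match matrix by an
#' independent scalar re-evaluation of the six criteria.
#'
#' @param world from [makeSyntheticWorld()].
#' @param seed integer seed (reserved for future stochastic panels; the
#'   default panel is deterministic given the world).
#' @return `list(species = <list of SpeciesRecord>, expected_match =
#'   <logical matrix areas x species>, areas_key = <character>)`.
#' @export
makeSpeciesPanel <- function(world, seed = 1) {
  gt <- world$ground_truth$areas
  if (is.null(gt) || !nrow(gt)) stop("world has no target areas")
  set.seed(seed)
  czn <- world$climate_zone
  mat <- vapply(gt$gez_id, function(g) mean(czn[[g]]$temp), numeric(1))
  map <- vapply(gt$gez_id, function(g) sum(czn[[g]]$prec), numeric(1))
  gez_all <- unique(gt$gez_id)

  # a cut strictly between two attained attribute values (margin-safe)
  midcut <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1) u + 1 else (u[1] + u[2]) / 2
  }
  wide <- function(v, pad) c(min(v) - pad, max(v) + pad)

  base <- list(
    dm = c(product = 2, stem = 5, leaf = 2, root = 2),
    c_pct = c(product = 45, stem = 45, leaf = 42, root = 40),
    ret = c(product = 0, stem = 1, leaf = 1, root = 1)
  )
  sp <- list(
    speciesRecord("universal grass", "Panicum universale", "grass",
                  "perennial", lifetime_yr = 10,
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = base$dm, c_pct = base$c_pct,
                  soil_return = base$ret, cover_factor = 0.05),
    speciesRecord("warm-zone shrub", "Acacia calida", "tree",
                  "perennial", lifetime_yr = 20,
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100),
                  gez_ok = gez_all[1],
                  dm = c(product = 0, stem = 30, leaf = 8, root = 15),
                  c_pct = c(product = 48, stem = 48, leaf = 45,
                            root = 45),
                  soil_return = c(product = 0, stem = 0.3, leaf = 1,
                                  root = 1),
                  deciduous = TRUE, cover_factor = 0.15),
    speciesRecord("cool-tolerant crop", "Zea frigida", "crop", "annual",
                  temp_abs = c(min(mat) - 5, midcut(mat)),
                  prec_abs = wide(map, 100), ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = c(product = 6, stem = 4, leaf = 1, root = 1.5),
                  c_pct = base$c_pct,
                  soil_return = c(product = 0, stem = 1, leaf = 1,
                                  root = 1),
                  cover_factor = 0.35, cover_months = 4:10),
    speciesRecord("acid-intolerant herb", "Medicago basophila", "grass",
                  "perennial", lifetime_yr = 5,
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = c(midcut(gt$ph), max(gt$ph) + 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = base$dm, c_pct = base$c_pct,
                  soil_return = base$ret, cover_factor = 0.1),
    speciesRecord("fine-soil specialist", "Vertisola amans", "grass",
                  "perennial", lifetime_yr = 8,
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = base$dm, c_pct = base$c_pct,
                  soil_return = base$ret, cover_factor = 0.12),
    speciesRecord("lowland-only crop", "Oryza demissa", "crop", "annual",
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = c(min(gt$elevation_m) - 100,
                              midcut(gt$elevation_m)),
                  gez_ok = gez_all,
                  dm = c(product = 5, stem = 5, leaf = 1, root = 1),
                  c_pct = base$c_pct,
                  soil_return = c(product = 0, stem = 0.5, leaf = 1,
                                  root = 1),
                  cover_factor = 0.4, cover_months = 5:10),
    speciesRecord("no-residue bare crop", "Gossypium nudum", "crop",
                  "annual",
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = wide(gt$ph, 0.5),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = c(product = 2, stem = 1, leaf = 0.5, root = 0.3),
                  c_pct = base$c_pct,
                  soil_return = c(product = 0, stem = 0, leaf = 0,
                                  root = 0.2),
                  cover_factor = 0.9, cover_months = 6:8),
    speciesRecord("alkaline-desert reject", "Halophyton extremum",
                  "grass", "perennial", lifetime_yr = 3,
                  temp_abs = wide(mat, 5), prec_abs = wide(map, 100),
                  ph_abs = c(max(gt$ph) + 0.6, max(gt$ph) + 1.6),
                  texture_ok = c("coarse", "medium", "fine"),
                  alt_abs = wide(gt$elevation_m, 100), gez_ok = gez_all,
                  dm = base$dm, c_pct = base$c_pct,
                  soil_return = base$ret, cover_factor = 0.2)
  )

  # independent scalar expectation of the six matching criteria
  expected <- matrix(FALSE, nrow(gt), length(sp))
  for (ai in seq_len(nrow(gt))) for (si in seq_along(sp)) {
    s <- sp[[si]]
    expected[ai, si] <-
      mat[ai] >= s@tempAbs[1] && mat[ai] <= s@tempAbs[2] &&
      map[ai] >= s@precAbs[1] && map[ai] <= s@precAbs[2] &&
      gt$ph[ai] >= s@phAbs[1] && gt$ph[ai] <= s@phAbs[2] &&
      gt$texture[ai] %in% s@textureOk &&
      gt$elevation_m[ai] >= s@altAbs[1] &&
      gt$elevation_m[ai] <= s@altAbs[2] &&
      gt$gez_id[ai] %in% s@gezOk
  }
  rownames(expected) <- paste(gt$region_id, gt$gez_id, sep = "\r")
  colnames(expected) <- vapply(sp, function(s) s@taxon, character(1))
  list(species = sp, expected_match = expected,
       areas_key = rownames(expected))
}

#' Brute-force scenario expectation for a synthetic world
#'
#' Independent scalar re-derivation of the simulation stage: for every
#' expected match in the panel it initialises pools, steps the five-pool
#' turnover and the erosion bookkeeping with plain per-month arithmetic
#' (no calls into the pipeline's model functions), and derives the
#' expected net-positive count and best-case selection. Used to verify
#' the pipeline end to end.
#'
#' @param world from [makeSyntheticWorld()].
#' @param panel from [makeSpeciesPanel()].
#' @param horizon_years simulation horizon (default 80).
#' @param c_ref reference cover factor (default 0.5).
#' @return `list(results = <data.frame>, n_net_positive, best =
#'   <data.frame region_id/gez_id/taxon/net_soc>)`.
#' @export
bruteForceSimulate <- function(world, panel, horizon_years = 80,
                               c_ref = 0.5) {
  gt <- world$ground_truth$areas
  czn <- world$climate_zone
  rows <- list()
  for (ai in seq_len(nrow(gt))) for (si in seq_along(panel$species)) {
    if (!panel$expected_match[ai, si]) next
    s <- panel$species[[si]]
    a <- gt[ai, ]
    clim <- czn[[a$gez_id]]

    # annual C input, plain arithmetic
    dm <- s@dmFractions; cc <- s@cContentPct / 100; ret <- s@soilReturn
    life <- if (s@lifecycle == "perennial") s@lifetimeYr else 1
    above <- dm[["product"]] * cc[["product"]] * ret[["product"]] / life +
      dm[["stem"]] * cc[["stem"]] * ret[["stem"]] / life +
      dm[["leaf"]] * cc[["leaf"]] * ret[["leaf"]] /
        (if (s@deciduous) 1 else life)
    cin <- above + dm[["root"]] * cc[["root"]] * ret[["root"]] / life

    # pedotransfer initialisation
    soc0 <- a$soc_init; clay <- a$clay_pct
    iom <- 0.049 * soc0^1.139
    rpm <- (0.1847 * soc0 + 0.1555) * (clay + 1.2750)^-0.1158
    hum <- (0.7148 * soc0 + 0.5069) * (clay + 0.3421)^0.0184
    bio <- (0.0140 * soc0 + 0.0075) * (clay + 8.8473)^0.0567
    dpm <- soc0 - (iom + rpm + hum + bio)
    if (dpm < 0) {
      sc <- (soc0 - iom) / (rpm + hum + bio)
      rpm <- rpm * sc; hum <- hum * sc; bio <- bio * sc; dpm <- 0
    }

    x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))
    fco2 <- x / (x + 1); fbio <- 0.46 / (x + 1); fhum <- 0.54 / (x + 1)
    k <- c(10, 0.3, 0.66, 0.02)
    ratio <- if (s@lifeForm == "tree") 0.25 else 1.44
    cov <- rep(FALSE, 12)
    cov[if (length(s@coverMonths)) s@coverMonths else 1:12] <- TRUE
    um <- numeric(12); um[cov] <- cin / sum(cov)
    depth <- a$soil_depth_cm; bd <- a$bulk_density

    acc <- 0
    pools <- c(dpm, rpm, bio, hum)
    yearly <- numeric(horizon_years)
    for (y in seq_len(horizon_years)) {
      for (m in 1:12) {
        tM <- clim$temp[m]
        aT <- if (tM > -18.27)
          47.91 / (1 + exp(106.06 / (tM + 18.27))) else 0
        cap <- -(20 + 1.3 * clay - 0.01 * clay^2) * depth / 23
        if (!cov[m]) cap <- cap / 1.8
        acc <- min(max(acc + clim$prec[m] - clim$pet[m], cap), 0)
        bW <- if (abs(acc) < 0.444 * abs(cap)) 1 else
          0.2 + 0.8 * (abs(cap) - abs(acc)) / (0.556 * abs(cap))
        cM <- if (cov[m]) 0.6 else 1
        dec <- pools * (1 - exp(-aT * bW * cM * k / 12))
        pools <- pools - dec
        d <- sum(dec)
        pools[3] <- pools[3] + d * fbio
        pools[4] <- pools[4] + d * fhum
        pools[1] <- pools[1] + um[m] * ratio / (1 + ratio)
        pools[2] <- pools[2] + um[m] / (1 + ratio)
      }
      yearly[y] <- sum(pools) + iom
    }
    e_adj <- a$soil_loss * s@coverFactor / c_ref
    eroded <- sum(e_adj * yearly / (bd * depth * 100))
    final <- yearly[horizon_years]
    rows[[length(rows) + 1]] <- data.frame(
      region_id = a$region_id, gez_id = a$gez_id, taxon = s@taxon,
      soc_final = final, eroded_cum = eroded, net_soc = final - eroded,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  pos <- res[res$net_soc > 0, , drop = FALSE]
  best <- do.call(rbind, lapply(
    split(pos, paste(pos$region_id, pos$gez_id, sep = "\r")),
    function(g) {
      g <- g[g$net_soc == max(g$net_soc), , drop = FALSE]
      g[order(g$taxon), ][1, ]
    }))
  rownames(best) <- NULL
  list(results = res, n_net_positive = nrow(pos), best = best)
}

#' Write a synthetic world to disk
#'
#' Serialises every raster as an ESRI ASCII grid, the per-zone climate
#' normals as CSV, and the ground truth as JSON, exercising the same I/O
#' paths as real inputs.
#'
#' @param world from [makeSyntheticWorld()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(world$rasters))
    writeAsciiGrid(world$rasters[[nm]], file.path(dir,
                                                  paste0(nm, ".asc")))
  cz <- world$climate_zone
  clim <- do.call(rbind, lapply(names(cz), function(g) data.frame(
    gez_id = g, month = 1:12, temp = cz[[g]]$temp, prec = cz[[g]]$prec,
    pet = cz[[g]]$pet, stringsAsFactors = FALSE)))
  utils::write.csv(clim, file.path(dir, "climate_normals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(world$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
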