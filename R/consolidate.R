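#' Attach region and ecological-zone identities to marginal cells (step 2)
#'
#' Labels each retained cell with its `(region_id, gez_id)` pair. Cells
#' falling on missing region or GEZ codes are dropped from the labelled
#' mask with a logged count. Water and polar GEZ codes are excluded by
#' default.
#'
#' @param mask a [MarginalLandMask-class].
#' @param regions,gez categorical [RasterLayer-class]s of zone codes,
#'   aligned to the mask grid.
#' @param exclude_gez GEZ codes to drop (default: water and polar).
#' @return `list(region = <matrix>, gez = <matrix>, mask = <logical matrix>,
#'   dropped = <int>)` where `mask` is the retained mask after drops and the
#'   code matrices are `NA` off-mask.
#' @export
assignZones <- function(mask, regions, gez, exclude_gez = c("WA", "P")) {
  stopifnot(is(mask, "MarginalLandMask"),
            is(regions, "RasterLayer"), is(gez, "RasterLayer"))
  m <- mask@mask
  if (!identical(dim(m), dim(regions@values)) ||
      !identical(dim(m), dim(gez@values)))
    stop("zone layers must be aligned to the mask grid")
  r <- regions@values
  g <- gez@values
  gchr <- .gezAsCode(g)
  ok <- m & !is.na(r) & !is.na(gchr) & !(gchr %in% exclude_gez)
  dropped <- sum(m & !ok)
  if (dropped)
    message(dropped, " marginal cell(s) dropped (missing/excluded zone)")
  r[!ok] <- NA
  gchr[!ok] <- NA
  list(region = r, gez = gchr, mask = ok, dropped = dropped)
}

# GEZ rasters are coded numerically; translate through the shipped GEZ code
# table so downstream records carry the mnemonic code (e.g. "TBSh").
.gezAsCode <- function(g) {
  tab <- readGEZTable()
  out <- matrix(NA_character_, nrow(g), ncol(g))
  ok <- !is.na(g)
  idx <- match(g[ok], tab$num)
  out[ok] <- tab$code[idx]
  out
}

#' Global ecological zone code table
#'
#' The 19 GEZ classes plus water, with the numeric raster coding used by
#' the package. Shipped as editable CSV (`gez_classes.csv`).
#'
#' @param path CSV with columns `num`, `code`, `label`.
#' @return data.frame.
#' @export
readGEZTable <- function(path = system.file("extdata", "gez_classes.csv",
                                            package = "marginalSOC")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.taNumSlots <- c(clayPct = "clay", ph = "ph", bulkDensity = "bulk_density",
                 soilDepthCm = "soil_depth", elevationM = "elevation",
                 slopePct = "slope", soilLoss = "soil_loss")

#' Consolidate labelled cells into target areas (step 2)
#'
#' Builds one [TargetArea-class] per occupied `(region_id, gez_id)` pair.
#' Continuous attributes and monthly climate normals are area-weighted
#' means over the zone's retained cells; texture is the area-weighted modal
#' class; `area_ha` is the sum of cell areas. A zone whose attribute is
#' missing on every cell gets `NA` for that attribute and is flagged
#' unusable for matching (see [isUsable()]).
#'
#' @param mask a [MarginalLandMask-class].
#' @param zones result of [assignZones()].
#' @param soc SOC stock raster (initial SOC source).
#' @param soil named list of rasters: `clay` (%), `ph`, `texture` (coded
#'   1=coarse, 2=medium, 3=fine), `bulk_density` (Mg m-3), `soil_depth`
#'   (cm).
#' @param terrain named list: `elevation` (m), `slope` (%).
#' @param soil_loss raster, Mg soil ha-1 yr-1.
#' @param climate list with elements `temp`, `prec`, `pet`, each a list of
#'   12 monthly rasters.
#' @param min_area_ha zones smaller than this are dropped (default 0).
#' @return List of [TargetArea-class] objects, ordered by region then GEZ.
#' @export
consolidateTargetAreas <- function(mask, zones, soc, soil, terrain,
                                   soil_loss, climate, min_area_ha = 0) {
  stopifnot(is(mask, "MarginalLandMask"))
  on <- zones$mask
  if (!any(on)) stop("no retained cells to consolidate")
  area <- cellAreaHa(mask@grid)

  idx <- which(on)
  key <- paste(zones$region[idx], zones$gez[idx], sep = "\r")
  w <- area[idx]

  wmean <- function(vals) {
    v <- vals[idx]
    vapply(split(seq_along(v), key), function(ix) {
      ok <- !is.na(v[ix])
      if (!any(ok)) return(NA_real_)
      sum(v[ix][ok] * w[ix][ok]) / sum(w[ix][ok])
    }, numeric(1))
  }
  wmode <- function(vals) {
    v <- vals[idx]
    vapply(split(seq_along(v), key), function(ix) {
      ok <- !is.na(v[ix])
      if (!any(ok)) return(NA_real_)
      ww <- tapply(w[ix][ok], v[ix][ok], sum)
      min(as.numeric(names(ww)[ww == max(ww)]))
    }, numeric(1))
  }

  keys <- sort(unique(key))
  areas_ha <- vapply(split(seq_along(idx), key), function(ix) sum(w[ix]),
                     numeric(1))

  src <- c(soil, terrain, list(soil_loss = soil_loss))
  vals <- list(soc = wmean(soc@values))
  for (nm in names(.taNumSlots)) {
    layer <- src[[.taNumSlots[[nm]]]]
    if (is.null(layer)) stop("missing attribute layer: ", .taNumSlots[[nm]])
    vals[[nm]] <- wmean(layer@values)
  }
  tex_num <- wmode(soil$texture@values)
  clim <- list()
  for (v in c("temp", "prec", "pet"))
    clim[[v]] <- vapply(climate[[v]], function(r) wmean(r@values),
                        numeric(length(keys)))

  tex_lab <- c("coarse", "medium", "fine")
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (areas_ha[[k]] < min_area_ha) next
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cm <- if (length(keys) == 1)
      list(temp = clim$temp, prec = clim$prec, pet = clim$pet)
    else
      list(temp = clim$temp[i, ], prec = clim$prec[i, ],
           pet = clim$pet[i, ])
    out[[i]] <- new("TargetArea",
      regionId = parts[1], gezId = parts[2], areaHa = areas_ha[[k]],
      tempMonthly = as.numeric(cm$temp), precMonthly = as.numeric(cm$prec),
      petMonthly = as.numeric(cm$pet),
      clayPct = vals$clayPct[[k]], ph = vals$ph[[k]],
      texture = if (is.na(tex_num[[k]])) NA_character_
                else tex_lab[tex_num[[k]]],
      bulkDensity = vals$bulkDensity[[k]],
      soilDepthCm = vals$soilDepthCm[[k]],
      elevationM = vals$elevationM[[k]], slopePct = vals$slopePct[[k]],
      soilLoss = vals$soilLoss[[k]], socInit = vals$soc[[k]])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Target areas as a data.frame
#'
#' One row per area; monthly climate vectors become 12 suffixed columns
#' (`temp_01`..`temp_12`, etc.). The inverse of the CSV interface.
#'
#' @param areas list of [TargetArea-class].
#' @return data.frame.
#' @export
targetAreasToDataFrame <- function(areas) {
  rows <- lapply(areas, function(a) {
    base <- data.frame(
      region_id = a@regionId, gez_id = a@gezId, area_ha = a@areaHa,
      clay_pct = a@clayPct, ph = a@ph, texture = a@texture,
      bulk_density = a@bulkDensity, soil_depth_cm = a@soilDepthCm,
      elevation_m = a@elevationM, slope_pct = a@slopePct,
      soil_loss = a@soilLoss, soc_init = a@socInit,
      stringsAsFactors = FALSE)
    for (v in c("temp", "prec", "pet")) {
      m <- slot(a, paste0(v, "Monthly"))
      for (j in 1:12) base[[sprintf("%s_%02d", v, j)]] <- m[j]
    }
    base
  })
  do.call(rbind, rows)
}

#' @rdname targetAreasToDataFrame
#' @param df data.frame in the [targetAreasToDataFrame()] layout.
#' @export
dataFrameToTargetAreas <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    mv <- function(v) as.numeric(r[sprintf("%s_%02d", v, 1:12)])
    new("TargetArea",
        regionId = as.character(r$region_id),
        gezId = as.character(r$gez_id), areaHa = r$area_ha,
        tempMonthly = mv("temp"), precMonthly = mv("prec"),
        petMonthly = mv("pet"), clayPct = r$clay_pct, ph = r$ph,
        texture = as.character(r$texture), bulkDensity = r$bulk_density,
        soilDepthCm = r$soil_depth_cm, elevationM = r$elevation_m,
        slopePct = r$slope_pct, soilLoss = r$soil_loss,
        socInit = r$soc_init)
  })
}

#' Summarise target areas (step 2 reporting)
#'
#' @param areas list of [TargetArea-class].
#' @param reference_mha optional reference area (Mha) to express the grand
#'   total as a percentage of (e.g. the SOC-deficient marginal-land total).
#' @return `list(total_mha, by_region, by_gez, pct_of_reference)`;
#'   per-region and per-GEZ tables carry Mha and percent of the total.
#' @export
summarizeAreas <- function(areas, reference_mha = NULL) {
  if (!length(areas)) stop("no target areas to summarise")
  df <- data.frame(
    region = vapply(areas, function(a) a@regionId, character(1)),
    gez = vapply(areas, function(a) a@gezId, character(1)),
    mha = vapply(areas, function(a) a@areaHa, numeric(1)) / 1e6)
  total <- sum(df$mha)
  byr <- aggregate(mha ~ region, df, sum)
  byr$pct <- 100 * byr$mha / total
  byg <- aggregate(mha ~ gez, df, sum)
  byg$pct <- 100 * byg$mha / total
  list(
    total_mha = total,
    by_region = byr,
    by_gez = byg,
    pct_of_reference = if (is.null(reference_mha)) NA_real_
                       else 100 * total / reference_mha
  )
}
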