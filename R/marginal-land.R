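.lcRoles <- c("cropland", "mosaic_cropland", "grassland", "sparse", "bare",
              "shrubland", "herbaceous_mosaic", "other")

# land-cover roles that qualify a cropland pixel as abandoned at t1
.abandonTargets <- c("mosaic_cropland", "grassland", "sparse", "bare",
                     "herbaceous_mosaic", "shrubland")

#' Read a land-cover legend
#'
#' Maps raster category codes to functional roles used by the marginal-land
#' filters. The shipped default (`system.file("extdata",
#' "landcover_legend.csv", package = "marginalSOC")`) follows the ESA-CCI
#' 22-class coding; the mapping is configuration, so regional codings can be
#' supplied instead.
#'
#' @param path CSV with columns `code`, `role`, `label`; `role` must be one
#'   of cropland, mosaic_cropland, grassland, sparse, bare, shrubland,
#'   herbaceous_mosaic, other. Defaults to the shipped ESA-CCI legend.
#' @return Named character vector: names are codes, values are roles.
#' @export
readLandCoverLegend <- function(path = system.file("extdata",
                                                   "landcover_legend.csv",
                                                   package = "marginalSOC")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "role") %in% names(df)))
    stop("legend must have columns 'code' and 'role'")
  if (anyDuplicated(df$code))
    stop("legend maps a code more than once: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  bad <- setdiff(unique(df$role), .lcRoles)
  if (length(bad)) stop("unknown legend role(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$role, df$code)
}

.rolesOf <- function(lc, legend) {
  codes <- lc@values
  u <- unique(codes[!is.na(codes)])
  missing <- setdiff(u, as.numeric(names(legend)))
  if (length(missing))
    stop("land-cover code(s) not in legend: ",
         paste(sort(missing), collapse = ", "))
  role <- matrix(NA_character_, nrow(codes), ncol(codes))
  ok <- !is.na(codes)
  role[ok] <- legend[as.character(codes[ok])]
  role
}

#' Select bare and sparsely vegetated land (step 1.1)
#'
#' Retains cells whose land-cover role is `bare` or `sparse` (vegetation
#' cover below 15%); all other covers are excluded as actually or
#' potentially productive, ecologically valuable, or unusable.
#'
#' @param lc categorical [RasterLayer-class] of land-cover codes.
#' @param legend named role map from [readLandCoverLegend()].
#' @return `list(mask = <logical matrix>, provenance = <character matrix>)`,
#'   provenance `"bare"`/`"sparse"` where selected, `NA` elsewhere.
#' @export
selectCandidateCover <- function(lc, legend = readLandCoverLegend()) {
  stopifnot(is(lc, "RasterLayer"))
  if (lc@kind != "categorical") stop("land cover must be categorical")
  role <- .rolesOf(lc, legend)
  mask <- !is.na(role) & role %in% c("bare", "sparse")
  prov <- matrix(NA_character_, nrow(role), ncol(role))
  prov[mask] <- role[mask]
  list(mask = mask, provenance = prov)
}

#' Detect cropland abandonment between two epochs (step 1.2)
#'
#' A cell is flagged abandoned when it was cropland at `t0` and transitions
#' to mosaic cropland/natural vegetation, grassland, sparse vegetation,
#' bare area, mosaic herbaceous cover or shrubland at `t1`.
#'
#' @param lc_t0,lc_t1 categorical [RasterLayer-class] for the earlier and
#'   later epoch, on one grid and legend.
#' @param legend named role map.
#' @return Logical matrix.
#' @export
detectAbandonment <- function(lc_t0, lc_t1,
                              legend = readLandCoverLegend()) {
  stopifnot(is(lc_t0, "RasterLayer"), is(lc_t1, "RasterLayer"))
  if (!.sameGrid(lc_t0, lc_t1)) stop("epochs must share a grid")
  r0 <- .rolesOf(lc_t0, legend)
  r1 <- .rolesOf(lc_t1, legend)
  !is.na(r0) & !is.na(r1) & r0 == "cropland" & r1 %in% .abandonTargets
}

#' Filter to SOC-deficient cells and bin SOC classes (step 1.3)
#'
#' Retains masked cells with `0 < SOC <= threshold` and assigns the
#' 10 Mg C ha-1 class `ceiling(SOC / 10)` with bins (0,10] .. (40,50].
#' SOC of exactly `threshold` is retained (upper bound inclusive); SOC of 0
#' is treated as no-soil and excluded. Negative values are reported via a
#' warning and the cells dropped.
#'
#' @param mask logical matrix of candidate cells.
#' @param soc continuous [RasterLayer-class], Mg C ha-1 to 30 cm.
#' @param threshold deficiency cutoff, Mg C ha-1 (default 50).
#' @return `list(mask = <logical matrix>, soc_class = <integer matrix>)`.
#' @export
filterSOC <- function(mask, soc, threshold = 50) {
  stopifnot(is(soc, "RasterLayer"), is.logical(mask))
  if (!identical(dim(mask), dim(soc@values)))
    stop("mask and SOC grid dimensions differ")
  v <- soc@values
  neg <- mask & !is.na(v) & v < 0
  if (any(neg))
    warning(sum(neg), " cell(s) with negative SOC dropped")
  keep <- mask & !is.na(v) & v > 0 & v <= threshold
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[keep] <- as.integer(ceiling(v[keep] / 10))
  list(mask = keep, soc_class = cls)
}

#' Exclude protected areas (step 1.4)
#'
#' @param mask logical matrix.
#' @param protected [RasterLayer-class]; non-zero/non-missing = protected.
#' @return Logical matrix with protected cells removed.
#' @export
excludeProtected <- function(mask, protected) {
  stopifnot(is(protected, "RasterLayer"), is.logical(mask))
  if (!identical(dim(mask), dim(protected@values)))
    stop("mask and protected grid dimensions differ")
  p <- protected@values
  mask & !(!is.na(p) & p != 0)
}

#' Exclude problem land (step 1.5)
#'
#' Removes cells whose problem-land code carries a (sub-)severe soil or
#' terrain restriction that would exceed plant tolerances (e.g. too cold,
#' too dry, steep > 30% slope, shallow, poorly drained, saline/sodic, acid
#' sulphate, peats). The severity set is configuration; the shipped default
#' table (`problem_land.csv`) marks these typologies severe.
#'
#' @param mask logical matrix.
#' @param problem categorical [RasterLayer-class] of problem-land codes.
#' @param severity_codes numeric codes to exclude; defaults to codes marked
#'   `severe` in the shipped table.
#' @return Logical matrix.
#' @export
excludeProblemLand <- function(mask, problem,
                               severity_codes = defaultSeverityCodes()) {
  stopifnot(is(problem, "RasterLayer"), is.logical(mask))
  if (!identical(dim(mask), dim(problem@values)))
    stop("mask and problem grid dimensions differ")
  p <- problem@values
  known <- c(0, readProblemLandTable()$code)
  u <- unique(p[!is.na(p)])
  bad <- setdiff(u, union(known, severity_codes))
  if (length(bad))
    stop("unmapped problem-land code(s): ", paste(sort(bad), collapse = ", "))
  mask & !(!is.na(p) & p %in% severity_codes)
}

#' @rdname excludeProblemLand
#' @param path CSV with columns `code`, `typology`, `severity`
#'   (`severe`/`moderate`/`none`).
#' @export
readProblemLandTable <- function(path = system.file("extdata",
                                                    "problem_land.csv",
                                                    package = "marginalSOC")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname excludeProblemLand
#' @export
defaultSeverityCodes <- function() {
  tab <- readProblemLandTable()
  tab$code[tab$severity == "severe"]
}

#' Identify marginal land (steps 1.1-1.5)
#'
#' Composes the five filters: (candidate covers from the later epoch OR
#' abandoned cropland) AND SOC-deficient AND not protected AND not severe
#' problem land. Provenance precedence for cells satisfying both 1.1 and
#' 1.2 is abandoned > sparse > bare.
#'
#' @param lc_t0,lc_t1 land-cover rasters for the two epochs (aligned).
#' @param soc SOC stock raster, Mg C ha-1.
#' @param protected protected-area mask raster.
#' @param problem problem-land raster.
#' @param legend land-cover legend.
#' @param severity_codes problem codes to exclude.
#' @param soc_threshold SOC deficiency cutoff, Mg C ha-1.
#' @return `list(mask = <`[MarginalLandMask-class]`>, composition =
#'   <data.frame provenance/cells/area_ha/share_pct>)`; shares are percent
#'   of the retained area and sum to 100 when any cell is retained.
#' @export
identifyMarginalLand <- function(lc_t0, lc_t1, soc, protected, problem,
                                 legend = readLandCoverLegend(),
                                 severity_codes = defaultSeverityCodes(),
                                 soc_threshold = 50) {
  for (l in list(lc_t1, soc, protected, problem))
    if (!.sameGrid(lc_t0, l)) stop("all layers must be aligned to one grid")

  cand <- selectCandidateCover(lc_t1, legend)
  aband <- detectAbandonment(lc_t0, lc_t1, legend)

  mask <- cand$mask | aband
  prov <- cand$provenance
  prov[aband] <- "abandoned"          # precedence: abandoned > sparse > bare

  f <- filterSOC(mask, soc, soc_threshold)
  mask <- f$mask
  mask <- excludeProtected(mask, protected)
  mask <- excludeProblemLand(mask, problem, severity_codes)

  prov[!mask] <- NA_character_
  cls <- f$soc_class
  cls[!mask] <- NA_integer_

  mm <- new("MarginalLandMask", mask = mask, provenance = prov,
            socClass = cls, grid = lc_t1)

  area <- cellAreaHa(lc_t1)
  lev <- c("bare", "sparse", "abandoned")
  cells <- vapply(lev, function(p) sum(prov == p, na.rm = TRUE), integer(1))
  ha <- vapply(lev, function(p) sum(area[!is.na(prov) & prov == p]),
               numeric(1))
  total <- sum(ha)
  comp <- data.frame(
    provenance = lev, cells = cells, area_ha = ha,
    share_pct = if (total > 0) 100 * ha / total else rep(NA_real_, 3),
    row.names = NULL
  )
  list(mask = mm, composition = comp)
}
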