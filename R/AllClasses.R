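#' @import methods
NULL

#' Gridded raster layer
#'
#' Minimal in-memory container for a regular, north-up, single-band grid.
#' Values are stored as a numeric matrix with missing cells as `NA`; the
#' original nodata sentinel is kept only for (de)serialisation. Row 1 is the
#' northernmost row and coordinates refer to cell centers.
#'
#' @slot values numeric matrix of cell values (`NA` = missing).
#' @slot xll,yll numeric, coordinates of the lower-left corner of the grid.
#' @slot cellsize numeric, cell edge length (degrees for geographic CRS,
#'   meters otherwise).
#' @slot crs character CRS identifier (e.g. `"EPSG:4326"`).
#' @slot nodata numeric sentinel used when the grid is written to disk.
#' @slot kind `"continuous"` or `"categorical"`.
#'
#' @aliases RasterLayer-class
#' @exportClass RasterLayer
setClass("RasterLayer",
  representation(
    values = "matrix",
    xll = "numeric",
    yll = "numeric",
    cellsize = "numeric",
    crs = "character",
    nodata = "numeric",
    kind = "character"
  ),
  prototype(
    xll = 0, yll = 0, cellsize = 1,
    crs = "EPSG:4326", nodata = -9999, kind = "continuous"
  )
)

setValidity("RasterLayer", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (is.null(d) || any(d <= 0))
    msg <- c(msg, "grid dimensions must be positive")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (length(object@cellsize) != 1 || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be a single positive number")
  if (!object@kind %in% c("continuous", "categorical"))
    msg <- c(msg, "kind must be 'continuous' or 'categorical'")
  if (length(object@nodata) != 1 || !is.finite(object@nodata))
    msg <- c(msg, "nodata must be a single finite number")
  if (object@kind == "categorical" &&
      any(object@values == object@nodata, na.rm = TRUE))
    msg <- c(msg, "nodata sentinel collides with a valid category code")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterLayer
#'
#' @param values numeric matrix; cells equal to `nodata` are converted to
#'   `NA` on construction.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize cell edge length.
#' @param crs CRS identifier string.
#' @param nodata nodata sentinel for serialisation.
#' @param kind `"continuous"` or `"categorical"`.
#' @return A [RasterLayer-class] object.
#' @examples
#' r <- rasterLayer(matrix(1:4, 2), cellsize = 0.5)
#' dim(r)
#' @export
rasterLayer <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = "EPSG:4326", nodata = -9999,
                        kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[values == nodata] <- NA_real_
  new("RasterLayer", values = values, xll = xll, yll = yll,
      cellsize = cellsize, crs = crs, nodata = nodata, kind = kind)
}

#' Consolidated marginal-land mask
#'
#' Boolean grid of retained marginal cells with per-cell provenance
#' (`"bare"`, `"sparse"` or `"abandoned"`) and an SOC-deficiency class
#' (1..5, 10 Mg C ha-1 bins over (0, 50]). Provenance and class are defined
#' exactly where the mask is `TRUE`.
#'
#' @slot mask logical matrix.
#' @slot provenance character matrix (`NA` off-mask).
#' @slot socClass integer matrix (`NA` off-mask).
#' @slot grid the [RasterLayer-class] the mask is registered to (values
#'   unused; geometry only).
#'
#' @aliases MarginalLandMask-class
#' @exportClass MarginalLandMask
setClass("MarginalLandMask",
  representation(
    mask = "matrix",
    provenance = "matrix",
    socClass = "matrix",
    grid = "RasterLayer"
  )
)

setValidity("MarginalLandMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@mask), dim(object@provenance)) ||
      !identical(dim(object@mask), dim(object@socClass)))
    msg <- c(msg, "mask, provenance and socClass must share dimensions")
  on <- object@mask & !is.na(object@mask)
  if (any(is.na(object@provenance[on])))
    msg <- c(msg, "provenance must be defined on every retained cell")
  if (any(!is.na(object@provenance[!on])))
    msg <- c(msg, "provenance must be undefined off-mask")
  if (any(is.na(object@socClass[on])))
    msg <- c(msg, "socClass must be defined on every retained cell")
  if (any(!is.na(object@socClass[!on])))
    msg <- c(msg, "socClass must be undefined off-mask")
  prov <- object@provenance[on]
  if (length(prov) && !all(prov %in% c("bare", "sparse", "abandoned")))
    msg <- c(msg, "provenance codes must be bare/sparse/abandoned")
  cls <- object@socClass[on]
  if (length(cls) && !all(cls %in% 1:5))
    msg <- c(msg, "socClass must be in 1..5")
  if (length(msg)) msg else TRUE
})

#' Consolidated target area
#'
#' One world-region by global-ecological-zone (GEZ) unit of marginal land,
#' characterised by area-weighted pedoclimatic and terrain attributes.
#' Monthly climate normals are stored as length-12 vectors (Jan..Dec).
#' A missing (all-`NA`-source) attribute is stored as `NA`; such an area is
#' flagged unusable for matching (see [isUsable()]).
#'
#' @slot regionId,gezId character zone codes.
#' @slot areaHa numeric, hectares.
#' @slot tempMonthly,precMonthly,petMonthly numeric length-12 normals
#'   (deg C, mm, mm).
#' @slot clayPct,ph,bulkDensity,soilDepthCm,elevationM,slopePct,soilLoss,socInit
#'   numeric scalars (units: %, -, Mg m-3, cm, m, %, Mg soil ha-1 yr-1,
#'   Mg C ha-1).
#' @slot texture character, one of `"coarse"`, `"medium"`, `"fine"` (modal).
#'
#' @aliases TargetArea-class
#' @exportClass TargetArea
setClass("TargetArea",
  representation(
    regionId = "character", gezId = "character", areaHa = "numeric",
    tempMonthly = "numeric", precMonthly = "numeric", petMonthly = "numeric",
    clayPct = "numeric", ph = "numeric", texture = "character",
    bulkDensity = "numeric", soilDepthCm = "numeric",
    elevationM = "numeric", slopePct = "numeric",
    soilLoss = "numeric", socInit = "numeric"
  )
)

setValidity("TargetArea", function(object) {
  msg <- character()
  if (length(object@areaHa) != 1 || is.na(object@areaHa) ||
      object@areaHa <= 0)
    msg <- c(msg, "areaHa must be a single positive number")
  for (s in c("tempMonthly", "precMonthly", "petMonthly"))
    if (length(slot(object, s)) != 12)
      msg <- c(msg, paste(s, "must have 12 entries"))
  if (!is.na(object@clayPct) &&
      (object@clayPct < 0 || object@clayPct > 100))
    msg <- c(msg, "clayPct must be in [0, 100]")
  if (!is.na(object@texture) &&
      !object@texture %in% c("coarse", "medium", "fine"))
    msg <- c(msg, "texture must be coarse/medium/fine")
  if (!is.na(object@socInit) && object@socInit <= 0)
    msg <- c(msg, "socInit must be positive")
  if (length(msg)) msg else TRUE
})

#' Plant species trait record
#'
#' Pedoclimatic tolerance ranges (ECOCROP-style absolute bounds), life form
#' and lifecycle, dry-matter fractions with carbon contents and soil-return
#' shares for the carbon-input computation, and the RUSLE cover-management
#' factor for the erosion coupling.
#'
#' @slot name common name.
#' @slot taxon species/subspecies label (unique key).
#' @slot lifeForm `"grass"`, `"crop"` or `"tree"`.
#' @slot lifecycle `"annual"` or `"perennial"`.
#' @slot lifetimeYr rotation length, years (1 for annuals).
#' @slot tempAbs,precAbs,phAbs,altAbs numeric `[min, max]` tolerance ranges
#'   (deg C mean annual; mm yr-1; pH; m).
#' @slot textureOk subset of `c("coarse","medium","fine")`.
#' @slot gezOk character set of compatible GEZ codes.
#' @slot yieldDm product yield, Mg DM ha-1 yr-1 (bookkeeping only).
#' @slot dmFractions named numeric (`product`,`stem`,`leaf`,`root`) dry
#'   matter, Mg DM ha-1 (per year for annuals, per rotation for perennials;
#'   deciduous leaf mass is per year).
#' @slot cContentPct named numeric, % carbon per fraction.
#' @slot soilReturn named numeric in `[0,1]`, share of each fraction left in
#'   the field.
#' @slot deciduous logical (perennials: leaves shed and returned yearly).
#' @slot coverFactor RUSLE cover-management C factor in (0, 1].
#' @slot coverMonths integer months (1..12) with the soil covered by the
#'   crop/canopy.
#'
#' @aliases SpeciesRecord-class
#' @exportClass SpeciesRecord
setClass("SpeciesRecord",
  representation(
    name = "character", taxon = "character",
    lifeForm = "character", lifecycle = "character", lifetimeYr = "numeric",
    tempAbs = "numeric", precAbs = "numeric", phAbs = "numeric",
    textureOk = "character", altAbs = "numeric", gezOk = "character",
    yieldDm = "numeric", dmFractions = "numeric", cContentPct = "numeric",
    soilReturn = "numeric", deciduous = "logical",
    coverFactor = "numeric", coverMonths = "integer"
  )
)

.fractions <- c("product", "stem", "leaf", "root")

setValidity("SpeciesRecord", function(object) {
  msg <- character()
  if (!object@lifeForm %in% c("grass", "crop", "tree"))
    msg <- c(msg, "lifeForm must be grass/crop/tree")
  if (!object@lifecycle %in% c("annual", "perennial"))
    msg <- c(msg, "lifecycle must be annual/perennial")
  if (object@lifetimeYr < 1) msg <- c(msg, "lifetimeYr must be >= 1")
  for (s in c("tempAbs", "precAbs", "phAbs", "altAbs")) {
    r <- slot(object, s)
    if (length(r) != 2) msg <- c(msg, paste(s, "must be [min, max]"))
    else if (!any(is.na(r)) && r[1] > r[2])
      msg <- c(msg, paste(s, "min exceeds max"))
  }
  if (!length(object@gezOk)) msg <- c(msg, "gezOk must be non-empty")
  if (!all(object@textureOk %in% c("coarse", "medium", "fine")))
    msg <- c(msg, "textureOk entries must be coarse/medium/fine")
  for (s in c("dmFractions", "cContentPct", "soilReturn")) {
    v <- slot(object, s)
    if (!all(.fractions %in% names(v)))
      msg <- c(msg, paste(s, "must name product/stem/leaf/root"))
    else if (any(v[.fractions] < 0, na.rm = TRUE))
      msg <- c(msg, paste(s, "must be non-negative"))
  }
  if (all(.fractions %in% names(object@soilReturn)) &&
      any(object@soilReturn[.fractions] > 1, na.rm = TRUE))
    msg <- c(msg, "soilReturn shares must be in [0, 1]")
  if (length(object@coverFactor) != 1 || is.na(object@coverFactor) ||
      object@coverFactor <= 0 || object@coverFactor > 1)
    msg <- c(msg, "coverFactor must be in (0, 1]")
  if (length(object@coverMonths) &&
      !all(object@coverMonths %in% 1:12))
    msg <- c(msg, "coverMonths must be in 1..12")
  if (length(msg)) msg else TRUE
})

#' Five-pool RothC state
#'
#' Carbon pools in Mg C ha-1 (decomposable plant material, resistant plant
#' material, microbial biomass, humified organic matter, inert organic
#' matter) plus the accumulated topsoil moisture deficit (mm, non-positive)
#' carried between monthly steps.
#'
#' @slot dpm,rpm,bio,hum,iom numeric pools, Mg C ha-1.
#' @slot accTSMD accumulated topsoil moisture deficit, mm (<= 0).
#'
#' @aliases RothCState-class
#' @exportClass RothCState
setClass("RothCState",
  representation(dpm = "numeric", rpm = "numeric", bio = "numeric",
                 hum = "numeric", iom = "numeric", accTSMD = "numeric"),
  prototype(dpm = 0, rpm = 0, bio = 0, hum = 0, iom = 0, accTSMD = 0)
)

setValidity("RothCState", function(object) {
  pools <- c(object@dpm, object@rpm, object@bio, object@hum, object@iom)
  msg <- character()
  if (any(!is.finite(pools)) || any(pools < -1e-12))
    msg <- c(msg, "all pools must be finite and non-negative")
  if (object@accTSMD > 1e-12)
    msg <- c(msg, "accTSMD must be <= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn RothCState-class constructor.
#' @param dpm,rpm,bio,hum,iom pool sizes, Mg C ha-1.
#' @param accTSMD accumulated topsoil moisture deficit, mm (<= 0).
#' @export
rothCState <- function(dpm = 0, rpm = 0, bio = 0, hum = 0, iom = 0,
                       accTSMD = 0) {
  new("RothCState", dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = iom,
      accTSMD = accTSMD)
}
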