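#' Raster accessors
#'
#' @param x a [RasterLayer-class].
#' @return `rasterValues` the value matrix (`NA` = missing); `rasterKind`
#'   `"continuous"` or `"categorical"`; `rasterCRS` the CRS string.
#' @name raster-accessors
NULL

#' @rdname raster-accessors
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))
#' @rdname raster-accessors
#' @export
setGeneric("rasterKind", function(x) standardGeneric("rasterKind"))
#' @rdname raster-accessors
#' @export
setGeneric("rasterCRS", function(x) standardGeneric("rasterCRS"))

#' @rdname raster-accessors
setMethod("rasterValues", "RasterLayer", function(x) x@values)
#' @rdname raster-accessors
setMethod("rasterKind", "RasterLayer", function(x) x@kind)
#' @rdname raster-accessors
setMethod("rasterCRS", "RasterLayer", function(x) x@crs)

#' @describeIn raster-accessors grid dimensions (rows, columns).
#' @export
setMethod("dim", "RasterLayer", function(x) dim(x@values))

setMethod("show", "RasterLayer", function(object) {
  d <- dim(object@values)
  cat(sprintf("RasterLayer: %d x %d cells, %s\n", d[1], d[2], object@kind))
  cat(sprintf("  origin (xll, yll): (%g, %g), cellsize %g, CRS %s\n",
              object@xll, object@yll, object@cellsize, object@crs))
  v <- object@values
  cat(sprintf("  values: %d valid, %d missing", sum(!is.na(v)),
              sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf(", range [%g, %g]", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  cat("\n")
})

#' Total soil organic carbon of a RothC state
#'
#' @param x a [RothCState-class].
#' @return Sum of the five pools, Mg C ha-1.
#' @export
setGeneric("socTotal", function(x) standardGeneric("socTotal"))

#' @rdname socTotal
setMethod("socTotal", "RothCState", function(x)
  x@dpm + x@rpm + x@bio + x@hum + x@iom)

setMethod("show", "RothCState", function(object) {
  cat(sprintf(
    "RothCState [Mg C/ha]: DPM %.4g, RPM %.4g, BIO %.4g, HUM %.4g, IOM %.4g\n",
    object@dpm, object@rpm, object@bio, object@hum, object@iom))
  cat(sprintf("  total %.4g; accTSMD %.4g mm\n", socTotal(object),
              object@accTSMD))
})

setMethod("show", "MarginalLandMask", function(object) {
  on <- object@mask & !is.na(object@mask)
  cat(sprintf("MarginalLandMask: %d of %d cells retained\n", sum(on),
              length(on)))
  if (any(on)) {
    tab <- table(object@provenance[on])
    cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
})

setMethod("show", "TargetArea", function(object) {
  cat(sprintf("TargetArea %s x %s: %.1f ha\n", object@regionId,
              object@gezId, object@areaHa))
  cat(sprintf(
    "  MAT %.1f degC, MAP %.0f mm, pH %.2f, clay %.1f%%, %s texture\n",
    mean(object@tempMonthly), sum(object@precMonthly), object@ph,
    object@clayPct, object@texture))
  cat(sprintf("  SOC0 %.1f Mg C/ha, soil loss %.2f Mg/ha/yr, elev %.0f m\n",
              object@socInit, object@soilLoss, object@elevationM))
})

setMethod("show", "SpeciesRecord", function(object) {
  cat(sprintf("SpeciesRecord '%s' (%s): %s, %s, lifetime %g yr\n",
              object@name, object@taxon, object@lifeForm, object@lifecycle,
              object@lifetimeYr))
  cat(sprintf("  T [%g, %g] degC, P [%g, %g] mm, pH [%g, %g], alt [%g, %g] m\n",
              object@tempAbs[1], object@tempAbs[2], object@precAbs[1],
              object@precAbs[2], object@phAbs[1], object@phAbs[2],
              object@altAbs[1], object@altAbs[2]))
  cat(sprintf("  GEZ: %s; texture: %s; C factor %g\n",
              paste(object@gezOk, collapse = ","),
              paste(object@textureOk, collapse = ","), object@coverFactor))
})

#' Is a target area usable for matching?
#'
#' An area is unusable when any attribute tested by the matching criteria
#' (temperature, precipitation, pH, texture, elevation, GEZ) is missing.
#'
#' @param x a [TargetArea-class].
#' @return logical.
#' @export
isUsable <- function(x) {
  stopifnot(is(x, "TargetArea"))
  !(any(is.na(x@tempMonthly)) || any(is.na(x@precMonthly)) ||
      is.na(x@ph) || is.na(x@texture) || is.na(x@elevationM) ||
      is.na(x@gezId))
}
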