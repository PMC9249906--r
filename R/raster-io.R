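#' Read a raster from an ESRI ASCII grid file
#'
#' Parses the plain-text `.asc` interchange format (header keys `ncols`,
#' `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' optional `nodata_value`) followed by row-major values, northern row
#' first. A `.prj` sidecar file, when present next to the grid, supplies
#' the CRS string; otherwise `crs` is used.
#'
#' @param path path to the `.asc` file.
#' @param kind `"continuous"` (default) or `"categorical"`; the format
#'   carries no such metadata, so the caller decides.
#' @param crs fallback CRS identifier when no `.prj` sidecar exists.
#' @return A [RasterLayer-class].
#' @seealso [writeAsciiGrid()]
#' @export
readAsciiGrid <- function(path, kind = c("continuous", "categorical"),
                          crs = "EPSG:4326") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)

  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else stop("not an ESRI ASCII grid (no x origin): ", path)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else stop("not an ESRI ASCII grid (no y origin): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

  tok <- unlist(strsplit(trimws(lines[i:length(lines)]), "[[:space:]]+"))
  tok <- tok[nzchar(tok)]
  vals <- suppressWarnings(as.numeric(tok))
  if (length(vals) != nr * nc || anyNA(vals))
    stop("grid body does not match header dimensions: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)

  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  if (prj != path && file.exists(prj)) {
    p <- trimws(readLines(prj, warn = FALSE)[1])
    if (!nzchar(p)) stop("unreadable CRS in ", prj)
    crs <- p
  }
  rasterLayer(m, xll = xll, yll = yll, cellsize = cs, crs = crs,
              nodata = nodata, kind = kind)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full precision (`%.15g`) so integer grids
#' round-trip bit-exactly. The CRS is written to a `.prj` sidecar.
#'
#' @param layer a [RasterLayer-class].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  stopifnot(is(layer, "RasterLayer"))
  v <- layer@values
  v[is.na(v)] <- layer@nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.15g", layer@xll),
    sprintf("yllcorner %.15g", layer@yll),
    sprintf("cellsize %.15g", layer@cellsize),
    sprintf("NODATA_value %.15g", layer@nodata)
  )
  body <- apply(v, 1, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  if (prj != path) writeLines(layer@crs, prj)
  invisible(path)
}

# cell-center coordinates along each axis; rows are returned north->south
.cellCenters <- function(layer) {
  nr <- nrow(layer@values); nc <- ncol(layer@values); cs <- layer@cellsize
  list(
    x = layer@xll + (seq_len(nc) - 0.5) * cs,
    y = layer@yll + (nr - seq_len(nr) + 0.5) * cs
  )
}

.isGeographic <- function(crs) {
  grepl("4326|WGS ?84|longlat|CRS84", crs, ignore.case = TRUE)
}

.sameGrid <- function(a, b, tol = 1e-9) {
  identical(dim(a@values), dim(b@values)) &&
    abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol &&
    abs(a@cellsize - b@cellsize) < tol
}

#' Per-cell area in hectares
#'
#' For geographic (longitude/latitude) grids a geodesic approximation is
#' used: the east-west cell width is scaled by the cosine of the cell-center
#' latitude, with one degree taken as 111.32 km. For projected CRS the
#' cellsize is treated as meters.
#'
#' @param layer a [RasterLayer-class].
#' @return Numeric matrix of cell areas (ha), same shape as the grid.
#' @export
cellAreaHa <- function(layer) {
  stopifnot(is(layer, "RasterLayer"))
  nr <- nrow(layer@values); nc <- ncol(layer@values)
  if (.isGeographic(layer@crs)) {
    m_per_deg <- 111320
    lat <- .cellCenters(layer)$y
    side_ns <- layer@cellsize * m_per_deg
    side_ew <- layer@cellsize * m_per_deg * cos(lat * pi / 180)
    matrix(rep(side_ns * side_ew / 1e4, nc), nrow = nr, ncol = nc)
  } else {
    matrix(layer@cellsize^2 / 1e4, nrow = nr, ncol = nc)
  }
}

# 1-D fractional-overlap weight matrix between two regular axes given by
# their edge vectors (ascending). Rows: target intervals, cols: source.
.overlapWeights <- function(src_edges, dst_edges) {
  ns <- length(src_edges) - 1; nd <- length(dst_edges) - 1
  W <- matrix(0, nd, ns)
  for (j in seq_len(nd)) {
    lo <- dst_edges[j]; hi <- dst_edges[j + 1]
    ov <- pmin(hi, src_edges[-1]) - pmax(lo, src_edges[-length(src_edges)])
    ov[ov < 0] <- 0
    W[j, ] <- ov
  }
  W
}

#' Resample a raster onto a reference grid
#'
#' Categorical layers are resampled by nearest neighbour (cell-center to
#' cell-center); continuous layers by area-weighted mean of overlapping
#' source cells. Missing source cells are excluded from the weighted mean;
#' a target cell with no valid overlap is missing. Both layers must share a
#' CRS (no reprojection is attempted) and an already-aligned layer is
#' returned unchanged.
#'
#' @param layer a [RasterLayer-class] to resample.
#' @param reference a [RasterLayer-class] defining the output grid.
#' @return A [RasterLayer-class] on `reference`'s grid.
#' @export
alignToGrid <- function(layer, reference) {
  stopifnot(is(layer, "RasterLayer"), is(reference, "RasterLayer"))
  if (!nzchar(layer@crs) || !nzchar(reference@crs))
    stop("both layers must carry a CRS")
  if (layer@crs != reference@crs)
    stop("CRS mismatch (", layer@crs, " vs ", reference@crs,
         "); reprojection is not supported")
  if (.sameGrid(layer, reference)) return(layer)

  nr_o <- nrow(reference@values); nc_o <- ncol(reference@values)
  if (layer@kind == "categorical") {
    cc <- .cellCenters(reference)
    src <- .cellCenters(layer)
    nr_s <- nrow(layer@values); nc_s <- ncol(layer@values)
    ci <- pmin(pmax(round((cc$x - layer@xll) / layer@cellsize + 0.5), 1),
               nc_s)
    # rows count from the north
    ri <- pmin(pmax(round((layer@yll + nr_s * layer@cellsize - cc$y) /
                            layer@cellsize + 0.5), 1), nr_s)
    out <- layer@values[cbind(rep(ri, times = nc_o),
                              rep(ci, each = nr_o))]
    out <- matrix(out, nr_o, nc_o)
  } else {
    sx <- layer@xll + (0:ncol(layer@values)) * layer@cellsize
    dx <- reference@xll + (0:nc_o) * reference@cellsize
    sy <- layer@yll + (0:nrow(layer@values)) * layer@cellsize
    dy <- reference@yll + (0:nr_o) * reference@cellsize
    Wx <- .overlapWeights(sx, dx)                  # nc_o x nc_s
    Wy <- .overlapWeights(sy, dy)                  # nr_o x nr_s
    # matrices store row 1 = north = largest y; flip to ascending-y order
    V <- layer@values[rev(seq_len(nrow(layer@values))), , drop = FALSE]
    valid <- !is.na(V)
    Vz <- V; Vz[!valid] <- 0
    num <- Wy %*% Vz %*% t(Wx)
    den <- Wy %*% (valid + 0) %*% t(Wx)
    out <- ifelse(den > 0, num / den, NA_real_)
    out <- out[rev(seq_len(nr_o)), , drop = FALSE]
  }
  rasterLayer(out, xll = reference@xll, yll = reference@yll,
              cellsize = reference@cellsize, crs = reference@crs,
              nodata = layer@nodata, kind = layer@kind)
}

#' Zonal aggregation of a raster
#'
#' Aggregates `values` over the zones of one coded zone raster, or over the
#' cross of two (region and GEZ) when `zones` is a list of two rasters.
#' `mean` is weighted over non-missing cells; `sum` is the weighted sum;
#' `mode` is the weight-maximising category, ties broken by the smallest
#' category code. Empty zones (all cells missing) are absent from the
#' result, not zero.
#'
#' @param values a [RasterLayer-class].
#' @param zones a categorical [RasterLayer-class], or
#'   `list(region = <RasterLayer>, gez = <RasterLayer>)`.
#' @param stat `"mean"`, `"sum"` or `"mode"`.
#' @param weights optional numeric matrix of per-cell weights (e.g. cell
#'   areas from [cellAreaHa()]); defaults to equal weights.
#' @return A data.frame keyed by `zone_id` (or `region_id`, `gez_id`) with a
#'   `value` column.
#' @export
zonalAggregate <- function(values, zones, stat = c("mean", "sum", "mode"),
                           weights = NULL) {
  stat <- match.arg(stat)
  stopifnot(is(values, "RasterLayer"))
  two <- is.list(zones) && !is(zones, "RasterLayer")
  zl <- if (two) zones else list(zone = zones)
  for (z in zl) {
    stopifnot(is(z, "RasterLayer"))
    if (!.sameGrid(values, z))
      stop("values and zones must share a grid (align first)")
  }
  v <- as.vector(values@values)
  w <- if (is.null(weights)) rep(1, length(v)) else as.vector(weights)
  if (length(w) != length(v)) stop("weights must match the grid")

  keys <- lapply(zl, function(z) as.vector(z@values))
  ok <- !is.na(v) & Reduce(`&`, lapply(keys, function(k) !is.na(k)))
  if (!any(ok)) {
    out <- data.frame(matrix(numeric(0), 0, length(keys) + 1))
    names(out) <- c(if (two) c("region_id", "gez_id") else "zone_id",
                    "value")
    return(out)
  }
  kdf <- as.data.frame(lapply(keys, function(k) k[ok]))
  names(kdf) <- if (two) c("region_id", "gez_id") else "zone_id"
  key <- do.call(paste, c(kdf, sep = "\r"))
  v <- v[ok]; w <- w[ok]

  agg <- switch(stat,
    mean = tapply(seq_along(v), key, function(ix)
      sum(v[ix] * w[ix]) / sum(w[ix])),
    sum = tapply(seq_along(v), key, function(ix) sum(v[ix] * w[ix])),
    mode = tapply(seq_along(v), key, function(ix) {
      ww <- tapply(w[ix], v[ix], sum)
      cand <- as.numeric(names(ww)[ww == max(ww)])
      min(cand)
    })
  )
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(apply(parts, 2, as.numeric, simplify = FALSE))
  names(out) <- names(kdf)
  out$value <- as.numeric(agg)
  out <- out[do.call(order, out[names(kdf)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
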