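.criteria <- c("temperature", "precipitation", "ph", "texture",
               "elevation", "climate_zone")

#' Test pedoclimatic compatibility of one species with one target area
#' (step 4a)
#'
#' Six binary criteria must all pass: (1) mean annual temperature within
#' `tempAbs`; (2) annual precipitation sum within `precAbs`; (3) pH within
#' `phAbs`; (4) modal texture in `textureOk`; (5) elevation within
#' `altAbs` (lower bound -500 m when absent); (6) GEZ in `gezOk`. With
#' `temp_screen = "monthly_extremes"` the coldest and warmest monthly
#' normals must additionally lie within `tempAbs`.
#'
#' An area with a missing tested attribute yields an explicit unevaluable
#' result (`matched = NA`, `failed_criteria = "unevaluable"`), not a
#' silent non-match.
#'
#' @param species a [SpeciesRecord-class].
#' @param area a [TargetArea-class].
#' @param temp_screen `"annual"` (default) or `"monthly_extremes"`.
#' @return One-row data.frame: `region_id`, `gez_id`, `taxon`, `matched`,
#'   one logical column per criterion, and `failed_criteria`
#'   (semicolon-separated names, empty when matched).
#' @export
isMatch <- function(species, area,
                    temp_screen = c("annual", "monthly_extremes")) {
  temp_screen <- match.arg(temp_screen)
  stopifnot(is(species, "SpeciesRecord"), is(area, "TargetArea"))
  base <- data.frame(region_id = area@regionId, gez_id = area@gezId,
                     taxon = species@taxon, stringsAsFactors = FALSE)
  if (!isUsable(area)) {
    base$matched <- NA
    for (cr in .criteria) base[[cr]] <- NA
    base$failed_criteria <- "unevaluable"
    return(base)
  }
  inRange <- function(x, r) x >= r[1] & x <= r[2]
  mat <- mean(area@tempMonthly)
  pass <- c(
    temperature = inRange(mat, species@tempAbs) &&
      (temp_screen == "annual" ||
         (inRange(min(area@tempMonthly), species@tempAbs) &&
            inRange(max(area@tempMonthly), species@tempAbs))),
    precipitation = inRange(sum(area@precMonthly), species@precAbs),
    ph = inRange(area@ph, species@phAbs),
    texture = area@texture %in% species@textureOk,
    elevation = inRange(area@elevationM, species@altAbs),
    climate_zone = area@gezId %in% species@gezOk
  )
  base$matched <- all(pass)
  for (cr in .criteria) base[[cr]] <- unname(pass[cr])
  base$failed_criteria <- paste(.criteria[!pass], collapse = ";")
  base
}

#' Match every species against every target area (step 4a)
#'
#' Full cross of the two lists; equivalent to the brute-force double loop
#' over [isMatch()].
#'
#' @param species list of [SpeciesRecord-class].
#' @param areas list of [TargetArea-class].
#' @inheritParams isMatch
#' @return data.frame with `length(species) * length(areas)` rows in
#'   area-major order (all species for the first area, then the second...).
#' @export
matchAll <- function(species, areas,
                     temp_screen = c("annual", "monthly_extremes")) {
  temp_screen <- match.arg(temp_screen)
  if (!length(species) || !length(areas))
    stop("species and areas must be non-empty")
  rows <- vector("list", length(species) * length(areas))
  k <- 0
  for (a in areas) for (s in species) {
    k <- k + 1
    rows[[k]] <- isMatch(s, a, temp_screen)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of theoretically possible area-by-species pairings
#'
#' @param n_areas,n_species non-negative integers.
#' @return `n_areas * n_species`.
#' @export
countTheoretical <- function(n_areas, n_species) {
  stopifnot(n_areas >= 0, n_species >= 0)
  as.integer(n_areas) * as.integer(n_species)
}
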