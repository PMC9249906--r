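#' Rescale a mapped soil-loss rate to a new cover (step 4c)
#'
#' RUSLE soil loss is linear in the cover-management (C) factor, so a
#' mapped rate under a reference cover rescales to a candidate species'
#' cover as `e_adj = e_map x c_new / c_ref`.
#'
#' @param e_map mapped soil loss, Mg soil ha-1 yr-1 (`>= 0`).
#' @param c_new cover-management factor of the candidate species, (0, 1]
#'   (0 allowed as the perfect-cover boundary).
#' @param c_ref cover-management factor consistent with the map's land
#'   cover (default 0.5 for bare/sparse covers).
#' @return Adjusted soil loss, Mg soil ha-1 yr-1.
#' @export
adjustSoilLoss <- function(e_map, c_new, c_ref = 0.5) {
  stopifnot(all(e_map >= 0), c_new >= 0, c_new <= 1)
  if (c_ref <= 0 || c_ref > 1) stop("c_ref must be in (0, 1]")
  e_map * c_new / c_ref
}

#' Annual SOC loss from soil loss by water (step 4c)
#'
#' Converts a soil mass loss into a carbon loss through the topsoil carbon
#' concentration: topsoil mass `M = bulk_density x depth_cm x 100`
#' (Mg ha-1), loss `= e_adj x soc_stock / M x enrichment`.
#'
#' @param e_adj adjusted soil loss, Mg soil ha-1 yr-1.
#' @param soc_stock SOC stock in the topsoil, Mg C ha-1.
#' @param bulk_density Mg m-3.
#' @param depth_cm topsoil depth, cm.
#' @param enrichment enrichment ratio of carbon in eroded sediment
#'   (default 1).
#' @return SOC loss, Mg C ha-1 yr-1.
#' @export
socErosionAnnual <- function(e_adj, soc_stock, bulk_density, depth_cm = 30,
                             enrichment = 1) {
  stopifnot(all(e_adj >= 0), all(soc_stock >= 0), bulk_density >= 0,
            depth_cm >= 0)
  m <- bulk_density * depth_cm * 100
  if (m == 0) stop("topsoil mass is zero")
  e_adj * soc_stock / m * enrichment
}

#' Cumulative SOC erosion along a simulated trajectory (step 4c)
#'
#' Offline (bookkeeping) coupling: the year-y loss is computed from the
#' year-y simulated SOC stock and summed; losses are not fed back into the
#' turnover pools, matching the "final SOC prior to erosion" vs "eroded
#' SOC" accounting that is netted afterwards.
#'
#' @param soc_yearly yearly SOC totals (Mg C ha-1), length `>= years`.
#' @param e_adj adjusted soil loss, Mg soil ha-1 yr-1.
#' @param bulk_density Mg m-3.
#' @param depth_cm topsoil depth, cm.
#' @param years number of years to accumulate (default: whole trajectory).
#' @param enrichment enrichment ratio (default 1).
#' @return `list(annual = <numeric years>, cumulative = <numeric>)`, all
#'   entries `>= 0` and `cumulative = sum(annual)`.
#' @export
cumulativeErosion <- function(soc_yearly, e_adj, bulk_density,
                              depth_cm = 30, years = length(soc_yearly),
                              enrichment = 1) {
  if (length(soc_yearly) < years)
    stop("trajectory shorter than the requested horizon")
  ann <- socErosionAnnual(e_adj, soc_yearly[seq_len(years)], bulk_density,
                          depth_cm, enrichment)
  list(annual = ann, cumulative = sum(ann))
}
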