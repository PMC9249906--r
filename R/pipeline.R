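#' Run the full scenario pipeline on a synthetic world
#'
#' Convenience orchestration of the whole chain —
#' identify marginal land, consolidate target areas, match species,
#' simulate soil-carbon turnover with erosion netting, select best cases
#' and summarise — against a generated world and species panel. Mirrors
#' exactly what the command-line interface does stage by stage.
#'
#' @param world from [makeSyntheticWorld()].
#' @param panel from [makeSpeciesPanel()]; defaults to the world's
#'   engineered panel.
#' @param horizon_years simulation horizon (default 80).
#' @param c_ref reference cover factor for the soil-loss map.
#' @param params from [rothcParams()].
#' @return List: `marginal` (mask + composition), `zones`, `areas`,
#'   `matches`, `results`, `best`, `report`, `summary` (area totals).
#' @export
runPipeline <- function(world, panel = makeSpeciesPanel(world),
                        horizon_years = 80, c_ref = 0.5,
                        params = rothcParams()) {
  r <- world$rasters
  marginal <- identifyMarginalLand(r$lc_t0, r$lc_t1, r$soc, r$protected,
                                   r$problem)
  zones <- assignZones(marginal$mask, r$regions, r$gez)
  areas <- consolidateTargetAreas(
    marginal$mask, zones, r$soc,
    soil = list(clay = r$clay, ph = r$ph, texture = r$texture,
                bulk_density = r$bulk_density, soil_depth = r$soil_depth),
    terrain = list(elevation = r$elevation, slope = r$slope),
    soil_loss = r$soil_loss, climate = world$climate)
  matches <- matchAll(panel$species, areas)
  results <- simulateMatches(matches, areas, panel$species,
                             horizon_years = horizon_years, c_ref = c_ref,
                             params = params)
  best <- selectBestCase(results)
  report <- scenarioReport(matches, results, best,
                           horizon_years = horizon_years)
  list(marginal = marginal, zones = zones, areas = areas,
       matches = matches, results = results, best = best,
       report = report, summary = summarizeAreas(areas))
}
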