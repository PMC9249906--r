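#' Simulate one matched target-area by species pair (step 4)
#'
#' Initialises the five pools from the area's SOC stock and clay content,
#' runs the monthly turnover model over the horizon with the species'
#' annual carbon input and cover schedule, computes cumulative water-
#' erosion SOC losses from end-of-year stocks, and nets the two. The
#' `initial_loss_flag` marks pairs whose net SOC is positive yet below the
#' initial stock (sequestration did not offset the drawdown of the
#' starting stock).
#'
#' @param area a [TargetArea-class].
#' @param species a [SpeciesRecord-class].
#' @param horizon_years simulation horizon (default 80, i.e. 2020-2100).
#' @param c_ref reference cover factor of the soil-loss map (default 0.5).
#' @param coupling `"offline"` (default; erosion as bookkeeping) or
#'   `"online"` (each year's loss removed proportionally from all pools).
#' @param params from [rothcParams()].
#' @param rhizodeposition_mult passed to [annualCInput()].
#' @return One-row data.frame: `region_id`, `gez_id`, `taxon`, `soc_init`,
#'   `soc_final` (prior to erosion), `eroded_cum`, `net_soc`,
#'   `net_positive`, `annualized_net`, `initial_loss_flag`.
#' @export
simulatePair <- function(area, species, horizon_years = 80, c_ref = 0.5,
                         coupling = c("offline", "online"),
                         params = rothcParams(),
                         rhizodeposition_mult = 1) {
  coupling <- match.arg(coupling)
  stopifnot(is(area, "TargetArea"), is(species, "SpeciesRecord"))
  if (is.na(area@socInit) || is.na(area@clayPct))
    stop("area lacks SOC or clay; cannot simulate")

  cin <- annualCInput(species, rhizodeposition_mult)
  cover <- rep(FALSE, 12)
  cover[if (length(species@coverMonths)) species@coverMonths else 1:12] <-
    TRUE
  input_m <- numeric(12)
  input_m[cover] <- cin$annual / sum(cover)
  ratio <- params$dpm_rpm_ratio[[species@lifeForm]]
  clim <- list(temp = area@tempMonthly, prec = area@precMonthly,
               pet = area@petMonthly)
  depth <- if (is.na(area@soilDepthCm)) 30 else area@soilDepthCm
  bd <- if (is.na(area@bulkDensity)) 1.4 else area@bulkDensity
  e_adj <- adjustSoilLoss(if (is.na(area@soilLoss)) 0 else area@soilLoss,
                          species@coverFactor, c_ref)

  st <- initPools(area@socInit, area@clayPct)

  if (coupling == "offline") {
    traj <- runRothC(st, clim, input_m, cover, horizon_years,
                     area@clayPct, depth, ratio, params)
    soc_yearly <- traj$total[12 * seq_len(horizon_years)]
    ero <- cumulativeErosion(soc_yearly, e_adj, bd, depth, horizon_years)
    soc_final <- traj$total[nrow(traj)]
    eroded <- ero$cumulative
  } else {
    soc_final <- NA_real_
    eroded <- 0
    state <- st
    for (y in seq_len(horizon_years)) {
      traj <- runRothC(state, clim, input_m, cover, 1, area@clayPct,
                       depth, ratio, params)
      last <- traj[nrow(traj), ]
      loss <- socErosionAnnual(e_adj, last$total, bd, depth)
      eroded <- eroded + loss
      keep <- if (last$total > 0) max(0, 1 - loss / last$total) else 0
      state <- rothCState(last$dpm * keep, last$rpm * keep,
                          last$bio * keep, last$hum * keep,
                          last$iom * keep, accTSMD = last$acc_tsmd)
      soc_final <- last$total
    }
  }

  # online coupling already removed the losses from the pools, so the
  # end state is itself the net stock; offline nets the two terms here
  net <- if (coupling == "offline") soc_final - eroded else soc_final
  data.frame(
    region_id = area@regionId, gez_id = area@gezId, taxon = species@taxon,
    soc_init = area@socInit, soc_final = soc_final, eroded_cum = eroded,
    net_soc = net, net_positive = net > 0,
    annualized_net = net / horizon_years,
    initial_loss_flag = net > 0 & net < area@socInit,
    stringsAsFactors = FALSE
  )
}

#' Simulate all matched pairs
#'
#' @param matches data.frame from [matchAll()] (only rows with
#'   `matched == TRUE` are simulated).
#' @param areas list of [TargetArea-class].
#' @param species list of [SpeciesRecord-class].
#' @param ... passed to [simulatePair()].
#' @return data.frame of simulation results, one row per viable match.
#' @export
simulateMatches <- function(matches, areas, species, ...) {
  akey <- vapply(areas, function(a) paste(a@regionId, a@gezId, sep = "\r"),
                 character(1))
  skey <- vapply(species, function(s) s@taxon, character(1))
  viable <- matches[!is.na(matches$matched) & matches$matched, ,
                    drop = FALSE]
  rows <- lapply(seq_len(nrow(viable)), function(i) {
    a <- areas[[match(paste(viable$region_id[i], viable$gez_id[i],
                            sep = "\r"), akey)]]
    s <- species[[match(viable$taxon[i], skey)]]
    simulatePair(a, s, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(0), gez_id = character(0),
                      taxon = character(0), soc_init = numeric(0),
                      soc_final = numeric(0), eroded_cum = numeric(0),
                      net_soc = numeric(0), net_positive = logical(0),
                      annualized_net = numeric(0),
                      initial_loss_flag = logical(0))
  rownames(out) <- NULL
  out
}

#' Select the best-case species per target area
#'
#' Keeps only net-positive results, then the argmax of `net_soc` within
#' each `(region_id, gez_id)`; exact ties break by taxon name ascending.
#' Areas with no net-positive result are omitted (their count is in
#' [scenarioReport()]).
#'
#' @param results data.frame from [simulateMatches()].
#' @return data.frame, one row per area with a net-positive option.
#' @export
selectBestCase <- function(results) {
  pos <- results[results$net_positive, , drop = FALSE]
  if (!nrow(pos)) return(pos)
  key <- paste(pos$region_id, pos$gez_id, sep = "\r")
  pick <- unlist(lapply(split(seq_len(nrow(pos)), key), function(ix) {
    best <- ix[pos$net_soc[ix] == max(pos$net_soc[ix])]
    best[order(pos$taxon[best])][1]
  }))
  out <- pos[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired-sample t test on initial vs final SOC
#'
#' Two-sided paired t statistic and p-value on the differences
#' `final - initial`. Zero-variance differences are flagged degenerate and
#' no p-value is reported.
#'
#' @param initial,final numeric vectors of equal length `>= 2`.
#' @return `list(t, df, p, degenerate)`.
#' @export
pairedTTest <- function(initial, final) {
  if (length(initial) != length(final) || length(initial) < 2)
    stop("need two equal-length vectors of length >= 2")
  d <- final - initial
  if (stats::sd(d) == 0)
    return(list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1,
                p = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(final, initial, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Annualise a cumulative stock change
#'
#' @param cumulative Mg C ha-1 over the period.
#' @param start_year,end_year period bounds (`end_year > start_year`).
#' @return Mg C ha-1 yr-1 (`cumulative / (end_year - start_year)`).
#' @export
annualize <- function(cumulative, start_year, end_year) {
  if (end_year <= start_year) stop("end_year must exceed start_year")
  cumulative / (end_year - start_year)
}

#' Integer percentage share, half-up rounding
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 0).
#' @return `num/den` as a percent, rounded half-up.
#' @export
percentShare <- function(num, den, digits = 0) {
  if (den == 0) return(NA_real_)
  x <- 100 * num / den
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Derived summary statistics of a scenario run
#'
#' Emits the counts and shares that characterise a run: theoretical,
#' viable and net-positive match counts; unique species and area counts;
#' best-case selection size; percentage shares (half-up to the nearest
#' integer percent); annualised net rates (2 dp); and the erosion share of
#' final SOC per best case.
#'
#' @param matches data.frame from [matchAll()].
#' @param results data.frame from [simulateMatches()].
#' @param best data.frame from [selectBestCase()].
#' @param horizon_years horizon used for annualisation (default 80).
#' @param reference optional named list of denominators:
#'   `inventoried_species`, `preselected_biopumps`, `target_mha`,
#'   `marginal_mha`.
#' @return Named list of counts, shares and rates.
#' @export
scenarioReport <- function(matches, results, best, horizon_years = 80,
                           reference = list()) {
  evaluable <- matches[!is.na(matches$matched), , drop = FALSE]
  n_theoretical <- nrow(matches)
  n_viable <- sum(evaluable$matched)
  n_pos <- sum(results$net_positive)
  areas_all <- unique(paste(matches$region_id, matches$gez_id, sep = "\r"))
  areas_pos <- unique(paste(results$region_id[results$net_positive],
                            results$gez_id[results$net_positive],
                            sep = "\r"))
  sp_matched <- unique(results$taxon)
  sp_best <- unique(best$taxon)

  ero_share <- if (nrow(best))
    ifelse(best$soc_final > 0,
           100 * best$eroded_cum / best$soc_final, NA_real_)
  else numeric(0)

  out <- list(
    n_theoretical = n_theoretical,
    n_unevaluable = nrow(matches) - nrow(evaluable),
    n_viable = n_viable,
    n_net_positive = n_pos,
    n_areas = length(areas_all),
    n_areas_net_positive = length(areas_pos),
    n_species_matched = length(sp_matched),
    n_best_cases = nrow(best),
    n_species_best = length(sp_best),
    pct_viable_of_theoretical = percentShare(n_viable, n_theoretical),
    pct_net_positive_of_viable = percentShare(n_pos, n_viable),
    best_net_range = if (nrow(best)) range(best$net_soc) else c(NA, NA),
    best_annualized = if (nrow(best))
      round(best$net_soc / horizon_years, 2) else numeric(0),
    erosion_share_of_final_pct = ero_share
  )
  if (!is.null(reference$inventoried_species))
    out$pct_species_suitable <- percentShare(
      length(sp_matched), reference$inventoried_species)
  if (!is.null(reference$preselected_biopumps))
    out$pct_biopumps_matched <- percentShare(
      length(unique(results$taxon)), reference$preselected_biopumps)
  if (!is.null(reference$target_mha) && !is.null(reference$net_positive_mha))
    out$pct_area_net_positive <- percentShare(
      reference$net_positive_mha, reference$target_mha)
  if (!is.null(reference$marginal_mha) && !is.null(reference$target_mha))
    out$pct_target_of_marginal <- percentShare(
      reference$target_mha, reference$marginal_mha)
  out
}
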