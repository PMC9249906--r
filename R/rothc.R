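#' RothC v26.3 parameter set
#'
#' Decomposition rate constants and modifier constants of the five-pool
#' monthly turnover model. Defaults follow the RothC v26.3 documentation:
#' rate constants (yr-1) DPM 10.0, RPM 0.3, BIO 0.66, HUM 0.02; the
#' BIO/HUM split of non-respired decomposed carbon 0.46/0.54; the soil
#' cover rate modifier 0.6; the bare-soil topsoil-moisture-deficit divisor
#' 1.8; the moisture ramp threshold 0.444 with floor 0.2; incoming plant
#' carbon split DPM:RPM by a land-use ratio (crop and grass 1.44, tree
#' 0.25).
#'
#' @param k named rates (yr-1) for dpm, rpm, bio, hum.
#' @param dpm_rpm_ratio named land-use ratios.
#' @param bio_hum_split two shares summing to 1.
#' @param cover_rate_modifier multiplicative rate modifier when the soil is
#'   covered by a crop/canopy.
#' @param tsmd_bare_divisor divisor of the maximum deficit under bare soil.
#' @param tsmd_threshold fraction of the maximum deficit below which the
#'   moisture modifier is 1.
#' @param b_min floor of the moisture modifier.
#' @param pan_correction multiplier applied to the evapotranspiration input
#'   (1 = use the potential-evapotranspiration product directly; the
#'   classical open-pan correction would be 0.75).
#' @return Named list of parameters.
#' @export
rothcParams <- function(k = c(dpm = 10.0, rpm = 0.3, bio = 0.66,
                              hum = 0.02),
                        dpm_rpm_ratio = c(crop = 1.44, grass = 1.44,
                                          tree = 0.25),
                        bio_hum_split = c(bio = 0.46, hum = 0.54),
                        cover_rate_modifier = 0.6,
                        tsmd_bare_divisor = 1.8,
                        tsmd_threshold = 0.444,
                        b_min = 0.2,
                        pan_correction = 1.0) {
  stopifnot(all(k > 0), abs(sum(bio_hum_split) - 1) < 1e-12,
            cover_rate_modifier > 0, tsmd_bare_divisor > 0)
  list(k = k, dpm_rpm_ratio = dpm_rpm_ratio,
       bio_hum_split = bio_hum_split,
       cover_rate_modifier = cover_rate_modifier,
       tsmd_bare_divisor = tsmd_bare_divisor,
       tsmd_threshold = tsmd_threshold, b_min = b_min,
       pan_correction = pan_correction)
}

#' Temperature rate modifier
#'
#' `a(T) = 47.91 / (1 + exp(106.06 / (T + 18.27)))`, zero at and below the
#' -18.27 deg C singularity (no biological activity).
#'
#' @param t_mean mean monthly air temperature, deg C (vectorised).
#' @return Unitless modifier `>= 0`.
#' @export
rothcTemperatureModifier <- function(t_mean) {
  out <- numeric(length(t_mean))
  ok <- t_mean > -18.27
  out[ok] <- 47.91 / (1 + exp(106.06 / (t_mean[ok] + 18.27)))
  out
}

#' Maximum topsoil moisture deficit
#'
#' `maxTSMD = -(20.0 + 1.3 clay - 0.01 clay^2) x depth/23`, divided by the
#' bare-soil divisor when the soil is uncovered.
#'
#' @param clay_pct clay content, %.
#' @param depth_cm soil depth considered, cm.
#' @param covered logical; is the soil covered by a crop/canopy?
#' @param params from [rothcParams()].
#' @return Deficit capacity in mm, `<= 0`.
#' @export
rothcMaxTSMD <- function(clay_pct, depth_cm, covered = TRUE,
                         params = rothcParams()) {
  stopifnot(clay_pct >= 0, clay_pct <= 100, depth_cm > 0)
  m <- -(20.0 + 1.3 * clay_pct - 0.01 * clay_pct^2) * depth_cm / 23
  if (!covered) m <- m / params$tsmd_bare_divisor
  m
}

#' Moisture rate modifier and deficit bookkeeping
#'
#' Accumulates the monthly water balance `P - PET` into the topsoil
#' moisture deficit, clamped to `[maxTSMD, 0]`, and maps the deficit to
#' the rate modifier: 1 while the deficit is shallower than
#' `tsmd_threshold x |maxTSMD|`, then a linear ramp down to `b_min` at the
#' full deficit.
#'
#' @param p,pet monthly precipitation and (potential) evapotranspiration,
#'   mm. `pet` is multiplied by `params$pan_correction`.
#' @param acc_tsmd accumulated deficit carried in, mm (`<= 0`).
#' @param max_tsmd deficit capacity from [rothcMaxTSMD()] for this month's
#'   cover state, mm.
#' @param params from [rothcParams()].
#' @return `list(b, acc_tsmd)`.
#' @export
rothcMoistureModifier <- function(p, pet, acc_tsmd, max_tsmd,
                                  params = rothcParams()) {
  stopifnot(p >= 0, pet >= 0)
  acc <- acc_tsmd + (p - pet * params$pan_correction)
  acc <- min(max(acc, max_tsmd), 0)
  amax <- abs(max_tsmd)
  aacc <- abs(acc)
  b <- if (aacc < params$tsmd_threshold * amax) 1
       else params$b_min + (1 - params$b_min) *
         (amax - aacc) / ((1 - params$tsmd_threshold) * amax)
  list(b = b, acc_tsmd = acc)
}

#' Clay-dependent partition of decomposed carbon
#'
#' `x = 1.67 (1.85 + 1.60 exp(-0.0786 clay))` is the CO2 / (BIO + HUM)
#' ratio; the decomposed flux splits into `x/(x+1)` respired CO2 and
#' `1/(x+1)` retained, the retained part 0.46/0.54 between BIO and HUM.
#'
#' @param clay_pct clay content, %.
#' @param params from [rothcParams()].
#' @return Named numeric `c(co2, bio, hum)` summing to 1.
#' @export
rothcPartition <- function(clay_pct, params = rothcParams()) {
  stopifnot(clay_pct >= 0, clay_pct <= 100)
  x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay_pct))
  c(co2 = x / (x + 1),
    bio = params$bio_hum_split[["bio"]] / (x + 1),
    hum = params$bio_hum_split[["hum"]] / (x + 1))
}

#' Default pool pedotransfer regressions
#'
#' Predict RPM, HUM and BIO (Mg C ha-1) from total SOC and clay content;
#' IOM follows the Falloon regression `0.049 SOC^1.139`. The set is an
#' argument of [initPools()] so alternative supplements can be swapped in.
#'
#' @return Named list of `function(soc, clay)`.
#' @export
defaultPedotransfer <- function() {
  list(
    iom = function(soc, clay) 0.049 * soc^1.139,
    rpm = function(soc, clay)
      (0.1847 * soc + 0.1555) * (clay + 1.2750)^-0.1158,
    hum = function(soc, clay)
      (0.7148 * soc + 0.5069) * (clay + 0.3421)^0.0184,
    bio = function(soc, clay)
      (0.0140 * soc + 0.0075) * (clay + 8.8473)^0.0567
  )
}

#' Initialise the five pools from total SOC (pedotransfer)
#'
#' IOM, RPM, HUM and BIO come from the pedotransfer regressions; DPM is
#' the remainder so the pools sum to `soc0` exactly. When the regressions
#' overshoot (remainder negative), DPM is floored at 0 and RPM/HUM/BIO are
#' rescaled proportionally onto `soc0 - IOM`.
#'
#' @param soc0 total SOC stock, Mg C ha-1 (`> 0`).
#' @param clay_pct clay content, %.
#' @param regressions from [defaultPedotransfer()].
#' @return A [RothCState-class] with `accTSMD = 0`.
#' @export
initPools <- function(soc0, clay_pct, regressions = defaultPedotransfer()) {
  if (soc0 <= 0) stop("soc0 must be positive")
  iom <- regressions$iom(soc0, clay_pct)
  if (iom >= soc0) {   # degenerate tiny-stock case: all inert
    return(rothCState(iom = soc0))
  }
  rpm <- regressions$rpm(soc0, clay_pct)
  hum <- regressions$hum(soc0, clay_pct)
  bio <- regressions$bio(soc0, clay_pct)
  dpm <- soc0 - (iom + rpm + hum + bio)
  if (dpm < 0) {
    scale <- (soc0 - iom) / (rpm + hum + bio)
    rpm <- rpm * scale; hum <- hum * scale; bio <- bio * scale
    dpm <- 0
  }
  rothCState(dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = iom)
}

# core monthly update on a bare numeric state c(dpm, rpm, bio, hum, iom);
# returns list(pools, co2). Decay first, then this month's input enters
# DPM/RPM (new material starts decomposing the following month).
.stepPools <- function(pools, abc, c_input, ratio, k, part) {
  decay <- pools[1:4] * (1 - exp(-abc * k / 12))
  d <- sum(decay)
  pools[1:4] <- pools[1:4] - decay
  pools[3] <- pools[3] + d * part[["bio"]]
  pools[4] <- pools[4] + d * part[["hum"]]
  pools[1] <- pools[1] + c_input * ratio / (1 + ratio)
  pools[2] <- pools[2] + c_input / (1 + ratio)
  list(pools = pools, co2 = d * part[["co2"]])
}

#' One monthly RothC step
#'
#' Each active pool decays by `exp(-a b c k/12)`; the decomposed flux is
#' partitioned into respired CO2 and BIO/HUM transfers by the clay
#' partition; this month's plant input enters DPM and RPM in the ratio
#' `ratio : 1`. IOM is inert. Mass balance is exact:
#' `delta(total) = input - co2`.
#'
#' @param state a [RothCState-class].
#' @param a,b,c temperature, moisture and cover rate modifiers.
#' @param c_input plant carbon input this month, Mg C ha-1.
#' @param ratio DPM/RPM split of the input (land-use dependent).
#' @param clay_pct clay content, %.
#' @param params from [rothcParams()].
#' @return `list(state = <RothCState>, co2 = <Mg C ha-1>)`.
#' @export
stepMonth <- function(state, a, b, c, c_input, ratio, clay_pct,
                      params = rothcParams()) {
  stopifnot(is(state, "RothCState"), a >= 0, b >= 0, c >= 0, c_input >= 0)
  part <- rothcPartition(clay_pct, params)
  st <- .stepPools(c(state@dpm, state@rpm, state@bio, state@hum,
                     state@iom),
                   a * b * c, c_input, ratio, params$k, part)
  list(state = rothCState(st$pools[1], st$pools[2], st$pools[3],
                          st$pools[4], st$pools[5],
                          accTSMD = state@accTSMD),
       co2 = st$co2)
}

#' Run the monthly five-pool turnover model (step 4b)
#'
#' Steps the model over `12 * years` months, recycling 12-month climate
#' normals. Monthly modifiers are recomputed each step: the temperature
#' modifier from the monthly normal, the moisture modifier from the
#' accumulated deficit (capacity reduced by the bare divisor in uncovered
#' months), and the cover modifier 0.6 in covered months, 1.0 otherwise.
#'
#' @param state0 initial [RothCState-class] (e.g. from [initPools()]).
#' @param climate `list(temp, prec, pet)` of length-12 monthly normals
#'   (deg C, mm, mm).
#' @param input_monthly length-12 plant C input schedule (Mg C ha-1 per
#'   month), recycled annually; a scalar is spread evenly over 12 months.
#' @param cover_monthly length-12 logical cover schedule (TRUE = soil
#'   covered), recycled annually; a scalar is recycled.
#' @param years simulation length, years (`>= 1`).
#' @param clay_pct clay content, %.
#' @param depth_cm topsoil depth, cm.
#' @param ratio DPM/RPM input split.
#' @param params from [rothcParams()].
#' @return data.frame trajectory with one row per month: `month`, the five
#'   pools, `total`, `co2`, `acc_tsmd`; attributes `cum_co2` and
#'   `cum_input`.
#' @export
runRothC <- function(state0, climate, input_monthly, cover_monthly = TRUE,
                     years, clay_pct, depth_cm = 30, ratio = 1.44,
                     params = rothcParams()) {
  stopifnot(is(state0, "RothCState"), years >= 1)
  tm <- rep_len(as.numeric(climate$temp), 12)
  pm <- rep_len(as.numeric(climate$prec), 12)
  em <- rep_len(as.numeric(climate$pet), 12)
  if (length(input_monthly) == 1)
    input_monthly <- rep(input_monthly / 12, 12)
  input_monthly <- rep_len(as.numeric(input_monthly), 12)
  cover_monthly <- rep_len(as.logical(cover_monthly), 12)
  stopifnot(all(input_monthly >= 0))

  part <- rothcPartition(clay_pct, params)
  a12 <- rothcTemperatureModifier(tm)
  cap <- vapply(cover_monthly, function(cov)
    rothcMaxTSMD(clay_pct, depth_cm, covered = cov, params), numeric(1))
  cmod <- ifelse(cover_monthly, params$cover_rate_modifier, 1.0)

  n <- 12L * as.integer(years)
  traj <- matrix(0, n, 9)
  pools <- c(state0@dpm, state0@rpm, state0@bio, state0@hum, state0@iom)
  acc <- state0@accTSMD
  cum_co2 <- 0
  for (step in seq_len(n)) {
    m <- ((step - 1L) %% 12L) + 1L
    mm <- rothcMoistureModifier(pm[m], em[m], acc, cap[m], params)
    acc <- mm$acc_tsmd
    st <- .stepPools(pools, a12[m] * mm$b * cmod[m], input_monthly[m],
                     ratio, params$k, part)
    pools <- st$pools
    cum_co2 <- cum_co2 + st$co2
    traj[step, ] <- c(step, pools, sum(pools), st$co2, acc)
  }
  out <- as.data.frame(traj)
  names(out) <- c("month", "dpm", "rpm", "bio", "hum", "iom", "total",
                  "co2", "acc_tsmd")
  attr(out, "cum_co2") <- cum_co2
  attr(out, "cum_input") <- sum(input_monthly) * years
  out
}
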