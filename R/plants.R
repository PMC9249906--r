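#' Load a species trait table (step 3)
#'
#' Reads the documented CSV schema into validated [SpeciesRecord-class]
#' objects. Rows violating an invariant (e.g. a tolerance minimum above its
#' maximum) are rejected with row-level diagnostics naming the field;
#' valid rows are kept.
#'
#' @details Schema (one row per species): `name`, `taxon`, `life_form`
#'   (grass/crop/tree), `lifecycle` (annual/perennial), `lifetime_yr`,
#'   `temp_min`, `temp_max` (deg C), `prec_min`, `prec_max` (mm yr-1),
#'   `ph_min`, `ph_max`, `texture_ok` (pipe-separated subset of
#'   coarse|medium|fine), `alt_min`, `alt_max` (m; `alt_min` may be empty,
#'   defaulting to -500), `gez_ok` (pipe-separated GEZ codes), `yield_dm`,
#'   `dm_product`, `dm_stem`, `dm_leaf`, `dm_root` (Mg DM ha-1),
#'   `c_product`, `c_stem`, `c_leaf`, `c_root` (% C), `ret_product`,
#'   `ret_stem`, `ret_leaf`, `ret_root` (shares in 0..1), `deciduous`
#'   (TRUE/FALSE), `cover_factor` (RUSLE C factor), `cover_months`
#'   (pipe-separated month numbers; empty = all 12).
#'
#' @param path CSV path.
#' @return List of [SpeciesRecord-class]; rejected rows are attached as
#'   attribute `"rejected"` (data.frame `row`, `taxon`, `message`).
#' @export
loadSpecies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "taxon", "life_form", "lifecycle", "lifetime_yr",
            "temp_min", "temp_max", "prec_min", "prec_max", "ph_min",
            "ph_max", "texture_ok", "alt_min", "alt_max", "gez_ok",
            "dm_product", "dm_stem", "dm_leaf", "dm_root",
            "c_product", "c_stem", "c_leaf", "c_root",
            "ret_product", "ret_stem", "ret_leaf", "ret_root",
            "deciduous", "cover_factor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("species table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("species table is empty")

  splitPipe <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  }
  records <- list()
  rejected <- data.frame(row = integer(0), taxon = character(0),
                         message = character(0))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    rec <- try(speciesRecord(
      name = r$name, taxon = r$taxon, life_form = r$life_form,
      lifecycle = r$lifecycle, lifetime_yr = r$lifetime_yr,
      temp_abs = c(r$temp_min, r$temp_max),
      prec_abs = c(r$prec_min, r$prec_max),
      ph_abs = c(r$ph_min, r$ph_max),
      texture_ok = splitPipe(r$texture_ok),
      alt_abs = c(if (is.na(r$alt_min)) -500 else r$alt_min, r$alt_max),
      gez_ok = splitPipe(r$gez_ok),
      yield_dm = if ("yield_dm" %in% names(r) && !is.na(r$yield_dm))
        r$yield_dm else 0,
      dm = c(product = r$dm_product, stem = r$dm_stem, leaf = r$dm_leaf,
             root = r$dm_root),
      c_pct = c(product = r$c_product, stem = r$c_stem, leaf = r$c_leaf,
                root = r$c_root),
      soil_return = c(product = r$ret_product, stem = r$ret_stem,
                      leaf = r$ret_leaf, root = r$ret_root),
      deciduous = isTRUE(as.logical(r$deciduous)),
      cover_factor = r$cover_factor,
      cover_months = as.integer(splitPipe(
        if ("cover_months" %in% names(r)) r$cover_months else ""))
    ), silent = TRUE)
    if (inherits(rec, "try-error")) {
      rejected <- rbind(rejected, data.frame(
        row = i, taxon = as.character(r$taxon),
        message = trimws(conditionMessage(attr(rec, "condition")))))
    } else {
      records[[length(records) + 1]] <- rec
    }
  }
  if (nrow(rejected))
    warning(nrow(rejected), " species row(s) rejected; see attr 'rejected'")
  attr(records, "rejected") <- rejected
  records
}

#' @rdname loadSpecies
#' @param name,taxon,life_form,lifecycle,lifetime_yr,temp_abs,prec_abs,ph_abs,texture_ok,alt_abs,gez_ok,yield_dm,dm,c_pct,soil_return,deciduous,cover_factor,cover_months
#'   see the [SpeciesRecord-class] slots; `dm`, `c_pct`, `soil_return` are
#'   named vectors over product/stem/leaf/root.
#' @export
speciesRecord <- function(name, taxon, life_form, lifecycle,
                          lifetime_yr = 1,
                          temp_abs, prec_abs, ph_abs,
                          texture_ok = c("coarse", "medium", "fine"),
                          alt_abs = c(-500, 4000), gez_ok,
                          yield_dm = 0, dm, c_pct, soil_return,
                          deciduous = FALSE, cover_factor = 0.5,
                          cover_months = integer(0)) {
  new("SpeciesRecord",
      name = as.character(name), taxon = as.character(taxon),
      lifeForm = as.character(life_form),
      lifecycle = as.character(lifecycle),
      lifetimeYr = as.numeric(lifetime_yr),
      tempAbs = as.numeric(temp_abs), precAbs = as.numeric(prec_abs),
      phAbs = as.numeric(ph_abs), textureOk = texture_ok,
      altAbs = as.numeric(alt_abs), gezOk = gez_ok,
      yieldDm = as.numeric(yield_dm), dmFractions = dm,
      cContentPct = c_pct, soilReturn = soil_return,
      deciduous = deciduous, coverFactor = as.numeric(cover_factor),
      coverMonths = as.integer(cover_months))
}

#' Species records as a data.frame (inverse of [loadSpecies()])
#'
#' @param species list of [SpeciesRecord-class].
#' @return data.frame in the [loadSpecies()] CSV schema.
#' @export
speciesToDataFrame <- function(species) {
  rows <- lapply(species, function(s) data.frame(
    name = s@name, taxon = s@taxon, life_form = s@lifeForm,
    lifecycle = s@lifecycle, lifetime_yr = s@lifetimeYr,
    temp_min = s@tempAbs[1], temp_max = s@tempAbs[2],
    prec_min = s@precAbs[1], prec_max = s@precAbs[2],
    ph_min = s@phAbs[1], ph_max = s@phAbs[2],
    texture_ok = paste(s@textureOk, collapse = "|"),
    alt_min = s@altAbs[1], alt_max = s@altAbs[2],
    gez_ok = paste(s@gezOk, collapse = "|"),
    yield_dm = s@yieldDm,
    dm_product = s@dmFractions[["product"]],
    dm_stem = s@dmFractions[["stem"]],
    dm_leaf = s@dmFractions[["leaf"]],
    dm_root = s@dmFractions[["root"]],
    c_product = s@cContentPct[["product"]],
    c_stem = s@cContentPct[["stem"]],
    c_leaf = s@cContentPct[["leaf"]],
    c_root = s@cContentPct[["root"]],
    ret_product = s@soilReturn[["product"]],
    ret_stem = s@soilReturn[["stem"]],
    ret_leaf = s@soilReturn[["leaf"]],
    ret_root = s@soilReturn[["root"]],
    deciduous = s@deciduous, cover_factor = s@coverFactor,
    cover_months = paste(s@coverMonths, collapse = "|"),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harmonise Koeppen-based climate zones with GEZ codes (step 3)
#'
#' ECOCROP climate-zone entries follow a Koeppen-based classification;
#' target areas are zoned by FAO Global Ecological Zones. The shipped
#' many-to-many mapping table (`koppen_gez.csv`, editable) translates one
#' to the other; an unmapped Koeppen code is an error naming the code.
#'
#' @param koppen_zones character vector of Koeppen codes (may be empty).
#' @param mapping data.frame with columns `koppen`, `gez`; defaults to the
#'   shipped table.
#' @return Character vector: union of mapped GEZ codes.
#' @export
harmonizeClimateZones <- function(koppen_zones,
                                  mapping = readKoppenGEZMap()) {
  if (!length(koppen_zones)) return(character(0))
  unmapped <- setdiff(koppen_zones, mapping$koppen)
  if (length(unmapped))
    stop("unmapped Koeppen code(s): ", paste(unmapped, collapse = ", "))
  sort(unique(mapping$gez[mapping$koppen %in% koppen_zones]))
}

#' @rdname harmonizeClimateZones
#' @param path CSV path.
#' @export
readKoppenGEZMap <- function(path = system.file("extdata", "koppen_gez.csv",
                                                package = "marginalSOC")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.lifeFormMap <- c(
  grass = "grass", herb = "grass", herbaceous = "grass", forb = "grass",
  bamboo = "grass", "small shrub" = "grass", "herbaceous shrub" = "grass",
  crop = "crop", cereal = "crop", vegetable = "crop", "field crop" = "crop",
  tree = "tree", "woody shrub" = "tree", "tree-like shrub" = "tree",
  "short rotation coppice" = "tree", orchard = "tree"
)

#' Classify a life-form descriptor into grass, crop or tree (step 3)
#'
#' Deterministic mapping from dataset descriptors to the three land-use
#' classes that parametrise the turnover model: grasses, herbs and small
#' woody or herbaceous shrubs are `grass`; cultivated annual field crops
#' are `crop`; trees, orchards, coppice and tree-like woody shrubs are
#' `tree`.
#'
#' @param descriptor character descriptor (case-insensitive), e.g.
#'   `"herbaceous"`, `"cereal"`, `"woody shrub"`.
#' @return `"grass"`, `"crop"` or `"tree"`.
#' @export
classifyLifeForm <- function(descriptor) {
  key <- tolower(trimws(descriptor))
  out <- .lifeFormMap[key]
  if (any(is.na(out)))
    stop("unknown life-form descriptor(s): ",
         paste(key[is.na(out)], collapse = ", "))
  unname(out)
}

#' Annual plant carbon input to the soil (step 3)
#'
#' Fraction-and-partitioning computation of the organic carbon a species
#' returns to the soil each year, split into aboveground (product, stem,
#' leaf) and belowground (root) compartments:
#' `C_f = DM_f x (%C_f / 100) x return_f`.
#'
#' Annuals return each fraction every year. For perennials the dry-matter
#' fractions are per rotation and are annualised linearly over the lifetime
#' (uneven-aged stand assumption), except deciduous leaves, whose stated
#' mass is shed and returned every year. Root carbon always remains in the
#' soil over the rotation and is annualised as total root C / lifetime.
#'
#' @param species a [SpeciesRecord-class].
#' @param rhizodeposition_mult multiplier folding extra-root C into the
#'   root compartment (default 1 = off).
#' @return `list(aboveground, root, annual)` in Mg C ha-1 yr-1, with
#'   `annual = aboveground + root`.
#' @export
annualCInput <- function(species, rhizodeposition_mult = 1) {
  stopifnot(is(species, "SpeciesRecord"))
  dm <- species@dmFractions[.fractions]
  cc <- species@cContentPct[.fractions] / 100
  ret <- species@soilReturn[.fractions]
  if (any(c(dm, cc, ret) < 0, na.rm = TRUE)) stop("negative C-input data")
  life <- if (species@lifecycle == "perennial") species@lifetimeYr else 1

  per_fraction <- dm * cc * ret
  div <- c(product = life, stem = life,
           leaf = if (species@deciduous) 1 else life)
  above <- sum(per_fraction[c("product", "stem", "leaf")] /
                 div[c("product", "stem", "leaf")])
  root <- per_fraction[["root"]] * rhizodeposition_mult / life
  list(aboveground = above, root = root, annual = above + root)
}
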