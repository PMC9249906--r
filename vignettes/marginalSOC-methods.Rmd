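---
title: "Methods: identifying, matching and simulating SOC sequestration on marginal land"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying, matching and simulating SOC sequestration on marginal land}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginalSOC)
```

`marginalSOC` estimates how much soil organic carbon (SOC) could be
sequestered, net of water erosion, by planting candidate species on
SOC-deficient marginal land. This vignette explains the models and the
choices behind them; the README shows the surface workflow.

## Identification of marginal land

Marginal land is defined here as land currently unused by agriculture —
bare or sparsely vegetated covers, plus recently abandoned cropland —
that is SOC-deficient and not otherwise off limits. Five filters compose
`identifyMarginalLand()`:

1. *Candidate covers.* Cells whose land-cover role is `bare` or `sparse`
   (vegetation below 15 %). The role of each raster code is
   configuration (`landcover_legend.csv`, shipped with an ESA-CCI-style
   22-class default), not a constant: regional land-cover products use
   different codings.
2. *Abandonment.* Cells that were cropland in the earlier epoch and
   transitioned to mosaic cropland/natural vegetation, grassland, sparse
   vegetation, bare area, mosaic herbaceous cover or shrubland in the
   later epoch.
3. *SOC deficiency.* `0 < SOC ≤ 50` Mg C ha⁻¹ (to 30 cm), binned in
   10 Mg ha⁻¹ classes by `ceiling(SOC/10)`; the 50 bound is inclusive.
   SOC exactly 0 is treated as no-soil/nodata and excluded — gridded SOC
   products use 0 both ways, and a zero stock cannot initialise the
   turnover model. Negative cells are reported and dropped.
4. *Protection.* Any non-zero code in the protected-area layer excludes
   the cell.
5. *Problem land.* Codes carrying (sub-)severe soil/terrain restrictions
   (too cold, too dry, slopes > 30 %, shallow, poorly drained,
   saline/sodic, acid sulphate, peats, desert alluvium) exclude the
   cell; the severity set is configuration (`problem_land.csv`).

Filters 3–5 are pure intersections, so their order is irrelevant (this is
tested). A cell qualifying both as bare/sparse and as abandoned keeps
provenance `abandoned` (precedence abandoned > sparse > bare): the three
shares are reported separately and abandonment is the rarest, most
informative signal.

## Consolidation

Retained cells are labelled with world-region and Global Ecological Zone
(GEZ) codes and consolidated per occupied pair. Continuous attributes and
the 12 monthly climate normals are **area-weighted** means (the 30 arcsec
geographic grids this workflow targets have latitude-dependent cell areas;
we approximate cell area by scaling the east–west edge with the cosine of
the cell-centre latitude). Texture takes the area-weighted mode, ties to
the smaller code. Water and polar GEZ codes are excluded by default. A
zone whose attribute is missing everywhere keeps `NA` and is flagged
unusable for matching rather than silently non-matching.

Monthly normals (not annual scalars) are stored per target area because
the turnover model steps monthly; matching reduces them as needed.

## Species characterisation and carbon inputs

A species record carries ECOCROP-style *absolute* tolerance ranges
(temperature, precipitation, pH, texture classes, altitude, compatible
climate zones). Absolute rather than optimal bounds are used for
matching: the criterion is biophysical possibility, not yield optimality.
Köppen-based climate-zone entries are harmonised to GEZ codes through an
editable many-to-many table (`koppen_gez.csv`).

Annual carbon input to the soil follows dry-matter fractioning and carbon
partitioning: for each fraction *f* ∈ {product, stem, leaf, root},
`C_f = DM_f × %C_f/100 × return_f`. Annuals return every fraction each
year. Perennials are annualised linearly over the rotation lifetime
(uneven-aged stand assumption), with one exception: deciduous leaves are
shed and returned every year, so their stated mass enters annually
undivided. Root carbon always remains in the soil over the rotation and
is annualised as total root C / lifetime. Rhizodeposition can be folded
into the root compartment by a multiplier (default 1 = off, since the
four-fraction scheme does not name it).

Life forms map to three land-use classes (grass, crop, tree) that select
the DPM/RPM input ratio of the turnover model; small woody or herbaceous
shrubs count as grass, tree-like woody shrubs as tree.

## Matching

`isMatch()` tests six binary criteria; all must pass. Temperature is
screened on the mean annual value by default — monthly extremes are
available behind `temp_screen = "monthly_extremes"` for stricter
screening, but the default mirrors annual-tolerance databases. Texture is
set membership of the area's modal class (no partial credit). The
altitude lower bound defaults to −500 m when a record omits it (below any
land surface). `matchAll()` is the plain cross product and is verified
against a brute-force double loop on random panels.

## Five-pool turnover model

The monthly model follows RothC v26.3 semantics. Pools: DPM, RPM, BIO,
HUM active, IOM inert. Per month each active pool decays by
`exp(−a·b·c·k/12)`:

* rate constants `k` = 10 (DPM), 0.3 (RPM), 0.66 (BIO), 0.02 (HUM) yr⁻¹;
* `a(T) = 47.91/(1 + exp(106.06/(T + 18.27)))`, set to 0 at and below
  −18.27 °C (the singularity is treated as frozen inactivity);
* `b` from the accumulated topsoil moisture deficit: each month the
  deficit accumulates `P − PET`, clamped to `[maxTSMD, 0]` with
  `maxTSMD = −(20 + 1.3·clay − 0.01·clay²)·depth/23`, divided by 1.8 in
  uncovered months; `b = 1` while the deficit is shallower than 0.444 of
  capacity, then ramps linearly to 0.2;
* `c` = 0.6 in covered months, 1.0 bare.

Decomposed carbon splits into CO₂ and BIO/HUM by
`x = 1.67(1.85 + 1.60·e^{−0.0786·clay})` (CO₂ share `x/(x+1)`; the
retained part splits 0.46/0.54 into BIO/HUM). Plant input enters DPM:RPM
at `ratio/(1+ratio) : 1/(1+ratio)` — 1.44 for crop and grass, 0.25 for
tree, overridable per run. Decay precedes input within a month, so new
material starts decomposing the following month; mass balance
`Δtotal = input − CO₂` is exact by construction and asserted to 10⁻⁹
relative over 80-year runs.

The evapotranspiration input is used directly (a potential-ET product is
assumed); the classical 0.75 open-pan correction is available via
`rothcParams(pan_correction = 0.75)`.

One simplification: the accumulated deficit is clamped to the *current*
month's capacity, so an already-drier soil entering a bare month is
pulled up to the bare cap; the canonical bookkeeping would hold the
deficit until rain. At monthly normals recycled over decades the
difference is negligible relative to the consolidation uncertainty.

### Initialisation

Pools are initialised from total SOC by pedotransfer regressions: IOM by
Falloon (`0.049·SOC^1.139`); RPM, HUM, BIO from published SOC+clay
regressions; DPM is the remainder so pools sum to SOC exactly. When the
regressions overshoot, DPM floors at 0 and RPM/HUM/BIO are rescaled
proportionally onto `SOC − IOM` (IOM is kept: it is the best-constrained
regression). The regression set is an argument of `initPools()` so an
alternative supplement can be swapped in.

### Horizon and climate

The 2020–2100 horizon is simulated as 80 years of recycled 12-month
normals (near-term climate; future-climate trajectories are out of
scope). The annual carbon input is spread evenly over the species'
cover months (all twelve if unspecified) — the input calendar is not
specified by tolerance databases, and concentrating inputs in the growing
season is the least-surprising default.

## Erosion coupling

Water-erosion SOC losses rescale a mapped RUSLE-based soil-loss rate by
the species' cover-management factor, `e_adj = e_map·C_new/C_ref`
(`C_ref` defaults to 0.5, consistent with bare/sparse reference covers),
convert soil mass to carbon through the topsoil concentration
`SOC_y/(BD·depth·100)` with enrichment ratio 1 by default, and accumulate
over end-of-year simulated stocks. Coupling is *offline* by default —
losses are bookkept, not removed from the pools — because the framework
reports "final SOC prior to erosion" and "eroded SOC" as separate
quantities and nets them. An online mode (losses removed proportionally
from all pools yearly) exists behind `coupling = "online"` for
sensitivity work; there the reported final stock is already net.

Net SOC = final SOC − cumulative eroded SOC; a pair is net-positive when
this exceeds zero, which can coexist with a drawdown of the initial stock
(flagged `initial_loss_flag`). Best cases take the net-positive argmax
per target area, ties broken by taxon name for determinism. The paired
*t* test compares initial and final stocks across best cases; zero-
variance differences are flagged degenerate instead of reporting a
p-value. Report percentages round half-up to integer percent and rates
to 2 decimals, and numerators/denominators are always emitted alongside.

## Synthetic world: what it emulates, and what not

`makeSyntheticWorld()` is a pure function of (config, seed): a geographic
grid (default 100 × 100 at 0.05°) with region bands, GEZ bands
(tropical shrubland, subtropical steppe, temperate steppe by default),
land covers drawn at realistic shares, planted cropland-abandonment
transitions, SOC spanning the deficiency cutoff (2–70 Mg C ha⁻¹),
protected (8 %) and severe-problem (10 %) exclusions, HWSD-like soil
attributes, and sinusoidal monthly climate normals per zone. Soil-loss
rates span 1–80 Mg ha⁻¹ yr⁻¹ — global RUSLE-based maps reach such rates
in water-erosion hotspots on unprotected soil — so that erosion defeats
sequestration for a substantial minority of pairs, as in the motivating
global analysis.

Ground truth (marginal cells by provenance, consolidated attributes, the
match matrix, net-SOC outcomes) is derived inside the generator by
independent per-cell scalar loops, not by calling the pipeline; the
end-to-end tests require the pipeline to recover it exactly. The species
panel places tolerance cuts strictly between attained attribute values,
so no criterion sits on a floating-point boundary.

What the toy world does **not** emulate: real geography and spatial
autocorrelation, mixed-resolution inputs (e.g. 300 m land cover against
25 km soil loss), cell-level climate gradients within a zone, curated
trait data, and the scale of the global problem. Passing tests therefore
demonstrate correctness of the machinery, not calibration of global
estimates.

## Numerical choices and degenerate inputs

* Grids are regular, north-up, cell-centre referenced; row 1 is the
  northernmost row. No reprojection: cross-CRS alignment is an error,
  and all cross-layer operations require prior alignment.
* Continuous resampling is a separable area-weighted mean with
  missing-cell exclusion; categorical resampling is nearest-neighbour.
* Zonal and consolidation modes break ties toward the smallest code;
  best-case ties break by taxon name.
* An SOC stock small enough that Falloon IOM ≥ SOC initialises as
  all-inert.
* Unevaluable matches (missing area attributes) are explicit `NA`
  results, never silent non-matches; dropped cells (missing zones) are
  counted and logged.
* Problem sizes: the default test suite runs the full pipeline on
  20 × 20 and 100 × 100 worlds and 400-year equilibrium runs; an 80-year
  pair simulation takes ~20 ms.

## Known limitations

Semi-quantitative biopump preselection scoring, future-climate scenarios,
carbon-saturating soil models, wind erosion and invasive-species risk are
out of scope. The turnover model is non-saturating, so very high carbon
inputs extrapolate optimistically. The exact pedotransfer constants and
erosion-method details of any particular study supplement can be supplied
via the configurable regression set and enrichment/cover parameters.
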