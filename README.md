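# marginalSOC

Spatially explicit exploration of soil organic carbon (SOC) sequestration
on marginal land.

Large areas of the world's bare, sparsely vegetated and abandoned
agricultural land hold SOC-deficient soils (≤ 50 Mg C ha⁻¹ to 30 cm).
Planting such land with species chosen for their carbon inputs could turn
it into a carbon sink — provided the species tolerate the local pedoclimate
and the gain is not undone by water erosion. `marginalSOC` implements the
whole decision chain for researchers in land-based carbon-dioxide removal
and land-use planning:

1. **Identify** marginal land from gridded inputs: bare/sparse covers,
   cropland-abandonment transitions between two land-cover epochs,
   SOC-deficiency filtering in 10 Mg ha⁻¹ classes, and exclusion of
   protected areas and (sub-)severe problem land.
2. **Consolidate** the retained cells into target areas keyed by world
   region × FAO Global Ecological Zone (GEZ), with area-weighted
   pedoclimatic attributes.
3. **Characterise species** ("biopumps"): tolerance ranges, life form, and
   annual carbon input to the soil by dry-matter fractioning and carbon
   partitioning (product/stem/leaf above ground, roots below).
4. **Match** every species to every target area on six criteria: mean
   annual temperature, annual precipitation, pH, texture, elevation and
   climate-zone compatibility.
5. **Simulate** 2020–2100 SOC dynamics per matched pair with the five-pool
   monthly RothC (v26.3) turnover model, initialised by pedotransfer
   functions, subtract cumulative SOC losses from water erosion
   (RUSLE cover-factor rescaling of a mapped soil-loss rate), and report
   net-SOC best-case combinations with a paired *t* test.

## The model core

RothC tracks five pools — decomposable plant material (DPM), resistant
plant material (RPM), microbial biomass (BIO), humified organic matter
(HUM) and inert organic matter (IOM). Each month every active pool decays
by `exp(−a·b·c·k/12)`, where `k` is the pool's rate constant
(10, 0.3, 0.66, 0.02 yr⁻¹), `a` the temperature modifier
`47.91 / (1 + exp(106.06/(T + 18.27)))`, `b` the topsoil-moisture-deficit
modifier (1 down to 0.2), and `c` the soil-cover modifier (0.6 covered,
1.0 bare). Decomposed carbon splits into respired CO₂ and BIO/HUM
transfers by the clay-dependent ratio `x = 1.67(1.85 + 1.60 e^{−0.0786·clay})`;
plant inputs enter DPM:RPM at a land-use ratio (1.44 crop/grass, 0.25
tree). Pools are initialised from total SOC by pedotransfer regressions
(IOM via Falloon's `0.049·SOC^1.139`). Erosion is coupled offline:
`loss_y = e_adj · SOC_y / (BD · depth · 100)` with
`e_adj = e_map · C_new / C_ref`, and
`net SOC = final SOC − Σ loss_y`.

## Worked example

The deterministic synthetic-world generator creates toy rasters, climate
normals and an engineered species panel with machine-readable ground
truth, then the pipeline runs end to end:

```r
library(marginalSOC)
world <- makeSyntheticWorld(syntheticWorldConfig(nrow = 40, ncol = 40),
                            seed = 11)
panel <- makeSpeciesPanel(world)
pl <- runPipeline(world, panel, horizon_years = 80)

pl$marginal$composition
#>   provenance cells   area_ha share_pct
#> 1       bare   206 547077.39 54.654359
#> 2     sparse   157 416731.06 41.632444
#> 3  abandoned    14  37168.24  3.713197

pl$areas[[1]]
#> TargetArea 1 x SBSh: 108842.2 ha
#>   MAT 18.0 degC, MAP 420 mm, pH 6.69, clay 26.2%, medium texture
#>   SOC0 25.9 Mg C/ha, soil loss 44.27 Mg/ha/yr, elev 216 m

rep <- pl$report
sprintf("theoretical %d | viable %d | net-positive %d | best cases %d",
        rep$n_theoretical, rep$n_viable, rep$n_net_positive,
        rep$n_best_cases)
#> "theoretical 72 | viable 41 | net-positive 32 | best cases 9"

head(pl$best[, c("region_id", "gez_id", "taxon", "net_soc")], 3)
#>   region_id gez_id              taxon  net_soc
#> 1         1   SBSh      Acacia calida 70.72030
#> 2         1   TBSh Medicago basophila 19.01718
#> 3         1  TeBSk        Zea frigida 45.31247

pairedTTest(pl$best$soc_init, pl$best$soc_final)$t
#> [1] 3.268575
```

The composition table says where the marginal land came from (bare vs
sparse vs abandoned cropland); each `TargetArea` is one region × GEZ unit
with its area-weighted attributes; `net_soc` is the simulated 2100 SOC
stock prior to erosion minus the cumulative eroded carbon, in Mg C ha⁻¹;
the best-case table keeps the top net-positive species per area.

A thin command-line front end over the same functions lives at
`inst/scripts/soc-pipeline.R`
(`Rscript soc-pipeline.R run --dir world --seed 1`).

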