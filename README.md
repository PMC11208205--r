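# landesca

Cellular-automaton land-use change scenarios with perception-based
ecosystem-service assessment, for mosaic landscapes under rubber-plantation
and settlement expansion.

## What it does, and for whom

`landesca` is for landscape ecologists and land-use planners who want to turn
stakeholder-elicited knowledge — "cropland next to a rubber plantation in the
rural west converts to rubber with probability 85 %" — into spatially
explicit business-as-usual (BAU) projections and ecosystem-service (ES)
trade-off summaries. It implements the full chain:

1. **Landscape**: a categorical land-cover raster (ESRI ASCII) with a zone
   mask (WEST / EAST / road CORRIDOR). A seeded synthetic generator produces
   calibrated fixtures for a coastal West African municipality: eight classes
   at fixed area shares, rubber concentrated in the west, settlement in the
   east along a road corridor, one contiguous forest reserve, coastal
   mangrove wetland.
2. **Cellular automaton**: transition rules (source class, target class,
   probability *p*, minimum Moore-neighbor count of the target, allowed
   zones), applied synchronously; each eligible cell converts independently
   with probability *p*, so one step is Binomial(n_eligible, p) per rule.
   One iteration represents 5 years; 10 iterations project 50 years.
3. **ES scoring**: a (class × service) assessment matrix on a common 0–100
   capacity scale, built from elicited percentages, 0–5 Likert ratings
   (v = 20·score), Delphi expert means (soil quality) and the
   Shannon–Wiener diversity index H = −Σ pᵢ ln pᵢ rescaled by its cross-class
   maximum (species diversity). The landscape score of service *s* is the
   mean capacity over cells, E_s = Σ_l (A_l/100)·v(l,s) with A_l the area
   share of class *l*.
4. **Reporting**: area-change tables (percentage points vs. baseline,
   summing to zero by conservation), ES balance tables (spider-chart data),
   INCREASE/DECREASE/STABLE trade-off classification, and a reproducible
   `run_bau()` pipeline that writes rasters, CSVs and a manifest.

## Worked example

```r
library(landesca)

ls  <- generate_baseline_landscape(landscape_spec(seed = 42))
ls$grid
#> landscape_grid: 243 x 243 cells (59049 non-nodata), cell size 100 m
#> area: 590.5 km^2; classes: Settlement, Rubber plantations, Palm vegetation,
#>   Cropland, Forest, Shrubland, Waterbody, Wetlands

area_shares(ls$grid)          # calibrated composition (%; rounded)
#>                name share
#>          Settlement  7.61
#>  Rubber plantations 27.35
#>     Palm vegetation 19.67
#>            Cropland 22.26
#>              Forest  9.09
#>           Shrubland 11.46
#>           Waterbody  0.55
#>            Wetlands  2.00

mat <- default_es_matrix()    # packaged perception-based assessment matrix
res <- run_scenario(ls$grid, ls$mask, rubber_ruleset(), 10, seed = 1)
res
#> scenario_result: 'rubber_expansion', 10 iterations (50 years), seed 1

act <- area_change_table(res, c(2, 5, 10))
act[act$iteration == 10, ]    # area change at 50 years (pp vs. baseline)
#>                name share delta
#>          Settlement  7.61  0.00
#>  Rubber plantations 45.69 18.34
#>     Palm vegetation 13.39 -6.28
#>            Cropland 14.61 -7.65
#>              Forest  9.09  0.00
#>           Shrubland  7.05 -4.41
#>           Waterbody  0.55  0.00
#>            Wetlands  2.00  0.00

bal <- es_balance_table(res, mat, c(2, 5, 10))
classify_tradeoffs(bal, 10)
#>         service_id  delta classification
#>               food -13.18       DECREASE
#>         marketable   7.84       INCREASE
#>           fuelwood  -3.67       DECREASE
#>       soil_quality  -6.34       DECREASE
#>  species_diversity  -7.63       DECREASE
```

Reading: fifty simulated years of frontier-driven rubber expansion in the
western zone convert 18.3 percentage points of the landscape to rubber at the
expense of cropland, palm and shrubland (forest, wetland and waterbody are
never rule sources and stay fixed). Marketable products rise as the single
trade-off; food provision falls most, and every other service declines — the
characteristic BAU signature. The settlement scenario
(`settlement_ruleset()`) depresses all five services.

The whole pipeline is a pure function of (landscape, rule set, matrix,
iterations, seed): rerunning any step with the same seed reproduces outputs
byte-for-byte. A YAML-driven runner (`run_bau()`) and a thin CLI
(`inst/scripts/landesca` with `generate` / `simulate` / `assess` / `run-bau`
subcommands) wrap the same functions.

See `vignettes/landesca-methods.Rmd` for the model's assumptions, the
synthetic generator's conventions, and what the packaged perception fixtures
do and do not represent.

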