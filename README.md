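# tigersim

Roads and railways kill large carnivores directly and push their prey away.
`tigersim` is a spatially explicit, individual-based simulator built to ask
what that means for an isolated tiger (*Panthera tigris*) population of the
kind found in Nepal's Chitwan National Park: breeding females hold exclusive
territories sized to meet a monthly prey requirement on a 250 m
prey-biomass-production raster, males hold harems of up to six females and
fight over them, and transport infrastructure acts on the population through
two switchable mechanisms:

* **territory-intersection mortality** — a breeding female whose territory
  contains a primary-road or railway cell has her annual survival reduced
  from 0.9 to 0.297; a secondary road reduces it to 0.81 (the larger
  reduction wins when both intersect);
* **distance-decay prey depletion** — effective prey is 0 on a road and
  recovers linearly to the undisturbed level at 5 km from a primary road or
  railway and 2 km from a secondary road, with the minimum multiplier taken
  where zones overlap.

The model steps monthly (annual rates enter as `annual^(1/12)`). A scenario
runs 600 inert burn-in months (roads drawn but harmless), switches the
configured mechanisms on instantaneously at month 601, and records a
240-month experiment: per-step counts of adults, breeding females and
dependent offspring, a death log with the territory-road intersection at
death, and per-cell occupancy (the proportion of experiment months a cell
belonged to any female territory). Experiments are replicated (28 by
default, seeds `base_seed + r`) and reduced to t-based confidence bands,
Wilcoxon comparisons, road-attributed mortality proportions and near/far
road occupancy strata.

Demography follows long-term Chitwan field values: litters of 2–5
(0.23/0.58/0.17/0.02), 50:50 sex ratio, gestation 3–4 months, stage classes
cub/juvenile/transient/breeding at 12/24/36 months, class-specific annual
survival (cub 0.6, juvenile 0.9, transient female 0.7, male 0.65, breeding
female 0.9, resident male 0.8), natal dispersal caps of 33 km (females) and
66 km (males), greedy territory growth of at most 48 cells (3 km²) per
month until the utilized prey (10% of territory production) meets the
76 kg/month basal requirement, patch contests won by older females with
probability 0.25, male challenges decided by age-dependent strength, and
infanticide of cubs (0.79) and juveniles (0.24) after a takeover.

Because the real Chitwan prey raster and road layers are not bundled, a
synthetic-landscape generator reproduces their printed statistics: a 27,240
cell (30 × 56.75 km) raster with production 0–10.46 kg/month averaging
3.78, about 198 km of primary roads (including the proposed railway
corridor) and 723 km of secondary roads concentrated in a settled northern
band, with mean prey lower near roads (≈2.7) than far from them (≈4.8).
Real layers, if you have them, enter through the same interfaces: ESRI
ASCII grids (`read_ascii_grid()`) and GeoJSON LineStrings tagged
`road_class` (`read_roads_geojson()` + `rasterize_roads()`).

## A worked example

```r
library(tigersim)

land <- generate_landscape(synth_spec())
land$prey
#> <prey_grid> 120 x 227 cells of 250 m; production 0-10.5, mean 3.78 kg/month
land$roads
#> <road_layer> 120 x 227 cells; 689 primary, 2094 secondary road cells; 165.0 / 723.6 km

cfg  <- scenario_config(mechanisms = "mortality", burn_in = 600,
                        experiment = 240, replicates = 2, landscape = land)
runs <- run_replicates(cfg, land)
runs[[1]]
#> <tiger_run> seed 2, mechanisms {mortality}; end: 56 adults, 35 breeding females, 61 dependents; 5072 deaths

subset(population_summary(runs), step == 840)
#>      step            group mean       lo       hi n
#> 840   840           adults 57.5 38.44069 76.55931 2
#> 1680  840 breeding_females 35.5 29.14690 41.85310 2
#> 2520  840       dependents 61.5 55.14690 67.85310 2

occ <- occupancy_map(runs)
occupancy_strata(occ, near_road_mask(land$roads))
#>      near       far
#> 0.1958632 0.4038429
```

Read: with road mortality switched on after burn-in, the adult population
falls to a mean of 57.5 animals (95% CI 38.4–76.6 over these two quick
replicates) from a baseline that holds ~150, and female occupancy within
the road-effect zone (2 km of a secondary or 5 km of a primary road)
collapses to 0.20 while the interior keeps 0.40. Compare scenarios with

```r
base <- run_replicates(scenario_config(landscape = land, replicates = 28), land)
mort <- run_replicates(scenario_config(mechanisms = "mortality",
                                       landscape = land, replicates = 28), land)
total_deaths_comparison(base, mort)          # Wilcoxon on end adult counts
road_mortality_proportion(mort)              # annual road-attributed shares
```

A thin command-line front end is installed with the package
(`system.file("cli", "tigersim", package = "tigersim")`) with `synth`,
`simulate` and `report` subcommands writing `counts.csv`, `deaths.csv`,
`occupancy.asc` and summary tables.

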