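# sticklesim

Agent-based bioenergetics simulation of three-spined stickleback
(*Gasterosteus aculeatus*) populations under projected climate heating.

Climate warming acts on a freshwater fish population through two
coupled pathways: directly, because an ectotherm's metabolic and
ingestion rates scale with temperature, and indirectly, because the
production of its invertebrate prey also rises with temperature.
`sticklesim` is for ecological modellers who want both pathways in one
mechanistic, individual-based framework: it builds latitude- and
warming-dependent driver scenarios from published empirical
regressions, simulates a stickleback population day by day on a patchy
20 m² habitat, and runs the full warm-up / treatment / replication /
pre-breeding-census experiment design, so that population-level
consequences of IPCC warming levels (+1.4, +2.7, +4.4 °C by 2100)
emerge from individual energy budgets and competition.

## The model in brief

**Scenario engine.** A latitude `Lat` (°N) and warming level `dT` (°C)
determine the drivers through three regressions:

- GPP = 38.13 · Lat + 88.0  (gross primary production, mg C m⁻² d⁻¹)
- PCP = 0.02 · GPP + 9.04  (primary consumer production, mg C m⁻² d⁻¹)
- log₁₀ B = 0.138 · T + 1.090  (macroinvertebrate biomass, mg m⁻²)

PCP, spread over the 20 m² system and its 50 vegetated (food-bearing)
patches, gives annual mean food densities of 0.0196 / 0.0211 / 0.0226
g patch⁻¹ d⁻¹ at 50 / 55 / 60 °N; warming multiplies food by
10^(0.138·dT) (log₁₀ offsets 1.28 / 1.46 / 1.70 at the three IPCC
levels). A bootstrap (5000 resamples) quantifies the robustness of the
noisy GPP–latitude slope.

**Fish agent.** Each fish runs a daily energy cascade — ingestion
(allometric `m^0.75`, Q10 = 2 with an upper thermal taper),
assimilation (70%), maintenance (untapered Q10, so warming raises
costs monotonically), reproduction, rate- and size-capped growth, and
reserve storage — with an exactly balancing energy ledger. Fish forage
by the ideal free distribution over vegetated patches, share limited
patch food in proportion to demand, males compete for one nest
territory per vegetated patch, and survival combines stage-specific
background rates, a weak density penalty, starvation and senescence.
Carrying capacity is emergent, set by the daily food production.

All bioenergetic constants are documented package defaults, not values
fitted to any field dataset; every one is overridable in code or
through a YAML profile.

## Worked example

```r
library(sticklesim)

## a warming scenario: 60 degrees N under the +4.4 degC IPCC level
sc <- build_scenario(60, 4.4)
sc
#> scenario: 60 degN, dT = 4.4 degC | annual mean food 0.0916 g/patch/d
#>   temp (degC): 5.4 6.3 8.9 12.4 15.9 18.5 19.4 18.5 15.9 12.4 8.9 6.3
#>   food (g)   : 0.0522 0.0575 0.0719 0.0916 0.1113 0.1257 0.1309 0.1257 0.1113 0.0916 0.0719 0.0575
```

The annual mean food is the 60 °N baseline (0.0226 g patch⁻¹ d⁻¹)
times the +4.4 °C food factor 10^0.6072 ≈ 4.05; temperatures are the
baseline monthly series + 4.4 °C.

```r
## a short population simulation with annual April-1 censuses
out <- simulate_population(build_scenario(55, 0), years = 3, seed = 1)
out$census
#>   year abundance density  biomass mean_metabolic_rate
#> 1    1        36    1.80 2.924800            48.21757
#> 2    2       110    5.50 6.983617            40.31731
#> 3    3       167    8.35 7.377667            30.74633
```

`density` is post-larval fish m⁻², `biomass` g m⁻², and
`mean_metabolic_rate` the mean individual maintenance cost
(J d⁻¹ fish⁻¹) at the census temperature; the population climbs from
its 36-fish initialisation towards the food-set carrying capacity
(about 7–8 fish m⁻² at present-day 55 °N).

```r
## the full (scaled-down) warming experiment
cfg <- experiment_config(latitudes = c(50, 55, 60),
                         delta_ts = c(0, 1.4, 2.7, 4.4),
                         warmup_years = 5, treatment_years = 5,
                         n_replicates = 5, base_seed = 1)
census <- run_experiment(cfg)
summarize_final_census(census)   # means, SDs, percent change vs control
detect_effect(subset(census, latitude == 60 & delta_t == 0),
              subset(census, latitude == 60 & delta_t == 4.4),
              endpoint = "density")   # 5% detection rule
```

Under the default calibration, warming raises final pre-breeding
density and biomass at all three latitudes (most strongly at 60 °N),
and mean individual metabolic rate rises with warming within each
latitude while falling with latitude at present-day temperatures.

## Package layout

- `R/scenario.R`, `R/bootstrap.R` — scenario engine and bootstrap
- `R/landscape.R` — patch grid, food renewal and depletion
- `R/bioenergetics.R`, `R/params.R` — physiological rates and parameters
- `R/population.R`, `R/simulate.R` — agents, daily schedule, driver
- `R/experiment.R` — experiment design, censuses, effect detection
- `R/synthetic.R` — synthetic drivers (temperatures, GPP datasets,
  ration fixtures)
- `R/config.R` — YAML configuration profiles
  (`inst/extdata/example_config.yaml`)
- `vignettes/warming-bioenergetics.Rmd` — full methods description

## License

MIT
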