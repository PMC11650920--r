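---
title: "Methods: scenario construction and the bioenergetics agent-based model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario construction and the bioenergetics agent-based model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sticklesim)
```

## What the package models

`sticklesim` asks how projected climate heating changes the density and
biomass of an enclosed three-spined stickleback (*Gasterosteus
aculeatus*) population when warming acts twice: directly on the fish's
physiology (metabolic and ingestion rates rise with temperature) and
indirectly through the food web (invertebrate prey production also
rises with temperature). Both pathways are driven from published
empirical regressions, so a single latitude and an IPCC warming level
fully determine the drivers of a simulation.

The habitat is a 20 m^2^ enclosed freshwater system of 500 patches of
20 × 20 cm, one tenth of them vegetated; only vegetated patches carry
food. Fish are discrete agents with a daily schedule: move, eat,
allocate energy, grow, develop, breed, survive. Population dynamics —
including carrying capacity — are emergent, arising from competition
for the daily food production and for nest sites.

## Scenario engine

Three regressions turn latitude (`Lat`, degrees N) and a temperature
rise (`dT`, degrees C) into driver schedules:

* gross primary production: `GPP = 38.13 Lat + 88.0` (mg C m^-2^ d^-1^),
* primary consumer production: `PCP = 0.02 GPP + 9.04` (mg C m^-2^ d^-1^),
* macroinvertebrate biomass: `log10 B = 0.138 T + 1.090` (mg m^-2^).

`PCP` is spread over the habitat area and divided among the 50
vegetated patches, carbon production taken 1:1 as available food mass
(a configurable conversion factor defaults to 1). This yields annual
mean food densities of 0.0196, 0.0211 and 0.0226 g patch^-1^ d^-1^ at
50, 55 and 60 degrees N.

The temperature dependence of invertebrate biomass implies a warming
offset of `1.090 + 0.138 dT` on the log10 scale (1.28 / 1.46 / 1.70 at
the IPCC 2100 levels 1.4 / 2.7 / 4.4 degrees C). Removing the baseline
intercept and back-transforming gives a clean multiplicative food
factor `10^(0.138 dT)`. We adopt that multiplicative reading — an
additive-biomass formulation would have to say what baseline is
subtracted before back-transforming — and apply the factor to every
monthly food value, which
is equivalent to applying it to the annual mean because monthly values
are a rescaled seasonal shape. Both the offset and the factor are
exported (`warming_log10_offset()`, `warming_food_factor()`).

No measured monthly series ship with the package, so baselines are
explicit package conventions:
temperatures follow a sinusoid with a July peak, amplitude 7 degrees C
and annual means of 11 / 9.5 / 8 degrees C at 50 / 55 / 60 degrees N;
the within-year food shape is a summer-peaking sinusoid with its winter
minimum at 40% of its July maximum. Users with measured monthly tables
supply them via `build_scenario()` or `scenario_from_drivers()`, and a
scenario's food schedule is always rescaled so its mean matches the
regression-derived (warming-adjusted) annual mean.

The robustness of the noisy production-latitude trend is quantified by
a case-resampling bootstrap: `bootstrap_slope()` resamples the
(latitude, GPP) rows with replacement (5000 resamples by default),
refits the ordinary-least-squares slope each time, and reports the bias
and the bootstrap SE relative to the full-data slope.
`make_gpp_dataset()` emulates the global compilation (27 sites,
latitudes 18–78 degrees N, residual noise solved to give R^2^ of about
0.16 over that range).

## The fish agent

Each post-larval fish carries structural mass `m` (g), reserves (J), a
gonad store (J, females), length (mm, from `m = a L^3`), age, stage,
sex and a patch position. Physiological rates scale allometrically
(`m^0.75`) and with temperature via Q10 = 2 factors referenced to
15 degrees C inside a thermal window (CT~min~ 0, CT~opt~ 23, CT~max~
30 degrees C):

* **Ingestion** (and growth and egg/larval development) uses a Q10
  multiplier that tapers linearly to zero between CT~opt~ and CT~max~:
  performance saturates and collapses near the upper limit while
  remaining continuous in temperature.
* **Maintenance** uses the untapered Q10 factor up to CT~max~, so
  metabolic cost rises monotonically with warming — the mechanism by
  which heating squeezes energy budgets at warm, food-poor sites.

The daily energy cascade follows a fixed priority order:
maintenance (reserves buffer any shortfall; an unpayable remainder
flags the fish for starvation death), then reproduction (breeding
females route surplus to the gonad up to a daily quota of
30 J g^-0.75^), then growth (surplus converted to structure at
5000 J g^-1^, rate-capped at 0.025 g g^-0.75^ d^-1^ and bounded by an
asymptotic length of 60 mm), then storage (reserves up to 20% of body
mass at 7000 J g^-1^; residue is discarded as overflow). The per-fish
ledger satisfies, exactly,

```
assimilated = maintenance + reproduction + growth + storage_delta + overflow
```

where `maintenance` is energy actually expended and `storage_delta` the
realised reserve change. We record discarded `overflow` and unpayable
`deficit` as explicit ledger columns rather than folding them into the
other terms: a strict four-term identity cannot hold when storage is at
capacity or reserves are exhausted, and an explicit residual keeps the
conservation check exact to 1e-9 J rather than approximate.

Foraging follows the ideal free distribution: mobile post-larval fish
are redistributed daily over vegetated patches by sequential best
response in random order, each taking the patch maximising expected
intake (patch food over competitors + 1). When all patches carry equal
food — the usual state after the daily reset — the equilibrium is a
balanced occupancy and is computed directly; the closed-form
input-matching occupancy (`ifd_expected_occupancy()`) is used only as a
test oracle. When joint demand on a patch exceeds its stock, the stock
is split in proportion to demand (scramble competition).

Reproduction is density dependent through nest sites: vegetated patches
are the nesting habitat, at most one territorial male each, surplus
males excluded that day. Ready females (clutch interval of 7 days
elapsed, gonad plus spare reserves covering the clutch cost) spawn
`round(60 eggs/g × mass)` eggs on a random territorial male's patch,
paying `eggs × 0.002 g × 5000 J/g`. Eggs and larvae develop at a
temperature-scaled daily rate (10 and 20 reference-temperature days)
and do not feed; metamorphosing juveniles start at about 0.01 g.

Survival multiplies a stage-specific daily background rate
(egg 0.02, larva 0.08, juvenile 0.008, adult 0.004) by a mild
Beverton–Holt-style penalty `1/(1 + γN/A)` with γ = 1e-4 m^2^ per fish.
Starved fish die deterministically; maximum age is three years.

## Calibration of the default parameter set

The published regressions fix the food supply, but no physiological
parameter table is bundled with this package; it ships its own
documented default set, chosen
once so that the *given* food supply (about 1 g of carbon-equivalent
food per day across the whole system at present-day 50–60 degrees N)
sustains a realistic, stable, food-limited population, and frozen
thereafter. Three choices matter most and were genuinely open:

* **Food energy density 20 kJ/g.** The scenario food mass is carbon
  production taken 1:1 as food, so the energy density is referenced to
  carbon-equivalent mass (~40 kJ per g C in animal tissue; 20 kJ/g
  leaves margin for incomplete usability), not to wet prey mass.
* **Asymptotic length 60 mm with rate-limited growth.** Ingestion and
  maintenance share the 0.75 mass exponent, so without a size bound
  individual growth absorbs any food surplus and carrying capacity
  expresses itself as bigger fish rather than more fish. Bounding
  length at a realistic stickleback maximum routes surplus into
  reproduction and juvenile survival, which is what lets warming-driven
  food increases raise population *density* as well as biomass.
* **Weak direct density penalty (γ = 1e-4).** Regulation is meant to
  emerge from food competition and nest-site limitation; a strong
  abundance penalty would regulate numbers independently of food and
  mute the trophic pathway the model exists to study.

With these defaults a present-day 55 degrees N population settles at
about 7–8 post-larval fish per m^2^ (CV of pre-breeding density below
10% over warm-up years 6–10), and warming raises both density and
biomass at all three latitudes, most strongly at 60 degrees N, while
mean individual metabolic rate rises with warming and falls with
latitude. Absolute densities and percent changes are
parameter-dependent and are deliberately not asserted anywhere in the
tests; only these directions are.

## Experiment design

`run_experiment()` reproduces the study design: for each latitude ×
replicate a population is simulated through a warm-up under present-day
drivers (default 10 years; no results taken), then continued under each
temperature-rise level (0 is the control) for the treatment years
(default 10), with a pre-breeding census every April 1 recording
post-larval density, biomass per m^2^ and mean individual maintenance
cost (J d^-1^ fish^-1^) at the census temperature. The full default
design is 3 latitudes × 4 levels × 15 replicates × 10 census years =
1800 census rows.

Design details decided here: the warm-up state is shared across
temperature levels within a replicate and every continuation restarts
the same RNG stream (common random numbers), so treatment–control
contrasts are paired and the census table is independent of execution
order; "mean density over 10 years" averages the annual censuses within
replicate and then across replicates (the reverse aggregation order
differs negligibly); extinct replicates
stay in the means as zero-density rows; `detect_effect()` flags a
population-level effect when the decade-mean deviates from control by
more than 5%, and reports the final-year percent change alongside so
both aggregations are available.

Census metabolic rate is maintenance-only by design (total expenditure
depends on allocation bookkeeping; maintenance is the unambiguous
common denominator), and census density counts post-larval fish.

## Scaled-down test problem sizes

The automated checks run the full pipeline at reduced scale — 5-year
warm-up plus 5 treatment years, 5 replicates, all three latitudes and
all four warming levels — and test directions, not magnitudes: a
one-sided sign test across paired replicates for the density and
biomass increases at 60 degrees N, and strict orderings of mean
metabolic rate in warming level and latitude. Conservation checks
(energy ledger to 1e-9 J, daily food mass balance to 1e-12 g) run over
a two-year default simulation; bootstrap recovery uses the full 5000
resamples on the 27-site synthetic compilation.

## What the synthetic generators do and do not emulate

`make_monthly_temperatures()` and `make_gpp_dataset()` reproduce the
statistical *structure* the pipeline assumes — a sinusoidal seasonal
temperature cycle, and a linear production–latitude trend with large
site-to-site scatter. They do not emulate real-world features such as
inter-annual weather variation, autocorrelated residuals, heteroscedastic
scatter across latitudes, or the geographic clustering of the real
compilations. Passing tests therefore demonstrate that the pipeline is
correct and directionally faithful under its stated assumptions, not
that its magnitudes transfer to any particular river system.

## Known limitations

* All bioenergetic constants are package conventions, not fitted
  values; absolute densities, biomasses and percent changes move with
  them. Transcribe a measured parameter table into a YAML profile
  (`read_sim_config()`) for site-specific work.
* The system is closed: no migration, no predators, no genetic
  adaptation, no behavioural thermal responses, no hydrology.
* The 365-day calendar has no leap days and drivers step monthly, so
  within-month temperature variability is absent.
* Scramble food sharing and global (well-mixed) ideal-free movement
  ignore spatial structure beyond the vegetated/nonvegetated split;
  patch adjacency never matters.
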