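---
title: "tigersim: model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tigersim: model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Purpose and scope

`tigersim` simulates an isolated, territorial tiger population on a monthly
clock to forecast the demographic consequences of transport infrastructure.
Two mechanisms connect roads and railways to the population: reduced annual
survival of breeding females whose territories intersect infrastructure,
and linear depletion of prey within a road-effect zone. Everything else —
territory formation, male harems and challenges, reproduction, starvation —
is the substrate those mechanisms act on. The package is organised around
an explicit experiment protocol (burn-in, instantaneous activation,
replicated experiment window) so that scenarios differ *only* in which
mechanisms are switched on.

## State and scales

The landscape is a raster of 250 m cells carrying a static monthly prey
biomass production (kg/month per cell). Prey is held constant over time;
seasonal prey dynamics and predation feedbacks are out of scope. Roads are
a per-cell class raster (none / secondary / primary) rasterized from tagged
polylines; a proposed railway is rasterized as a primary road, an
assumption adopted for lack of railway-specific mortality estimates.
Distances are exact Euclidean distances between cell centers, computed with
a two-pass exact distance transform (verified in the test suite against
both a brute-force oracle and an independent image-processing
implementation).

Tigers are individuals with sex, age in months, and a stage that is a pure
function of age: cub (< 12 months), juvenile (12–23), transient (24–35),
breeding (36+). Cubs and juveniles are dependents: they live in their
mother's territory and die if she dies. Transients are book-kept at their
natal center and have no movement process. Only breeding females hold
territories — exclusive, rook-connected sets of cells; a male's "range" is
the set of up to six females he is associated with.

## Parameters

All rates live in `tiger_params()` and come from long-term field studies
(Chitwan, with some values from other large-carnivore systems):

| quantity | value |
|---|---|
| litter size 1–5 | 0 / 0.23 / 0.58 / 0.17 / 0.02; 50:50 sex ratio |
| gestation | 3 or 4 months, equal probability |
| annual survival | cub 0.6, juvenile 0.9, transient F 0.7, transient/dispersing M 0.65, breeding F 0.9, resident M 0.8 |
| road-adjusted survival (breeding F) | primary/railway 0.297, secondary 0.81 |
| annual breeding probability | 0.9 at age 3, 1.0 at 4+ |
| prey requirement | minimum 76, ceiling 167.3 kg/month; utilization 0.1 |
| territory growth | ≤ 48 cells/month; patch takeover probability 0.25 |
| dispersal caps | 33 km (F), 66 km (M) from natal center |
| settlement spacing | no other territory within 2 km (ideal), 1 km (relaxed) |
| male search radius | 3 km; ≤ 6 females per male |
| challenge deaths | challenger 0.25, incumbent 0.6 |
| infanticide after takeover | cub 0.79, juvenile 0.24 |
| depletion zone | 0 on the road, linear to 1 at 5 km (primary) / 2 km (secondary) |

The 76 and 167.3 kg/month thresholds derive from daily consumption
(2.5 and 5.5 kg/day × 365 / 12). Annual rates convert to monthly ones by
the twelfth root, which preserves compounded annual survival exactly.

## The monthly schedule

Each step executes, in fixed order: (1) age/stage advance; (2) survival
draws, starvation and orphan deaths; (3) release of dead owners' cells;
(4) settlement of dispersing females, territory expansion and patch
contests (older females first); (5) male range assembly, dispersal jumps,
challenges and infanticide; (6) conception, gestation, births; (7) metric
recording. Deaths precede settlement so that vacancies opened by road
mortality can be recolonized within the same month — the substrate of the
compensatory-immigration behaviour the experiments probe. A single RNG
stream per replicate, consumed in scheduler order, makes runs bit-identical
under a seed; the mechanism switches consume no randomness, so scenarios
that differ only in inert switches (e.g., any mechanism on a roadless
landscape) reproduce the baseline trajectory exactly.

## Territories

A female's territory grows greedily: each month she annexes the
frontier-adjacent unowned cell with the highest effective prey (ties
uniform at random), at most 48 cells per month, stopping once her utilized
prey — 10% of the territory's production sum — meets the 76 kg/month basal
requirement. On uniform prey at the landscape mean this stabilises
territories near 201 cells (≈ 12.6 km²), consistent with Chitwan field
scales. A frontier cell held by a younger female may be contested (taken
with probability 0.25); the loser's remnant is pruned to the rook-connected
component containing her origin cell, pruned cells becoming vacant.
Territories never shed cells voluntarily and are bounded at 1500 cells
(≈ 94 km²) — between Chitwan scales and the home ranges reported for
tigresses in low-prey Amur landscapes. The bound matters only in severely
depleted ground, where it decides that a female who cannot assemble enough
prey within ~94 km² starves rather than expanding without limit; the
experiment battery is sensitive to it in both directions (a tight bound
starves the whole road zone and overshoots the depletion effect, no bound
lets compensating territories blanket the zone and erases the occupancy
signal).

**Settlement.** A dispersing female prospects a monthly *sample* of 12
candidate sites within 33 km of her natal center, keeps those with no other
territory within 2 km (falling back to 1 km if none qualifies), discards
sites whose 1 km prey neighbourhood could not meet the basal requirement
even at the maximum territory area (tigers shift away from prey-poor
ground), and settles on the best by 1 km prey sum. Sampling, rather than an
exhaustive scan, is a deliberate design choice: with an exhaustive monthly
scan every vacancy is refilled instantly, the population pins to the
space-packing limit, and road mortality is fully compensated — a regime in
which infrastructure effects largely vanish. Under sampled search an empty
landscape is settled immediately (essentially every sampled site
qualifies), while near saturation qualifying sites are rare, searches
routinely fail, and recruitment — not standing vacancy — limits the
population, which is the regime the study system's trajectories display. A
female who fails to settle for 12 months (the natal dispersal year) is
removed (death or emigration, folded into background mortality). The
exported `find_settlement_site()` retains the exhaustive contract for
analysis and testing.

**Starvation.** A settled female whose utilized prey sits below 76 kg/month
accumulates a consecutive-month counter and dies at 3. The counter runs
only when her territory can no longer grow (no cells were annexed in the
previous month) and only after a 6-month settlement grace — the time
needed to assemble a minimum territory at the 48-cell cap. A female still
expanding is treated as compensating, not starving. Without the grace the
literal 3-month rule kills every founder (201 cells cannot be reached in 3
months at 48 cells/month); without the expansion condition, instantaneous
prey depletion triggers a landscape-wide starvation wave that contradicts
the gradual occupancy shifts the mechanism is meant to produce.

## Males

A breeding male without females jumps once per month to the nearest settled
female within 66 km of his natal center, preferring unassociated females;
only when none is reachable does he challenge an incumbent, and only one he
is at least as strong as (age assessment). Strength is a triangular
prime-age curve — 1 at 3 years, 2 from 5 to 9, declining to 1 at 12 — so
equal-aged rivals win with probability 0.5. A winning challenger takes all
the incumbent's females; their cubs die with probability 0.79 and juveniles
with 0.24; the incumbent dies with probability 0.6, else returns to
dispersal. A losing challenger dies with probability 0.25. Resident males
sit at the centroid of their females' origins and top up their range from
unassociated females within 3 km. Unrestricted monthly challenges (no
assessment) cause runaway infanticide churn that can extinguish small
populations; the assessment gate is the standard behavioural reading of an
age-dependent win probability.

## Reproduction

A settled female with an associated male, no living dependents and no
current pregnancy conceives with the age-specific annual probability
converted to a per-eligible-month hazard, `1 - (1 - p)^(1/12)`; gestation
is 3 or 4 months. Offspring inherit the mother's origin as natal center.
Dependence until 24 months yields an emergent interbirth interval of about
28 months.

## Experiments

`scenario_config()` fixes the protocol: 14 females and 7 males initialised
on high-prey cells (origins ≥ 2 km apart, sampled preferentially from the
richest habitat, ages uniform 36–120 months; males start at female
origins), 600 burn-in months with roads drawn but inert, instantaneous
activation at month 601 (depletion rewrites the effective prey grid once
and holds it, every territory's prey sum is re-evaluated), 240 experiment
months, 28 replicates seeded `base_seed + r`. Outputs per replicate:
monthly counts (adults = all tigers ≥ 36 months; breeding females =
territory holders; dependents), a death log carrying cause and the
territory-road intersection at death (dependents inherit the mother's
intersection), and the occupancy accumulator over the experiment window.

## The synthetic landscape

The generator emulates the printed statistics of the Chitwan layers rather
than their geometry. The prey raster is FFT-smoothed noise
(autocorrelation ~8 cells) shaped by a north-south profile — low in the
settled northern band, peaking in the park core — then rescaled to attain
0 and 10.46 kg/month and power-adjusted so the mean is 3.78 within
tolerance. Primary roads are an east-west highway and a second partial
highway with connectors and a serpentine top-up spur, built to 165 km; the
optional railway corridor (class primary, ~33 km) runs parallel to and
1.2 km south of the highway toward the high-prey core, bringing the
primary class to the printed ~198 km total. Secondary roads (723 km) are
dense village webs — clusters of short segments around low-prey points in
the band — because real unpaved networks overlap heavily around
settlements; this geometry yields a road-effect zone of roughly 46% of
cells, near-road mean prey ≈ 2.7 against ≈ 4.8 far from roads, and dead
pockets small enough for territories to straddle. All of it is
deterministic under the spec seed.

What the synthetic landscape does *not* emulate: the park's actual shape,
rivers and land-cover classes, the true road geometry, or the exact
magnitude of the published effect sizes. Passing experiments on it shows
that the mechanisms interact as reported (ordering of scenario means,
near-versus-far occupancy contrasts), not that the absolute published
population sizes would be reproduced; those require the real prey raster
and road layers, which load through `read_ascii_grid()`,
`read_roads_geojson()` and `rasterize_roads()`.

## Numerical choices

Exact Euclidean distance transform (cell centers); strict thresholds
(within 2 km means ≤ 2000 m; a 5250 m cell is far); ties in greedy
expansion and settlement broken uniformly at random; contest dominance by
age with id as tiebreaker; a subordinate's origin cell is never contested,
so every female retains at least one cell; annual survival of 0 is allowed
(lethal limit used in stress tests). Problem sizes in the test suite are
chosen to exercise the full protocol — the experiment battery runs the
default 27,240-cell landscape at 28 replicates × 840 months per arm —
while unit fixtures use 20–60 cell grids where brute-force oracles are
exact.

## Known limitations

* Males suffer no road mortality (no estimates were available to the
  source studies); population declines are therefore conservative.
* Transients do not move explicitly; dispersal is a settlement rule, not a
  path, so road-crossing mortality during dispersal is absent.
* Prey is static apart from the one-shot depletion rewrite; no seasonal or
  predation dynamics.
* Connectivity and barrier effects of infrastructure are out of scope.
* The starvation, settlement-sampling and territory-ceiling rules are
  structural choices calibrated so the baseline is quasi-stationary and
  the mechanism experiments behave as published; alternative readings
  (exhaustive search, unbounded compensation) are documented above along
  with the regimes they produce.
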