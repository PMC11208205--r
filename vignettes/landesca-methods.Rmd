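---
title: "Methods: cellular-automaton land-use scenarios and perception-based ecosystem-service scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular-automaton land-use scenarios and perception-based ecosystem-service scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landesca)
```

## The problem

Coastal West African mosaic landscapes are being converted to rubber
plantations (through out-grower schemes) and to settlement around growing
peri-urban centers. Both conversions change the landscape's capacity to
provide the ecosystem services (ESs) local people rely on: food, marketable
products, fuelwood, soil-quality regulation and species diversity.
`landesca` implements a participatory scenario-analysis chain for this
setting: stakeholder-elicited transition rules drive a stochastic cellular
automaton (CA) over a categorical land-cover raster, and each simulated
landscape is scored with a perception-based ES assessment matrix. The outputs
are area-change tables, ES balance tables (the data behind spider charts) and
a trade-off classification for business-as-usual (BAU) scenarios.

## The model

### Landscape and zones

A landscape is an integer raster of land-use/land-cover (LULC) classes with a
cell size in meters; the packaged codebook has eight classes (settlement,
rubber plantations, palm vegetation, cropland, forest, shrubland, waterbody,
wetlands). A zone mask with labels WEST, EAST, CORRIDOR and NONE encodes the
geography that conditions the elicited rules: rubber expands in the rural
western part, settlement in the eastern part and along a road corridor.

### Transition rules and the CA step

A transition rule is a tuple (source class, target class, probability $p$,
minimum Moore-neighbor count $m$ of the target class, allowed zones). One CA
iteration applies a rule set synchronously:

1. eligibility is evaluated on the input grid only — a cell is eligible for a
   rule if its class is the source, its zone is allowed, and at least $m$ of
   its 8 Moore neighbors are the target class;
2. every eligible cell converts independently with probability $p$
   (a Bernoulli trial), so the one-step conversion count for one rule is
   Binomial($n_\mathrm{eligible}$, $p$);
3. a cell whose trials fired under several rules adopts one of the fired
   targets uniformly at random;
4. all other cells are unchanged. The number of non-nodata cells is invariant.

One iteration represents five years, so 2, 5 and 10 iterations — the default
reporting grid — represent 10, 25 and 50 years.

The packaged BAU rule sets encode the elicited probabilities: cropland,
shrubland and palm convert to rubber at 85 %, 90 % and 60 % (WEST only), and
to settlement at 50 %, 90 % and 50 % (EAST and CORRIDOR), each with $m = 1$.

Design choices where the elicited protocol was open:

* **Neighborhood.** The rules refer only to "neighboring cells"; we use the
  Moore (8-cell) neighborhood, the common CA convention, with no wraparound
  (the study area is a bounded municipality). Off-grid and nodata neighbors
  count as non-target.
* **Probability semantics.** Elicited percentages are interpreted as
  per-eligible-cell, per-iteration conversion probabilities. Combined with
  the frontier requirement $m = 1$ this yields bounded, frontier-limited
  growth rather than instantaneous saturation.
* **Frontier requirement.** The elicited phrasing "with or without one
  neighboring cell" is ambiguous between a hard requirement and a modifier;
  we default to requiring one target neighbor ($m = 1$), and expose $m = 0$
  per rule for spontaneous seeding.
* **Synchronous update.** Eligibility frozen at step start gives
  order-independence and reproducibility; an asynchronous order would be an
  arbitrary extra convention.
* **Randomness.** `run_scenario()` derives iteration $k$'s RNG substream as
  `(seed + 1664525 * k) mod (2^31 - 1)`, so extending a run never perturbs
  earlier iterations and every output is a pure function of
  (landscape, rule set, matrix, iterations, seed).

### The assessment matrix and landscape scores

Every indicator is standardized to a common 0–100 capacity scale:

* percentage-type indicators (share of products used as food, sold, used as
  fuelwood) pass through unchanged;
* 0–5 Likert capacity ratings map linearly, $v = 20 \cdot \mathrm{score}$
  (0 → 0, 5 → 100);
* soil-quality regulation is the arithmetic mean of the final-round expert
  scores of a Delphi survey (convergence diagnostics are out of scope);
* species diversity is the Shannon–Wiener index
  $H = -\sum_i p_i \ln p_i$ of per-class species counts, rescaled by its
  observed maximum across classes so the most diverse class scores 100.
  Natural log is the default (the usual ecological convention); the base is
  configurable.

The landscape score of service $s$ is the mean capacity over cells,

$$E_s = \sum_l \frac{A_l}{100} \, v(l, s),$$

with $A_l$ the area share of class $l$ — a pure function of composition,
hence invariant under any spatial permutation of cells and bounded by the
per-service minimum and maximum over classes. ES balance tables report
$E_s$ per reported iteration with its change versus the baseline;
`classify_tradeoffs()` labels each service INCREASE/DECREASE/STABLE with a
dead band (default 0.5 score units — the source analysis classifies by sign
only, but stochastic, desk-scale deltas need a tolerance).

### Packaged perception values

The elicited matrix values are published as a color scale, not numbers, so
the packaged perception fixtures (`inst/extdata/*_synthetic.csv`) are
synthetic values chosen once to satisfy every ordinal statement of the
elicited assessment: cropland has the highest food and soil-quality capacity;
settlement and rubber have zero food and zero species-diversity capacity;
rubber tops marketable products with palm and cropland next; wetland
(mangroves) tops fuelwood; forest tops species diversity with cropland
second; settlement and waterbody have zero soil-quality capacity. With the
packaged composition these values reproduce the reported landscape-level
ordering (marketable products highest, soil-quality regulation second,
species diversity lowest, food second lowest). They are fixtures, not
measurements.

## The synthetic landscape generator

The original 2020 land-cover raster is not deposited, so the generator
emulates its composition and qualitative geography:

* **Quotas.** Cell quotas per class come from largest-remainder
  apportionment of the target composition (the published shares sum to
  99.99 %, so the remainder is cycled by remainder rank); realized shares are
  therefore exact to within a few cells (≪ 0.5 percentage points on grids of
  10,000+ cells).
* **Arrangement.** Wetland and waterbody fill the southern (bottom) edge — a
  fixed "coast" convention; forest grows as one contiguous reserve patch in
  the western interior; 80 % of the rubber quota grows in WEST; settlement
  is placed with the highest density inside the CORRIDOR band and about 85 %
  of its quota in the east; cropland, palm and shrubland fill the remainder
  as interleaved patches.
* **Cohesion.** Patches grow by seeded region growing (random frontier
  pops); `patch_cohesion` in [0, 1] sets the mean target patch size
  (≈ 10–300 cells), so higher cohesion gives fewer, larger, adjacency-richer
  patches — which the frontier-driven CA needs. The spatial autocorrelation
  of the real map is unknown; the default (0.9) is a fixed convention.
* **Scale.** The default grid is 243 × 243 cells of 100 m (≈ 59,000 cells,
  ≈ 590 km² — the study area's extent at a desk-scale resolution; the source
  platform's cell size is unpublished). Tests use 50–120-cell grids where
  composition suffices.

What the generator does **not** emulate: the real coastline and road
geometry, the historical map series, patch-size distributions, and any
terrain or suitability gradients (participants judged terrain non-binding).
Consequently, passing tests show the method's internal correctness and the
qualitative sign structure of the scenarios on a calibrated fixture — not
agreement with the published area-change magnitudes (e.g. rubber
+21.19 points at iteration 10), which depend on the undeposited raster's
spatial configuration and are not reproducible at desk scale.

## Numerical conventions and degenerate inputs

* Area shares always sum to 100 (±0.01) and every codebook class is listed,
  zero shares included; an all-nodata grid is an error.
* `normalize_likert()` rejects scores outside [0, 5]; matrix capacities are
  validated to [0, 100]; a missing (class, service) pair is an error naming
  the pair.
* `shannon_index()` rejects empty or non-positive counts; a single species
  gives exactly 0.
* Rule sets allow at most one rule per (source, target) pair; probabilities
  of 0 and 1 short-circuit to "no change" / "all eligible convert".
* ESRI ASCII is the raster dialect (integer body); round-trips are lossless
  on cell values, cell size and nodata. A body value absent from the codebook
  is an error naming the value and its position.

## Reporting conventions

Area changes are reported in percentage points of total landscape area (not
relative class changes); per-iteration deltas sum to zero by conservation.
Stochastic outputs are reported for a single seeded run by default, matching
the simplest reading of the source analysis; multi-seed summaries can be
built by mapping `run_scenario()` over seeds.

## Known limitations

* ES scores depend only on composition, not configuration: fragmentation
  effects, edge effects and spatial ES flows are outside the model (as in
  the assessment-matrix approach generally).
* No demand constraints or area caps: growth is limited only by frontiers,
  zones and probabilities, so long runs can saturate the allowed zones.
* The perception fixtures are ordinal-faithful but cardinally synthetic;
  conclusions about absolute score levels should not be drawn from them.
* Monetary valuation and services excluded from the elicitation
  (pollination, carbon, flood control, aesthetics) are out of scope.
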