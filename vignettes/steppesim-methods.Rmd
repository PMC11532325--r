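---
title: "Model and methods behind steppesim"
author: "steppesim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind steppesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steppesim)
```

# The model

`steppesim` simulates the dynamics of six plant functional groups of
temperate steppe and woodland-steppe vegetation — resprouter trees, spiny and
non-spiny subshrubs, perennial forbs, perennial gramineae, and annual herbs —
on a rectangular lattice (by default 100 × 100 cells of 10 m × 10 m, i.e. a
1 km² site). The model is a disturbance-and-response functional-group
simulator in the FATE tradition: population state is tracked as cohorts
(same-aged populations of one group in one cell), not individuals, and
processes operate on annual time steps. Everything is deterministic except
seed dispersal and the yearly choice of grazed cells, which draw from a
single seeded RNG stream, so a run is exactly reproducible from its seed.

## State

A cohort is `(group, age, abundance)` with abundance a continuous cover
fraction in [0, 1]. Stage is a function of age: age 0 is the germinant
(first-year seedling); ages 1 to maturity are immature; ages at or beyond
`mature_age` are mature; cohorts beyond `max_age` die of senescence. Each
cell additionally carries a transient propagule pool: the seed events that
arrived during the current year, which either germinate at the end of that
year or are lost (no multi-year seed bank — the disturbance parameters that
would interact with a bank, `propkill` and `seed_broken`, are 0 for every
shipped group, so a persistent bank would be inert anyway).

The per-cell, per-group total abundance is capped at 1 (the shipped
parameterisation sets the within-cell abundance ceiling, `maxab`, to its
lowest class for every group; we read that as a cap of 1.0 on the continuous
scale of each group rather than a cap on species counts).

*Reported* abundance — what `landscape_abundance()` returns and what all
time series contain — is the established plant cover: immature plus mature
cohorts. The age-0 germinant cohort is a within-year recruitment transient
(under grazing it is largely destroyed the following spring) and the
propagule pool is not vegetation; counting either would let a standing crop
of doomed seedlings masquerade as vegetation change.

## The annual step

Sub-steps run in a fixed order within each year:

1. **Grazing disturbance** (if the scenario grazes this year's cells),
2. **Aging**: every cohort ages one year; stage promotions and senescence,
3. **Resource computation** per cell and canopy stratum,
4. **Survival pass**,
5. **Seed production and dispersal**,
6. **Germination** from the year's seed rain.

The ordering is a modelling choice (the annual cycle: spring grazing and
growth, summer seed set, autumn germination); recorded yearly abundances are
taken after step 6.

## Light competition through strata

Each group occupies a canopy stratum (1 = ground layer … 5 = high canopy):
matures at their `stratum_mature`, immatures at `stratum_immature` weighted
by their relative size (`size_class`/4), germinants in stratum 1. The
shading score of stratum *s* in a cell is the weighted abundance of all
cohorts in strata strictly above *s*. Scores below 0.33 leave the resource
level **high**, scores in [0.33, 0.66) **medium**, and denser shade **low**
— the same thresholds that map continuous abundance onto the reporting
classes absent/low/medium/high. Equal-height neighbours do not shade each
other: competition is strictly asymmetric by height.

Survival is a Boolean matrix over (stage × resource): a cohort whose entry
is false at the resource level of its own stratum is removed. Germination is
graded: the germination level (ordinal 0–4, linearly mapped to fractions in
steps of 0.25, with "half" anchored at 0.5) at the ground-stratum resource
sets the new germinant cohort's abundance, scaled by seed saturation
`min(1, events / fecundity)` and clipped to the group's per-cell headroom. A
germinant cohort only forms where germinants can survive the current
resource level.

## Seed dispersal

Every cell holding mature plants of a group releases `fecundity` seeds per
year. Each seed draws a distance band — short, medium or long, with
probability proportional to the group's band capacities on the 4-level scale
No/Low/Med/High mapped geometrically to weights 0/0.25/0.5/1 — then a
distance (uniform within the short and medium bands; beyond the medium limit
an exponential decay at rate `k1` per long-band width out to the long limit
and `k2` beyond it), and a uniform direction from a uniform point within the
source cell. The seed lands in the cell containing the sampled point;
off-grid seeds are lost (the landscape is a bounded site, not a torus). The
sampler is validated against an independent rejection sampler of the same
density (Kolmogorov–Smirnov at n = 10⁵).

## Grazing

A scenario is (regime, fraction of cells grazed per year, events per year,
severity shift). Shipped regimes:

| regime      | cells grazed/yr | events/yr | rationale                          |
|-------------|-----------------|-----------|------------------------------------|
| none        | 0               | —         | grazing exclusion                  |
| moderate    | 40%             | 1         | within carrying capacity; ungrazed refugia rotate yearly |
| overgrazing | 100%            | 4         | stocking ≈ 4× carrying capacity → 4× event multiplicity |

Grazed cells are a fresh uniform random subset each year. Per event, a
cohort of age class *c* (age classes are half-open on the right,
[0, b₁), [b₁, b₂), [b₂, ∞)) splits into three parts: a fraction
`kill[c]` is killed, a fraction `resprout[c]` survives as resprouts whose
age is reset to `respage[c]` (no resprouting where `respage` is −1), and the
remainder is untouched. Kill and resprout are fractions of the same cohort
(they never exceed the whole; validated at load). This cohort-fraction
reading is what makes "resprouter" groups resprouters: perennial gramineae,
whose mature class has kill 0 and resprout "most", are continually age-reset
to 2 years and thus never senesce under grazing — which is exactly why they
hold their abundance under overgrazing while forbs and subshrubs, whose
resprouts re-enter heavily-killed young age classes, are churned to
extinction.

A population viability floor removes a group from a cell when its *total*
cover there falls below 0.01 — about one plant on a 100 m² cell. The floor
applies to the cell population, not to single cohorts, so the age
fragmentation created by resprout resets is not penalised; it is what turns
the asymptotic decay of heavily grazed populations into the observed
complete losses within the 50-year horizon. Every newborn germinant cohort
lies above the floor.

## Landscape initialisation

An archetype profile gives per-group target mean abundances (percent) and
optional per-group stage mixes. Initialisation occupies cells independently
with probability `target / E[A]` and gives occupied cells a within-cell
plant abundance `A` — Uniform(0.75, 1) for perennial and woody groups
(established stands carry dense local cover; the landscape mean is set
through occupancy, as in a mosaic of vegetated patches and gaps) and
Uniform(0.25, 0.75) for the short-lived annuals (diffuse therophyte
carpets). The expectation of the landscape mean equals the target exactly;
at 100 × 100 the realised mean is within a fraction of a percentage point.

Placement is *viability-conditional*: taller groups are placed first, and
each group is placed only into cells where its mature stage survives the
resource level set by the already-placed canopy, with occupancy rescaled to
preserve the landscape mean. A fully independent scatter would seed
shade-intolerant groups under closed canopies where the model removes them
in the first survival pass — an initial community that is not in viable
equilibrium with itself.

The stage mix defaults to a propagule share of 0.2 with the plant share
split immature:mature in proportion to the time a plant spends in each
stage, `(mature_age − 1) : (max_age − mature_age + 1)`. For trees (mature at
10, lifespan 300) this yields a ~3% immature share — a standing old-growth
population — while short-lived gramineae start with a quarter of their cover
immature. A flat one-third immature share would make half-grown woodland
collapse visibly in the first grazed year, which is demographically
implausible for a 300-year-lived dominant. Initial mature ages are uniform
on `[mature_age, min(max_age − 1, 2·mature_age)]`; initial propagule pools
hold one year's local seed rain.

The five shipped archetypes encode the vegetation types of the Central
Anatolian steppe belt: (1) tree-dominated woodland steppe (tree mean 50%),
(2) woodland steppe with less abundant trees (10%), (3)
herbaceous-dominated steppe with abundant non-spiny subshrubs, (4) non-spiny
subshrub-dominated steppe with low total abundance, and (5) spiny
subshrub-dominated steppe. Only the two tree means are fixed by published
numbers; the remaining targets encode the verbal type descriptions and are
overridable. Annual-herb targets (2–6%) sit near that group's demographic
steady state under the grazing-response table, consistent with the reported
stability of annuals where their initial abundance is highest.

## From relevés to archetypes

The data pathway mirrors standard phytosociological practice. Braun-Blanquet
cover codes convert to percent by the conventional class midpoints (r 0.1,
+ 0.5, 1 2.5, 2 15, 3 37.5, 4 62.5, 5 87.5; overridable). A relevé
aggregates to growth-form cover by the per-group *maximum* over its member
species; relevés average to alliance rows; alliances consolidate into
vegetation types by k-means. The number of types is chosen by the elbow
method, operationalised as the maximiser of the second difference of
**log** WSS over k. The log scale matters: on raw WSS the second difference
is dominated by the first, largest drops and defaults to k = 2 for any
hierarchically structured data — even when WSS collapses to zero at the true
k — whereas log-WSS curvature is scale-invariant and locates the elbow
where the *relative* decay breaks.

The synthetic relevé generator emulates the compiled dataset's scale (58
alliances, 668 relevés over 5 archetypes by default). Each relevé realises
the archetype means with independent Gaussian deviations (the
"within-alliance noise", default sd 5 on the percent scale, truncated to
[0, 100]); one species carries the group target so the per-group maximum is
the target, and up to two further species of the synthetic pool carry
uniformly smaller covers. Applying the noise per relevé (rather than one
draw per alliance) makes alliance means average over ~11 relevés exactly as
real tables do; with one draw per alliance, the whole-class Braun-Blanquet
discretisation jumps (15 vs 37.5) would transfer untouched into the
alliance rows and swamp the cluster structure. The generator does **not**
emulate real species composition, spatial autocorrelation among relevés,
unequal relevé quality, or non-Gaussian cover distributions — so passing
recovery tests demonstrate the pipeline's correctness, not robustness to
every pathology of field data.

# Numerical and design choices

* **Continuous internal abundance.** The ordinal classes
  (absent/low/medium/high) are a reporting and competition view; the grazing
  fractions ("half", "most") require an underlying continuum.
* **Extinction floor 0.01** per cell-population (above), applied after
  grazing and survival.
* **Seed output is per cell-population**, not per age-cohort: a cell's
  mature population of a group releases `fecundity` seeds per year. Tying
  output to each distinct age would make seed rain scale with the richness
  of the age structure, an artifact of cohort bookkeeping.
* **Degenerate inputs**: all-zero profiles give empty landscapes; an empty
  landscape is a fixed point of every operator; a clustering matrix with
  identical rows returns one type; all dispersal capacities at No produce
  seeds that are never placed.
* **Tie-breaks**: dominance maps resolve ties by taller mature stratum, then
  by a fixed canonical group order.
* **Problem sizes.** The full design is 5 landscapes × 3 regimes × 50 years
  at 100 × 100 cells; one run takes a few seconds, the full experiment about
  two minutes on one core. Unit tests exercise reduced grids (20–40 cells a
  side); the acceptance tests re-run the relevant parts of the full design.

# What the simulations reproduce — and what they do not

At the shipped defaults (seed 0) the 50-year runs reproduce the qualitative
regime contrasts: overgrazing eliminates perennial forbs and both subshrub
groups in every landscape while trees and gramineae hold their initial
abundance and annual herbs do not decline; grazing exclusion in the
woodland steppes produces a monotone tree increase toward closed woodland
and suppresses the herb layer; moderate grazing lets forbs, gramineae and
spiny subshrubs expand in the treeless steppes while non-spiny subshrubs are
selectively suppressed (spinescence as structural grazing defence).

Known limitations:

* Under **moderate** grazing the 40%-per-year cell coverage leaves tree
  juveniles a ~16% chance of escaping their vulnerable decade, so tree cover
  still creeps upward and the canopy eventually closes in the woodland
  landscapes — rather than staying strictly constant. As a consequence,
  non-spiny subshrubs and annual herbs in Landscapes 1–2 end *lower* under
  moderate grazing than under exclusion (canopy suppression plus grazing
  losses), while forbs and spiny subshrubs end higher, as expected. Holding
  trees exactly constant under moderate grazing would require grazing
  essentially every cell every year, which in turn collapses the subshrub
  layer; the partial-extent encoding of "moderate" cannot produce both
  outcomes at once.
* No climate forcing, no fire, no soil heterogeneity, no herbivore
  population dynamics: the landscape types and grazing regimes are the only
  drivers, which is precisely the contrast the design isolates.
* A single light-like resource axis; below-ground competition is not
  separated from above-ground shading.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the two
woodland-steppe initial grids at 100 × 100 and reports their realised mean
tree abundances (targets 50% and 10%) as JSON, recomputed from scratch at
each invocation. The test suite (`testthat::test_dir("tests/testthat")`)
covers everything else, including the 50-year endpoint contrasts.
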