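---
title: "Methods: the Antarctic Ecosystem Value index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Antarctic Ecosystem Value index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AEVIndex)
```

This vignette is the package's own account of its science: the models
it implements, the assumptions behind them, the parameters that
matter, and the choices made where a design was genuinely open.

## The index

The AEV index asks where, within the seasonal sea-ice zone, value
accumulates across trophic levels. Five layers enter — growing-season
net primary productivity (g C m⁻² season⁻¹), krill growth potential
(a growth increment), demersal fish biomass potential (g WW m⁻²),
and two penguin accessibility layers (individuals with access). Each
layer is divided by its maximum over the whole analysis domain, the
five scaled layers are summed, and the sum is rescaled by its maximum
within each management region (or over the whole hemisphere in
hemispheric mode). The design assumption is deliberate agnosticism:
every layer is weighted equally, and max-scaling removes units and
absolute magnitudes, so the index measures co-location of high values,
not biomass. A corollary the tests enforce is scale invariance:
multiplying any single input layer by a positive constant changes
neither the index nor the bins.

Two conventions needed a decision:

* **Missing layer values inside the zone contribute zero** to the sum
  rather than making the cell missing. The demersal layer exists only
  where bottom water is ≤ 1 °C and the krill model only where SST lies
  in [−1, 5] °C; treating those as missing would erase most of the
  domain from the index instead of recording that the layer offers no
  value there.
* **Percentile bins are unweighted cell counts** by default. The bins
  describe the distribution of index values within a region; an
  area-weighted variant is available (`binPercentiles(areaWeighted =
  TRUE)`) but is not the default. Overlap percentages (polynya,
  protected areas), in contrast, are statements about area and are
  always area-weighted.

Bins use type-7 quantiles (linear interpolation of order statistics)
with a strict tie rule: a cell enters the higher bin only when its
value is strictly above the cutoff. This is deterministic, and makes
the degenerate all-equal region fall entirely into "other" rather than
arbitrarily promoting ties. With distinct values the 5/10/25 cutoffs
reproduce 5/5/15/75 splits exactly when the cell count divides evenly.

## Layers

**Krill growth.** The empirical model sums a length, food and
temperature term. The food term as commonly transcribed,
`0.385·Chl/(0.328·Chl)`, is constant for any positive chlorophyll and
undefined at zero; the package's default is the saturating
Michaelis–Menten form `0.385·Chl/(0.328 + Chl)`, which is zero at zero
food, saturates at 0.385, and restores the monotone food response the
rest of the analysis assumes. The literal ratio form remains available
behind `kgpFood(literalFood = TRUE)` for audit. The temperature term
`0.0078·SST − 0.0101·SST²` peaks at 0.386 °C (`kgpTempOptimum()`), and
the model is evaluated only on [−1, 5] °C, the range it was derived
for; outside it the layer is missing. The length term is fixed at the
40 mm adult reference, giving −0.0836.

**Demersal fish.** Biomass is summed over size classes and kept where
bottom temperature is ≤ 1 °C inclusive — both boundary statements in
the source use the inclusive form, and the mask is idempotent.

**Accessibility.** Colony abundance decays with great-circle distance
(spherical Earth, R = 6371 km) as `exp(-k d)`, with `k` fixed by one
calibration point: half the colony at 414 km (Emperor mean dispersal
distance) or 10⁻⁶ of the colony at 1933 km (Adélie maximum dispersal
distance, used because a mean is not available for this species).
Distances are geodesic, not ocean-path: at the 1–2° resolution the
package targets, routing around coastlines would suggest a precision
the layer does not have. Accessibility is kept in absolute individuals;
the index's max-scaling removes the absolute scale anyway.

## Sea-ice masks

The seasonal sea-ice zone is the set of ocean cells whose multi-year
September-mean concentration is at least 15%.

Polynyas are contiguous pockets below a threshold — 0.4 m thickness
for model fields (the default), 85% concentration for satellite-style
fields — enclosed by land and/or consolidated ice. Three numerical
choices define the detector:

* **Connectivity defaults to 4-neighbour.** The source algorithm is
  silent on diagonals; 4-connectivity prevents a polynya "leaking"
  through a single-cell diagonal gap in a barrier. 8-connectivity is a
  flag.
* **"Open ocean" is operationalised** as any below-threshold component
  touching the northernmost ocean row of the domain. Components
  connected to it are not polynyas. This encodes "surrounded by land
  or ice above the threshold" on a bounded grid.
* **Longitude wraps**: a component spanning the 0°/360° seam is one
  component.

The implementation is an iterative flood fill; the test suite holds it
to exact agreement (label sets up to renumbering) with an
independently written minimum-label-propagation oracle on 200 random
grids per run, under both connectivities, including seam-spanning and
open-boundary cases.

A cell is a *typical* polynya cell when it is labelled in strictly
more than 10% of time steps ("more than" is read literally: 1 month in
12 is 8.3% and does not qualify; 2 in 12 does).

## The nest-count model

True logged nest abundance evolves as a random walk with colony drift,
`lz_{i,t} ~ N(lz_{i,t−1} + μ_ri, σ_i²)`; the drift is quadratic in the
colony's long-term mean sea-ice concentration with between-colony
scatter σ_r; per-colony process sds are shrunk through a truncated
normal N⁺(γ, τ²); and observed logged counts carry known observation
sds. Priors are weakly informative — N(0, 10²) on the quadratic
coefficients and half-normal(1) on all scale parameters — and are
configurable only by editing the model string, deliberately: the model
is the package's contract.

Sampling is Gibbs/Metropolis via JAGS. Internally the quadratic is
sampled on a centred covariate (SIC minus its across-colony mean) and
the draws are mapped back to the raw-scale coefficients; the raw
parameterisation leaves β₀, β₁, β₂ so collinear that chains mix an
order of magnitude more slowly. Four chains and a potential scale
reduction factor below 1.05 is the default convergence declaration;
fits with a single colony run but are flagged as weakly identified.
Colonies with fewer than 10 counts are dropped before fitting,
mirroring the restriction to long-running colonies.

Projection samples parameters from the posterior (100 draws per
ensemble member by default), draws colony-year means around the
quadratic with sd σ_r, then annual growth `r_{i,t} ~ N(μ, γ²)`. SIC
series fed to the fit and projection are bias-corrected per colony
(affine map equalising calibration-period mean and sd — the tests
require the equality to 1e-10) and window-averaged over the 40
strictly preceding years, clamped to the observed bounds so no
projection extrapolates beyond the data range the empirical model saw.

The Emperor pathway is implemented down to the growth extraction:
stage-abundance trajectories are supplied by the user or a generator
and `growthFromStageSeries()` returns the log ratio of totals. The
stage-projection matrix itself (vital rates as functions of sea-ice
anomalies) lives in the specialised demographic literature and is out
of scope here.

## Metapopulation projection

Each year composes a motionless reproduction phase (multiply each
colony by `exp(r_{i,t})`) with a dispersal phase: a fraction e of each
colony's post-reproduction abundance is redistributed with settlement
weights proportional to `exp(-k d)` over inter-colony distances. The
Adélie default e = 0.035 is the highest observed emigration rate.
Settlement includes the origin colony by default (departure is
informed, settlement is random, and random settlement can land an
emigrant back home); `includeSelf = FALSE` forces all emigrants
elsewhere. An informed-departure option scales departure up as local
growth falls; it is off by default because its functional form is this
package's approximation, not an estimated quantity. Either way the
dispersal phase conserves total abundance — the tests require
conservation to 1e-10 over century-long projections.

Decadal summaries pool all member × year samples in the five years
centred on a decade (250 samples for a 50-member ensemble) and report
the population sd (no dof correction), since the pooled samples are
the population of interest, not a draw from a larger one. Colony
health compares a decade to the 2000s-style baseline: declines of more
than 30/50/90% are vulnerable/endangered/quasi-extinct; everything
else, including growth, is not threatened.

## The synthetic emulator

`generateEnvironment()` produces what the analysis needs to be true of
its inputs, and nothing more: a seasonal ice cycle with September
maximum and late-summer minimum; thickness co-varying with
concentration; coastal pockets where both are multiplied by an
openness factor in (0, 1] and where chlorophyll and productivity are
amplified during ONDJFM; latitudinal temperature gradients with a
linear warming trend (default 0.3 °C/decade, an upper-middle-scenario
Southern Ocean surface rate) and ice decline (5%/decade); a shelf band
of elevated fish biomass next to the coast; and ensemble members that
differ only through independent Gaussian noise, truncated to physical
ranges. Identical seeds give bit-identical output.

What it does not emulate: ocean circulation, spatially correlated
noise, realistic polynya dynamics (pockets are static disks),
phytoplankton community composition, or daily variability. Passing
tests therefore demonstrate that the pipeline's logic is correct under
the statistical structure the analysis assumes — not that the index
would reproduce observed Southern Ocean values. Generated nest counts
are the exact generative twin of the fitted model, which is what makes
the parameter-recovery test meaningful.

Default problem sizes are chosen for desk-scale work: the tests run
the full pipeline on a 2°–6° grid with 2–3 members over 5–10 years
(seconds), and the parameter-recovery check fits 20 replicates of 38
colonies × 40 years with two chains of 1000 kept iterations (under a
minute in total). The generator accepts the full 10-member 1990–2100
configuration unchanged when more is wanted.

## Regions, boundaries, formats

The five management regions default to pure longitude sectors
(WS 60°W–30°E, EA 30°E–150°E, RS 150°E–140°W, AS 140°W–90°W,
AP 90°W–60°W) over ocean cells south of 60°S, shipped as an editable
YAML-serialisable spec. The documented shift of the Antarctic
Peninsula's southeastern boundary into the Weddell Sea is not
quantified anywhere we could implement from, so the default keeps
clean sectors and the spec allows per-analysis overrides; this is a
known, deliberate deviation.

Gridded fields are stored in a self-describing text format (one-line
JSON header with dims, coordinates, calendar stamps and units,
followed by full-precision value lines) that round-trips bit-exactly;
sea-ice concentration is held internally as a fraction, and
percent-labelled inputs are converted at the boundary with a warning.
Colony tables are plain CSV.

## Known limitations

* The index inherits every input model's uncertainty and offers no
  way to propagate it; layers are point fields.
* Equal layer weighting is an assumption, not an estimate. A
  half-weight-per-penguin-species variant can be built by scaling the
  EPP/APP layers before stacking, at the cost of the scale-invariance
  property for those layers.
* Accessibility ignores coastlines and bathymetry; dispersal ignores
  habitat quality at the destination unless informed departure is
  switched on.
* The Emperor demographic pathway requires externally supplied stage
  trajectories.
* The polynya enclosure rule is an operationalisation; algorithms that
  treat ice-edge-touching components differently will disagree on
  marginal cases.
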