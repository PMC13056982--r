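# AEVIndex

An R package for quantifying the ecological value of Southern Ocean
marine areas across trophic levels, and for projecting how that value
changes under a warming climate. It is aimed at quantitative ecologists
and conservation planners working with gridded Earth-system-model
output (sea ice, temperature, biogeochemistry) and penguin colony
tables at the circumpolar, management-region scale.

## The index

The Antarctic Ecosystem Value (AEV) index combines five trophic input
layers, one value per ocean grid cell inside the seasonal sea-ice zone
(cells whose multi-year September-mean sea-ice concentration is at
least 15%):

* **NPP** — net primary productivity totalled over the austral growing
  season (ONDJFM),
* **KGP** — empirical Antarctic krill growth potential,
  `KGP = KGP_length + KGP_food + KGP_temp` with
  `KGP_length = -0.066 + 0.002 L - 0.000061 L²` at reference length
  `L = 40` mm, a saturating food term `0.385 · Chl / (0.328 + Chl)`,
  and `KGP_temp = 0.0078 · SST - 0.0101 · SST²`, valid for SST in
  [-1, 5] °C (the temperature term peaks at SST = 0.386 °C),
* **DFP** — demersal fish biomass potential, masked to bottom
  temperatures ≤ 1 °C (Antarctic toothfish habitability),
* **EPP / APP** — Emperor and Adélie penguin accessibility: colony
  abundance spread over the ocean with an exponential distance-decay
  kernel `exp(-k d)` calibrated so that half a colony reaches 414 km
  (Emperor) and 10⁻⁶ of a colony reaches 1933 km (Adélie).

Each layer is scaled by its domain-wide maximum and the scaled layers
are summed:

    AEVsum_ij = NPP_ij/NPP_max + KGP_ij/KGP_max + DFP_ij/DFP_max
              + EPP_ij/EPP_max + APP_ij/APP_max

and the sum is rescaled by the maximum within each management region
(Weddell Sea, East Antarctic, Ross Sea, Amundsen Sea, Antarctic
Peninsula — or the whole hemisphere), giving `AEV ∈ [0, 1]`. Cells are
binned per region into exceptional / very high / high / other at the
top 5/10/25 percentiles.

Around the index the package provides:

* polynya detection by thresholded, longitude-wrap-aware connected
  components (default 0.4 m sea-ice thickness for model fields, 85%
  concentration for satellite-style fields), with typical-polynya
  frequency maps (cells labelled in more than 10% of time steps);
* a hierarchical Bayesian state-space model for nest-count time
  series (`lz_{i,t} ~ N(lz_{i,t-1} + mu_ri, sigma_i²)` with colony mean
  growth quadratic in long-term sea-ice concentration), fitted by MCMC
  through JAGS, plus mean/variance bias correction of climate model
  series and 40-year trailing window averaging;
* a metapopulation projection alternating exponential reproduction
  with conservative distance-decay dispersal, and colony-health
  categories (declines of >30/50/90% from a baseline decade);
* area-weighted regional statistics: polynya inside/outside means,
  symmetric percent differences, protected-area overlap, and per-layer
  contribution tables with dominant-layer maps;
* a synthetic Earth-system emulator so every stage runs with no
  downloads.

## Worked example

```r
library(AEVIndex)

cfg <- pipelineConfig(
  scenario = scenarioConfig(years = 2000:2009, nMembers = 3, seed = 42),
  gridLonStep = 3, gridLatStep = 2, seed = 42)
out <- runPipeline(cfg)

out$result
#> AevResult (regional scaling): 840 scored cells,
#>   bins: exceptional=43, high=125, other=630, very_high=42

out$polynyas
#> PolynyaMap: 120 step(s), SIT < 0.4, 4-connectivity; 19 typical cells (freq > 0.1)

cbind(out$tables$polynyaStats[1], round(out$tables$polynyaStats[, 2:7], 2))
#>   region meanInside sdInside meanOutside sdOutside pctDifference pctAreaInside
#> 1     WS       0.93     0.01        0.40      0.21         80.75          1.04
#> 2     EA         NA       NA        0.46      0.24            NA          0.00
#> 3     RS       0.98     0.01        0.41      0.22         82.55          1.85
#> 4     AS       0.87     0.05        0.33      0.18         89.04          6.45
#> 5     AP         NA       NA        0.44      0.25            NA          0.00
#> 6   Hemi       0.90     0.06        0.41      0.22         74.39          1.63
```

Reading the table: on this synthetic decade the typical polynyas
occupy 1–6% of each region's area but carry index values roughly twice
those outside (`pctDifference` is the symmetric percent difference
`100·(in − out)/(0.5·(in + out))`); regions whose synthetic polynya
pockets fall elsewhere (EA, AP here) have no inside statistics. The
generator plants elevated chlorophyll and thin ice in its polynya
pockets, so the high inside means are the expected signature, not a
measurement of the real Southern Ocean.

Single quantities are available directly:

```r
kgpTempOptimum()                        # 0.3861386 degC
accessibilityKernel(414, EPP_CALIBRATION)   # exactly 0.5
```

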