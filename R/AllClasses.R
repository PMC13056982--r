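#' @import methods
NULL

#' Grid: geometry of a regular lat/lon grid
#'
#' Cell-centre latitudes and longitudes of a regular circumpolar grid,
#' spherical cell areas in km^2 and a logical land mask (`TRUE` = land).
#' Longitudes are stored in \[0, 360) degrees east and wrap: the last
#' column is adjacent to the first.
#'
#' @slot latCenters numeric, strictly increasing degrees north
#' @slot lonCenters numeric, degrees east in \[0, 360)
#' @slot latStep,lonStep numeric, grid spacing in degrees
#' @slot cellArea matrix (nlat x nlon) of cell areas, km^2
#' @slot landMask logical matrix (nlat x nlon), `TRUE` = land
#' @exportClass Grid
setClass("Grid", representation(
  latCenters = "numeric",
  lonCenters = "numeric",
  latStep = "numeric",
  lonStep = "numeric",
  cellArea = "matrix",
  landMask = "matrix"
))

setValidity("Grid", function(object) {
  msgs <- character()
  nlat <- length(object@latCenters)
  nlon <- length(object@lonCenters)
  if (nlat < 1 || nlon < 1) msgs <- c(msgs, "empty grid")
  if (any(diff(object@latCenters) <= 0))
    msgs <- c(msgs, "latCenters must be strictly increasing")
  if (any(object@lonCenters < 0 | object@lonCenters >= 360))
    msgs <- c(msgs, "lonCenters must lie in [0, 360)")
  if (!all(dim(object@cellArea) == c(nlat, nlon)))
    msgs <- c(msgs, "cellArea dimensions disagree with coordinates")
  if (!all(dim(object@landMask) == c(nlat, nlon)))
    msgs <- c(msgs, "landMask dimensions disagree with coordinates")
  if (any(object@cellArea <= 0)) msgs <- c(msgs, "cellArea must be positive")
  # area proportional to cos(lat) * dlat * dlon
  expect <- .sphericalCellArea(object@latCenters, object@latStep, object@lonStep)
  rel <- abs(object@cellArea - matrix(expect, nrow = nlat, ncol = nlon)) /
    object@cellArea
  if (any(rel > 1e-10))
    msgs <- c(msgs, "cellArea inconsistent with spherical closed form")
  if (length(msgs)) msgs else TRUE
})

#' GriddedField: a physical variable on (member, time, lat, lon)
#'
#' Monthly fields are stored as a 4-d array indexed
#' `[member, time, lat, lon]`; single-member or time-invariant data use
#' length-1 dimensions. `years` and `months` give the calendar stamp of
#' every time step. Missing data are `NA`.
#'
#' @slot name variable name (e.g. "SIC")
#' @slot units unit string; sea-ice concentration is stored as fraction
#' @slot data 4-d numeric array `[member, time, lat, lon]`
#' @slot years,months integer vectors, one per time step
#' @exportClass GriddedField
setClass("GriddedField", representation(
  name = "character",
  units = "character",
  data = "array",
  years = "integer",
  months = "integer"
))

setValidity("GriddedField", function(object) {
  msgs <- character()
  d <- dim(object@data)
  if (length(d) != 4)
    return("data must be a 4-d array [member, time, lat, lon]")
  if (length(object@years) != d[2] || length(object@months) != d[2])
    msgs <- c(msgs, "years/months length must equal the time dimension")
  if (length(object@months) && any(object@months < 1 | object@months > 12))
    msgs <- c(msgs, "months must lie in 1..12")
  if (length(object@name) != 1 || length(object@units) != 1)
    msgs <- c(msgs, "name and units must be single strings")
  if (length(msgs)) msgs else TRUE
})

#' RegionSet: named boolean region masks on a grid
#'
#' The five management regions (WS, EA, RS, AS, AP) plus "Hemi", their
#' union. The five regional masks are pairwise disjoint; membership is
#' restricted to ocean cells south of 60 degrees S.
#'
#' @slot masks named list of logical matrices (nlat x nlon)
#' @slot gridDim integer c(nlat, nlon) the masks are defined on
#' @exportClass RegionSet
setClass("RegionSet", representation(
  masks = "list",
  gridDim = "integer"
))

setValidity("RegionSet", function(object) {
  msgs <- character()
  nm <- names(object@masks)
  if (is.null(nm) || any(!nzchar(nm))) msgs <- c(msgs, "masks must be named")
  for (m in object@masks) {
    if (!is.logical(m) || !all(dim(m) == object@gridDim))
      msgs <- c(msgs, "every mask must be a logical matrix on the grid")
  }
  reg <- setdiff(nm, "Hemi")
  if (length(reg) > 1) {
    tot <- Reduce(`+`, object@masks[reg])
    if (any(tot > 1)) msgs <- c(msgs, "regional masks must be pairwise disjoint")
    if ("Hemi" %in% nm) {
      uni <- Reduce(`|`, object@masks[reg])
      if (!identical(uni, object@masks[["Hemi"]]))
        msgs <- c(msgs, "Hemi must equal the union of the regional masks")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PolynyaMap: labelled polynya components and frequency statistics
#'
#' @slot labels integer array `[time, lat, lon]`; 0 = not in a polynya
#' @slot frequency matrix, fraction of time steps each cell is labelled
#' @slot typicalMask logical matrix, `frequency > cutoff`
#' @slot threshold numeric threshold the labels were computed at
#' @slot variable variable the threshold applies to ("SIC" or "SIT")
#' @slot connectivity 4 or 8
#' @slot cutoff typical-polynya frequency cutoff (strict)
#' @exportClass PolynyaMap
setClass("PolynyaMap", representation(
  labels = "array",
  frequency = "matrix",
  typicalMask = "matrix",
  threshold = "numeric",
  variable = "character",
  connectivity = "integer",
  cutoff = "numeric"
))

setValidity("PolynyaMap", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3)
    return("labels must be a 3-d array [time, lat, lon]")
  if (any(object@frequency < 0 | object@frequency > 1, na.rm = TRUE))
    msgs <- c(msgs, "frequency must lie in [0, 1]")
  if (!identical(dim(object@frequency), dim(object@typicalMask)))
    msgs <- c(msgs, "frequency and typicalMask dimensions disagree")
  if (!object@connectivity %in% c(4L, 8L))
    msgs <- c(msgs, "connectivity must be 4 or 8")
  if (length(msgs)) msgs else TRUE
})

#' LayerStack: the five trophic input layers on a common grid
#'
#' One value per ocean cell for NPP, KGP, DFP, EPP and APP; cells outside
#' the seasonal sea-ice zone are `NA`. KGP may be negative (its length
#' term is negative at the reference length); the other layers are
#' non-negative.
#'
#' @slot layers named list of matrices: NPP, KGP, DFP, EPP, APP
#' @slot units named character, units per layer
#' @slot zoneMask logical matrix, the seasonal sea-ice zone
#' @exportClass LayerStack
setClass("LayerStack", representation(
  layers = "list",
  units = "character",
  zoneMask = "matrix"
))

setValidity("LayerStack", function(object) {
  msgs <- character()
  need <- c("NPP", "KGP", "DFP", "EPP", "APP")
  if (!all(need %in% names(object@layers)))
    msgs <- c(msgs, paste("layers must contain", paste(need, collapse = ", ")))
  dm <- dim(object@zoneMask)
  for (k in names(object@layers)) {
    if (!all(dim(object@layers[[k]]) == dm))
      msgs <- c(msgs, paste("layer", k, "not on the zone-mask grid"))
  }
  for (k in setdiff(need, "KGP")) {
    if (k %in% names(object@layers) &&
        any(object@layers[[k]] < 0, na.rm = TRUE))
      msgs <- c(msgs, paste("layer", k, "must be non-negative"))
  }
  if (length(msgs)) msgs else TRUE
})

#' AevResult: the Antarctic Ecosystem Value index and its bins
#'
#' @slot aev matrix in \[0, 1\]; `NA` outside the analysis domain
#' @slot aevSum matrix of summed max-scaled layers (before the
#'   regional rescaling)
#' @slot bins character matrix: "exceptional", "very_high", "high",
#'   "other" or `NA`
#' @slot scaledLayers named list of the five max-scaled layers
#' @slot regions the [RegionSet-class] used
#' @slot mode "regional" or "hemispheric"
#' @slot cutoffs numeric percentile cutoffs (default 5, 10, 25)
#' @exportClass AevResult
setClass("AevResult", representation(
  aev = "matrix",
  aevSum = "matrix",
  bins = "matrix",
  scaledLayers = "list",
  regions = "RegionSet",
  mode = "character",
  cutoffs = "numeric"
))

setValidity("AevResult", function(object) {
  msgs <- character()
  if (any(object@aev < -1e-12 | object@aev > 1 + 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "aev must lie in [0, 1]")
  if (!object@mode %in% c("regional", "hemispheric"))
    msgs <- c(msgs, "mode must be 'regional' or 'hemispheric'")
  ok <- c("exceptional", "very_high", "high", "other")
  b <- object@bins
  if (any(!is.na(b) & !(b %in% ok)))
    msgs <- c(msgs, "bins must be exceptional/very_high/high/other")
  if (length(msgs)) msgs else TRUE
})

#' NestCounts: nest-count time series for the Adelie state-space model
#'
#' Logged nest counts with their observation errors, plus the long-term
#' mean sea-ice concentration (fraction) in each colony's catchment.
#' When produced by [generateNestCounts()] the generating parameters are
#' kept in `truth` for parameter-recovery checks.
#'
#' @slot counts data.frame with columns colony_id, year, y (logged nest
#'   count), s (observation sd of y)
#' @slot sicMean named numeric, long-term mean SIC per colony
#' @slot truth list of generating parameters (empty for real data)
#' @exportClass NestCounts
setClass("NestCounts", representation(
  counts = "data.frame",
  sicMean = "numeric",
  truth = "list"
))

setValidity("NestCounts", function(object) {
  msgs <- character()
  need <- c("colony_id", "year", "y", "s")
  if (!all(need %in% names(object@counts)))
    msgs <- c(msgs, paste("counts must have columns",
                          paste(need, collapse = ", ")))
  else {
    if (any(object@counts$s < 0, na.rm = TRUE))
      msgs <- c(msgs, "observation sds must be >= 0")
    ids <- unique(object@counts$colony_id)
    if (!all(ids %in% names(object@sicMean)))
      msgs <- c(msgs, "every colony needs a sicMean entry")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NestCounts", function(object) {
  ids <- unique(object@counts$colony_id)
  cat(sprintf("NestCounts: %d colonies, %d counts, years %d..%d\n",
              length(ids), nrow(object@counts),
              min(object@counts$year), max(object@counts$year)))
})

#' ScenarioConfig: parameters of the synthetic Earth-system emulator
#'
#' Defaults emulate a desk-scale analogue of a coupled-model large
#' ensemble: a 2-degree circumpolar grid, 10 members, 1990-2100, a
#' warming trend on surface and bottom temperature, a sea-ice decline
#' trend, coastal low-ice polynya pockets with amplified chlorophyll
#' blooms, and independent Gaussian noise per field truncated to
#' physical ranges.
#'
#' @slot years integer vector of simulated calendar years (inclusive)
#' @slot nMembers ensemble size
#' @slot warmingRate degrees C per decade added to SST and TBOT
#' @slot iceDeclineRate fraction per decade removed from SIC/SIT
#' @slot polynyas data.frame(lat, lon, radiusKm, openness); openness in
#'   (0, 1] multiplies SIC/SIT inside the pocket
#' @slot bloomAmplification chlorophyll/NPP multiplier inside polynyas
#'   during the growing season (ONDJFM)
#' @slot noiseSd named numeric, Gaussian noise sd per field
#' @slot seed integer RNG seed
#' @exportClass ScenarioConfig
setClass("ScenarioConfig", representation(
  years = "integer",
  nMembers = "integer",
  warmingRate = "numeric",
  iceDeclineRate = "numeric",
  polynyas = "data.frame",
  bloomAmplification = "numeric",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("ScenarioConfig", function(object) {
  msgs <- character()
  if (length(object@years) < 1) msgs <- c(msgs, "years must be non-empty")
  if (object@nMembers < 1) msgs <- c(msgs, "nMembers must be >= 1")
  p <- object@polynyas
  if (nrow(p)) {
    if (any(p$radiusKm <= 0)) msgs <- c(msgs, "polynya radii must be positive")
    if (any(p$openness <= 0 | p$openness > 1))
      msgs <- c(msgs, "openness must lie in (0, 1]")
  }
  if (any(object@noiseSd < 0)) msgs <- c(msgs, "noise sds must be >= 0")
  if (length(msgs)) msgs else TRUE
})
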