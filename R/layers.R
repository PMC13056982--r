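# The five trophic input layers: growing-season NPP, krill growth
# potential (KGP), demersal fish biomass potential (DFP), and penguin
# accessibility (EPP/APP).

#' Growing-season net primary productivity
#'
#' Per-cell mean over seasons of the total NPP summed over the austral
#' growing season ONDJFM, where a season spans October of year y
#' through March of year y+1. Members are pooled into the mean.
#'
#' @param npp a [GriddedField-class] of monthly NPP
#' @param years integer vector of season start years (the year of the
#'   season's October); default all years with a complete season
#' @return matrix, NPP per season (units of the monthly field x 6)
#' @export
growingSeasonNpp <- function(npp, years = NULL) {
  stopifnot(is(npp, "GriddedField"))
  yrs <- fieldYears(npp)
  mos <- fieldMonths(npp)
  if (is.null(years)) {
    years <- intersect(unique(yrs[mos %in% 10:12]),
                       unique(yrs[mos %in% 1:3] - 1L))
    years <- sort(years)
  }
  if (!length(years)) stop("no complete ONDJFM season in the field")
  d <- dim(npp@data)
  total <- matrix(0, d[3], d[4])
  missing <- character()
  for (y in years) {
    want <- rbind(cbind(y, 10:12), cbind(y + 1L, 1:3))
    for (k in seq_len(nrow(want))) {
      sel <- which(yrs == want[k, 1] & mos == want[k, 2])
      if (!length(sel)) {
        missing <- c(missing, sprintf("%d-%02d", want[k, 1], want[k, 2]))
        next
      }
      slice <- npp@data[, sel, , , drop = FALSE]
      total <- total + apply(slice, c(3, 4), mean)   # pool members
    }
  }
  if (length(missing))
    stop("missing growing-season months: ", paste(missing, collapse = ", "))
  total / length(years)
}

#' Krill growth potential
#'
#' Empirical growth increment for adult Antarctic krill as the sum of a
#' length term, a food (chlorophyll) term and a temperature term:
#' \deqn{KGP = -0.066 + 0.002 L - 0.000061 L^2
#'       + 0.385\,Chl/(0.328 + Chl) + 0.0078\,SST - 0.0101\,SST^2}
#' evaluated only for SST in \[-1, 5\] degC (missing outside, the range
#' the empirical model was derived for). The food term is the
#' saturating Michaelis-Menten form; `literalFood = TRUE` switches to
#' the degenerate ratio form `0.385 * Chl / (0.328 * Chl)` for audit
#' purposes (constant for Chl > 0, undefined at 0).
#'
#' @param chl chlorophyll, mg m-3 (scalar, vector or matrix; >= 0)
#' @param sst sea surface temperature, degC (same shape)
#' @param lengthMm initial krill length, mm (default 40)
#' @param sstRange valid SST range, degC
#' @param literalFood use the degenerate ratio food term
#' @return growth value(s); `NA` where SST is outside `sstRange`
#' @export
kgp <- function(chl, sst, lengthMm = 40, sstRange = c(-1, 5),
                literalFood = FALSE) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be >= 0")
  v <- kgpLength(lengthMm) + kgpFood(chl, literalFood) + kgpTemp(sst)
  v[is.na(sst) | sst < sstRange[1] | sst > sstRange[2]] <- NA_real_
  v
}

#' @rdname kgp
#' @export
kgpLength <- function(lengthMm = 40) {
  -0.066 + 0.002 * lengthMm - 0.000061 * lengthMm^2
}

#' @rdname kgp
#' @export
kgpFood <- function(chl, literalFood = FALSE) {
  if (literalFood) 0.385 * chl / (0.328 * chl)
  else 0.385 * chl / (0.328 + chl)
}

#' @rdname kgp
#' @export
kgpTemp <- function(sst) 0.0078 * sst - 0.0101 * sst^2

#' SST at which the KGP temperature term peaks
#'
#' Closed form 0.0078 / (2 * 0.0101) of the quadratic temperature term,
#' within the valid range.
#'
#' @return degrees C
#' @export
kgpTempOptimum <- function() 0.0078 / (2 * 0.0101)

#' Demersal fish biomass potential
#'
#' Fish biomass summed over size classes, kept only where the ocean
#' bottom temperature is habitable for Antarctic toothfish
#' (TBOT <= 1 degC inclusive); missing elsewhere.
#'
#' @param fishBiomass matrix of biomass (g WW m-2), or a list of
#'   matrices (one per size class) summed cell-wise
#' @param tbot matrix of bottom temperature, degC
#' @param maxTbot habitability threshold, default 1 degC (inclusive)
#' @return matrix; `NA` where TBOT > `maxTbot` or TBOT missing
#' @export
dfp <- function(fishBiomass, tbot, maxTbot = 1) {
  if (is.list(fishBiomass)) fishBiomass <- Reduce(`+`, fishBiomass)
  stopifnot(all(dim(fishBiomass) == dim(tbot)))
  out <- fishBiomass
  out[is.na(tbot) | tbot > maxTbot] <- NA_real_
  out
}

#' Exponential distance-decay accessibility kernel
#'
#' Fraction of a colony's individuals that can reach a point `d` km
#' away, `exp(-k d)` with `k = -log(fraction) / distance` calibrated so
#' that exactly `fraction` of individuals reach `distance` km.
#'
#' @param d distance, km
#' @param calibration `c(distance_km, surviving_fraction)`; presets:
#'   Emperor `c(414, 0.5)` (half the colony reaches the 414 km mean
#'   dispersal distance), Adelie `c(1933, 1e-6)` (one in a million
#'   reaches the 1933 km maximum dispersal distance)
#' @return fraction in (0, 1]
#' @export
accessibilityKernel <- function(d, calibration) {
  if (calibration[2] <= 0 || calibration[2] >= 1)
    stop("surviving fraction must lie in (0, 1)")
  if (calibration[1] <= 0) stop("calibration distance must be positive")
  exp(-(-log(calibration[2]) / calibration[1]) * d)
}

#' Emperor accessibility calibration (414 km, half the colony)
#' @rdname accessibilityKernel
#' @export
EPP_CALIBRATION <- c(414, 0.5)

#' Adelie accessibility calibration (1933 km, 1e-6 of the colony)
#' @rdname accessibilityKernel
#' @export
APP_CALIBRATION <- c(1933, 1e-6)

#' Penguin colony accessibility layer
#'
#' For each ocean grid cell, the number of individuals that can access
#' it, summed over colonies: `sum_c abundance_c * exp(-k d_c)` where
#' `d_c` is the great-circle distance (spherical Earth, R = 6371 km)
#' from colony c to the cell centre and k comes from the calibration.
#'
#' @param colonies data.frame with columns lat, lon, abundance
#' @param grid a [Grid-class]
#' @param calibration `c(distance_km, fraction)`; see
#'   [accessibilityKernel()]
#' @return matrix of individuals with access; `NA` on land
#' @export
accessibility <- function(colonies, grid, calibration = EPP_CALIBRATION) {
  stopifnot(is(grid, "Grid"),
            all(c("lat", "lon", "abundance") %in% names(colonies)))
  if (calibration[2] <= 0 || calibration[2] >= 1)
    stop("surviving fraction must lie in (0, 1)")
  nlat <- length(latCenters(grid))
  nlon <- length(lonCenters(grid))
  latM <- matrix(latCenters(grid), nlat, nlon)
  lonM <- matrix(lonCenters(grid), nlat, nlon, byrow = TRUE)
  out <- matrix(0, nlat, nlon)
  for (c in seq_len(nrow(colonies))) {
    d <- .greatCircleKm(latM, lonM, colonies$lat[c], colonies$lon[c])
    out <- out + colonies$abundance[c] *
      accessibilityKernel(matrix(d, nlat, nlon), calibration)
  }
  out[landMask(grid)] <- NA_real_
  out
}

#' Assemble the five-layer stack
#'
#' Restricts each layer to the seasonal sea-ice zone (cells outside are
#' missing) and bundles them with units.
#'
#' @param npp,kgp,dfp,epp,app matrices on the common grid
#' @param zone logical matrix, the seasonal sea-ice zone
#' @return a [LayerStack-class]
#' @export
layerStack <- function(npp, kgp, dfp, epp, app, zone) {
  layers <- list(NPP = npp, KGP = kgp, DFP = dfp, EPP = epp, APP = app)
  layers <- lapply(layers, function(m) {
    m[!zone] <- NA_real_
    m
  })
  new("LayerStack", layers = layers,
      units = c(NPP = "g C m-2 season-1", KGP = "growth increment",
                DFP = "g WW m-2", EPP = "individuals",
                APP = "individuals"),
      zoneMask = zone)
}
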