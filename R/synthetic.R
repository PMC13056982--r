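# Synthetic Earth-system-model emulator: gridded environmental fields,
# penguin colony tables, and nest-count series with the statistical
# structure the downstream analysis assumes.

#' Build a scenario configuration
#'
#' Defaults describe the desk-scale study conditions: a 10-member
#' ensemble over 1990-2100 with a 0.3 degC/decade surface warming
#' trend, 5%/decade sea-ice decline, three coastal polynya pockets with
#' doubled chlorophyll blooms, and modest per-field Gaussian noise.
#'
#' @param years integer vector of calendar years
#' @param nMembers ensemble size
#' @param warmingRate degC per decade on SST and TBOT
#' @param iceDeclineRate fraction of ice lost per decade
#' @param polynyas data.frame(lat, lon, radiusKm, openness)
#' @param bloomAmplification chlorophyll/NPP multiplier inside polynyas
#'   during the growing season
#' @param noiseSd named numeric noise sd per field (missing fields get 0)
#' @param seed RNG seed
#' @return a [ScenarioConfig-class]
#' @export
scenarioConfig <- function(years = 1990:2100, nMembers = 10,
                           warmingRate = 0.3, iceDeclineRate = 0.05,
                           polynyas = defaultPolynyas(),
                           bloomAmplification = 2,
                           noiseSd = defaultNoiseSd(),
                           seed = 42) {
  if (!length(years)) stop("years must be non-empty")
  new("ScenarioConfig", years = as.integer(years),
      nMembers = as.integer(nMembers), warmingRate = warmingRate,
      iceDeclineRate = iceDeclineRate, polynyas = polynyas,
      bloomAmplification = bloomAmplification,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @rdname scenarioConfig
#' @export
defaultPolynyas <- function() {
  data.frame(lat = c(-75, -74, -75),
             lon = c(10, 180, 250),
             radiusKm = c(300, 250, 300),
             openness = c(0.4, 0.5, 0.35))
}

#' @rdname scenarioConfig
#' @export
defaultNoiseSd <- function() {
  c(SIC = 0.03, SIT = 0.05, SST = 0.2, TBOT = 0.1,
    CHL = 0.05, NPP = 0.3, DFP_raw = 0.2)
}

#' Synthetic Antarctic land mask
#'
#' Marks cells south of a longitude-dependent coastline as land; the
#' coastline undulates sinusoidally around a mean edge latitude so the
#' coast crosses several grid rows and provides coastal cells for
#' colonies and polynya enclosure.
#'
#' @param grid a [Grid-class]
#' @param meanEdge mean coastline latitude (degrees north)
#' @param amplitude undulation amplitude in degrees
#' @return logical matrix, `TRUE` = land
#' @export
syntheticLandMask <- function(grid, meanEdge = -74, amplitude = 2) {
  lat <- latCenters(grid)
  lon <- lonCenters(grid)
  edge <- meanEdge + amplitude * sin(2 * pi * lon / 360) +
    0.5 * amplitude * sin(6 * pi * lon / 360)
  outer(seq_along(lat), seq_along(lon),
        function(i, j) lat[i] < edge[j])
}

# Growing-season (ONDJFM) membership per month 1..12.
.inGrowingSeason <- function(m) m %in% c(10, 11, 12, 1, 2, 3)

# Seasonal cycle factor: 1 in September, minimum in March.
.seasonFactor <- function(m) 0.5 * (1 + cos(2 * pi * (m - 9) / 12))

# Openness multiplier per cell from the polynya spec (1 outside pockets;
# overlapping pockets take the strongest opening).
.opennessField <- function(grid, polynyas) {
  nlat <- length(latCenters(grid))
  nlon <- length(lonCenters(grid))
  o <- matrix(1, nlat, nlon)
  if (!nrow(polynyas)) return(o)
  latM <- matrix(latCenters(grid), nlat, nlon)
  lonM <- matrix(lonCenters(grid), nlat, nlon, byrow = TRUE)
  for (p in seq_len(nrow(polynyas))) {
    d <- .greatCircleKm(latM, lonM, polynyas$lat[p], polynyas$lon[p])
    d <- matrix(d, nlat, nlon)
    inside <- d <= polynyas$radiusKm[p]
    o[inside] <- pmin(o[inside], polynyas$openness[p])
  }
  o
}

#' Generate synthetic gridded environmental fields
#'
#' Emulates monthly Earth-system-model output: sea-ice concentration
#' (SIC, fraction) with an austral seasonal cycle (September maximum,
#' late-summer minimum) and a decline trend; co-varying sea-ice
#' thickness (SIT, m); sea surface and bottom temperature (SST/TBOT,
#' degC) with a latitudinal gradient and a warming trend; surface
#' chlorophyll (CHL, mg m-3) and net primary productivity (NPP, g C m-2
#' month-1) concentrated in the growing season (ONDJFM) and amplified
#' inside polynya pockets; and raw demersal fish biomass (DFP_raw,
#' g WW m-2) elevated on the continental-shelf band next to the coast.
#' Inside each configured polynya pocket, SIC and SIT are multiplied by
#' the pocket's openness factor before noise. Ensemble members share
#' the deterministic structure and differ only through noise draws; the
#' same seed gives bit-identical output.
#'
#' @param grid a [Grid-class]; its land mask defines the coast (use
#'   [syntheticLandMask()] for a synthetic coastline)
#' @param config a [ScenarioConfig-class]
#' @return named list of [GriddedField-class]: SIC, SIT, SST, TBOT,
#'   CHL, NPP, DFP_raw
#' @export
generateEnvironment <- function(grid, config) {
  stopifnot(is(grid, "Grid"), is(config, "ScenarioConfig"))
  validObject(config)
  years <- config@years
  if (!length(years)) stop("years must be non-empty")
  lat <- latCenters(grid)
  nlat <- length(lat)
  nlon <- length(lonCenters(grid))
  nyr <- length(years)
  nt <- nyr * 12L
  yearVec <- rep(years, each = 12L)
  monthVec <- rep(1:12, times = nyr)
  land <- landMask(grid)
  open <- .opennessField(grid, config@polynyas)

  # latitudinal ice affinity: 1 deep south, 0 at the northern edge
  f <- pmin(pmax((-55 - lat) / 20, 0), 1)
  s <- .seasonFactor(monthVec)                      # per time step
  decadal <- (yearVec - years[1]) / 10
  iceTrend <- pmax(1 - config@iceDeclineRate * decadal, 0)
  warm <- config@warmingRate * decadal
  grow <- .inGrowingSeason(monthVec)

  # deterministic base [time, lat, lon]
  base <- function(perTimeLat) {               # outer over lon (uniform)
    array(perTimeLat, dim = c(nt, nlat, nlon))
  }
  ftl <- outer(rep(1, nt), f)                       # [time, lat]
  sicTL <- outer(iceTrend * (0.15 + 0.85 * s), f)   # trend x season x lat
  sic0 <- base(sicTL)
  sstTL <- outer(1.5 * (1 - s) + warm, rep(1, nlat)) +
    outer(rep(1, nt), -1.8 + 8 * (lat + 78) / 28)
  sst0 <- base(sstTL)
  tbotTL <- outer(warm, rep(1, nlat)) +
    outer(rep(1, nt), -1.0 + 4 * (lat + 78) / 28)
  tbot0 <- base(tbotTL)
  chlTL <- outer(grow * (1 - s), rep(1, nlat)) * (0.8 + 1.2 * ftl)
  chl0 <- base(0.05 + chlTL)
  nppTL <- outer(grow * (1 - s), rep(1, nlat)) * (4 + 6 * ftl)
  npp0 <- base(nppTL)

  # polynya openness on ice, bloom amplification on CHL/NPP in season
  openT <- aperm(array(open, dim = c(nlat, nlon, nt)), c(3, 1, 2))
  sic0 <- sic0 * openT
  sit0 <- 2.0 * sic0
  bloomT <- 1 + (config@bloomAmplification - 1) *
    (openT < 1) * array(grow, dim = c(nt, nlat, nlon))
  chl0 <- chl0 * bloomT
  npp0 <- npp0 * bloomT

  # shelf band: ocean cells within 2 cells of land (lon wrap aware)
  shelf <- .nearLand(land, steps = 2)
  shelfT <- aperm(array(shelf, dim = c(nlat, nlon, nt)), c(3, 1, 2))
  dfp0 <- (0.3 + 2.2 * shelfT) * array(ftl, dim = c(nt, nlat, nlon))

  sd0 <- function(nm) {
    v <- config@noiseSd[nm]
    if (is.na(v)) 0 else unname(v)
  }
  bases <- list(SIC = sic0, SIT = sit0, SST = sst0, TBOT = tbot0,
                CHL = chl0, NPP = npp0, DFP_raw = dfp0)
  lo <- c(SIC = 0, SIT = 0, SST = -Inf, TBOT = -Inf, CHL = 0, NPP = 0,
          DFP_raw = 0)
  hi <- c(SIC = 1, SIT = Inf, SST = Inf, TBOT = Inf, CHL = Inf,
          NPP = Inf, DFP_raw = Inf)
  units <- c(SIC = "1", SIT = "m", SST = "degC", TBOT = "degC",
             CHL = "mg m-3", NPP = "g C m-2 month-1",
             DFP_raw = "g WW m-2")

  nm <- config@nMembers
  out <- .withSeed(config@seed, {
    lapply(names(bases), function(fn) {
      arr <- array(NA_real_, dim = c(nm, nt, nlat, nlon))
      for (m in seq_len(nm)) {
        noise <- if (sd0(fn) > 0)
          array(stats::rnorm(nt * nlat * nlon, 0, sd0(fn)),
                dim = c(nt, nlat, nlon))
        else 0
        arr[m, , , ] <- pmin(pmax(bases[[fn]] + noise, lo[fn]), hi[fn])
      }
      landT <- aperm(array(land, dim = c(nlat, nlon, nt)), c(3, 1, 2))
      for (m in seq_len(nm)) arr[m, , , ][landT] <- NA_real_
      new("GriddedField", name = fn, units = unname(units[fn]),
          data = arr, years = yearVec, months = monthVec)
    })
  })
  names(out) <- names(bases)
  out
}

# Ocean cells within `steps` cells of land (4-neighbourhood, lon wrap).
.nearLand <- function(land, steps = 1) {
  if (!any(land)) {
    # no land: treat the southernmost rows as the shelf analogue
    m <- matrix(FALSE, nrow(land), ncol(land))
    m[seq_len(min(steps, nrow(land))), ] <- TRUE
    return(m)
  }
  reach <- land
  for (i in seq_len(steps)) {
    up <- rbind(reach[-1, , drop = FALSE], FALSE)
    down <- rbind(FALSE, reach[-nrow(reach), , drop = FALSE])
    left <- cbind(reach[, -1, drop = FALSE], reach[, 1])
    right <- cbind(reach[, ncol(reach)], reach[, -ncol(reach), drop = FALSE])
    reach <- reach | up | down | left | right
  }
  reach & !land
}

#' Generate a synthetic penguin colony table
#'
#' Places colonies on coastal ocean cells (ocean cells adjacent to
#' land) with log-uniform abundances.
#'
#' @param grid a [Grid-class] with a land mask
#' @param nColonies number of colonies (>= 1)
#' @param abundanceRange length-2 numeric, individuals
#' @param seed RNG seed
#' @param species species tag stored in the table
#' @return data.frame(colony_id, lat, lon, abundance, species)
#' @export
generateColonies <- function(grid, nColonies, abundanceRange = c(1e3, 1e5),
                             seed = 1, species = "adelie") {
  stopifnot(is(grid, "Grid"), nColonies >= 1)
  coastal <- .nearLand(landMask(grid), steps = 1) & !landMask(grid)
  if (!any(landMask(grid)) || !any(coastal))
    stop("grid has no coastal cells; set a land mask first")
  idx <- which(coastal, arr.ind = TRUE)
  .withSeed(seed, {
    pick <- idx[sample.int(nrow(idx), nColonies,
                           replace = nColonies > nrow(idx)), , drop = FALSE]
    ab <- if (abundanceRange[1] == abundanceRange[2])
      rep(abundanceRange[1], nColonies)
    else exp(stats::runif(nColonies, log(abundanceRange[1]),
                          log(abundanceRange[2])))
    data.frame(
      colony_id = sprintf("%s_%03d", substr(species, 1, 3),
                          seq_len(nColonies)),
      lat = latCenters(grid)[pick[, 1]],
      lon = lonCenters(grid)[pick[, 2]],
      abundance = ab,
      species = species,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate nest-count series from the Adelie state-space model
#'
#' The generative twin of the hierarchical nest-count model: per colony,
#' a process sd is drawn from a normal truncated at zero,
#' `sigma_i ~ N+(gamma, tau^2)`; a mean growth rate from the quadratic
#' sea-ice curve, `mu_ri ~ N(b0 + b1*SIC + b2*SIC^2, sigma_r^2)`; the
#' true logged abundance evolves as `lz_t ~ N(lz_{t-1} + mu_ri,
#' sigma_i^2)`; and observed logged counts as `y_t ~ N(lz_t, s_t^2)`.
#'
#' @param truth named list/vector with beta0, beta1, beta2, sigmaR,
#'   gamma, tau
#' @param sicByColony named numeric of long-term mean SIC (fraction) per
#'   colony, or data.frame(colony_id, sic) or (colony_id, year, sic)
#'   whose per-colony mean is used
#' @param years integer vector of observation years
#' @param obsErrorSd observation sd of logged counts (scalar or one per
#'   count, recycled per colony-year)
#' @param lz0Range range of the initial logged abundance (uniform)
#' @param seed RNG seed
#' @return a [NestCounts-class]
#' @export
generateNestCounts <- function(truth, sicByColony, years,
                               obsErrorSd = 0.05, lz0Range = c(4, 8),
                               seed = 1) {
  truth <- as.list(truth)
  need <- c("beta0", "beta1", "beta2", "sigmaR", "gamma", "tau")
  if (!all(need %in% names(truth)))
    stop("truth must name ", paste(need, collapse = ", "))
  if (any(unlist(truth[c("sigmaR", "gamma", "tau")]) < 0))
    stop("variance parameters must be non-negative")
  if (is.data.frame(sicByColony)) {
    sic <- tapply(sicByColony$sic, sicByColony$colony_id, mean)
    sic <- stats::setNames(as.numeric(sic), names(sic))
  } else sic <- sicByColony
  if (is.null(names(sic))) stop("sicByColony must be named by colony")
  nyr <- length(years)
  .withSeed(seed, {
    rows <- lapply(names(sic), function(id) {
      si <- .rtruncnorm0(1, truth$gamma, truth$tau)
      mu <- stats::rnorm(1, truth$beta0 + truth$beta1 * sic[[id]] +
                           truth$beta2 * sic[[id]]^2, truth$sigmaR)
      lz <- numeric(nyr)
      lz[1] <- stats::runif(1, lz0Range[1], lz0Range[2])
      for (t in seq_len(nyr - 1) + 1)
        lz[t] <- lz[t - 1] + mu + stats::rnorm(1, 0, si)
      s <- rep_len(obsErrorSd, nyr)
      y <- stats::rnorm(nyr, lz, s)
      data.frame(colony_id = id, year = years, y = y, s = s,
                 stringsAsFactors = FALSE)
    })
    new("NestCounts", counts = do.call(rbind, rows),
        sicMean = sic, truth = truth)
  })
}

# Exact draws from N(mean, sd^2) truncated at zero (inverse-cdf).
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}
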