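# Penguin population dynamics: climate bias correction, the Adelie
# hierarchical nest-count model (fit + projection), intrinsic growth
# extraction, metapopulation projection, and colony-health categories.

#' Mean/variance bias correction of a model series
#'
#' Affine rescaling so the model series' calibration-period mean and sd
#' match the observations:
#' `(delta_obs / delta_model) * (y_t - theta_model) + theta_obs`,
#' applied to every time step. Matrices are corrected row-wise (one row
#' per colony), each colony separately.
#'
#' @param modelSeries numeric vector, or matrix colonies x years with
#'   year column names
#' @param obsSeries observed series on the same layout, covering the
#'   calibration years
#' @param calibrationYears integer vector of calibration years (for
#'   vectors: indices into the series are matched by `names()`, or the
#'   first `length(calibrationYears)` entries when unnamed)
#' @return corrected series, same shape as `modelSeries`
#' @export
biasCorrect <- function(modelSeries, obsSeries, calibrationYears) {
  if (is.matrix(modelSeries)) {
    stopifnot(is.matrix(obsSeries),
              nrow(obsSeries) == nrow(modelSeries))
    out <- modelSeries
    for (i in seq_len(nrow(modelSeries)))
      out[i, ] <- biasCorrect(modelSeries[i, ], obsSeries[i, ],
                              calibrationYears)
    return(out)
  }
  pick <- function(x) {
    if (!is.null(names(x))) {
      sel <- names(x) %in% as.character(calibrationYears)
      if (sum(sel) != length(calibrationYears))
        stop("series does not cover the calibration years")
      x[sel]
    } else {
      if (length(x) < length(calibrationYears))
        stop("series shorter than the calibration period")
      x[seq_along(calibrationYears)]
    }
  }
  mCal <- pick(modelSeries)
  oCal <- pick(obsSeries)
  thM <- mean(mCal)
  dM <- stats::sd(mCal)
  thO <- mean(oCal)
  dO <- stats::sd(oCal)
  if (!is.finite(dM) || dM == 0)
    stop("degenerate variance: model sd over the calibration period is 0")
  (dO / dM) * (modelSeries - thM) + thO
}

#' Trailing moving-window average with observed-bound clamping
#'
#' Each output year's value is the mean of the strictly preceding
#' `window` years, then clamped to the observed bounds (no
#' extrapolation beyond the data range the empirical model saw).
#'
#' @param series numeric vector named by year (or matrix colonies x
#'   years with year column names, processed row-wise)
#' @param window window length in years, default 40
#' @param bounds `c(min, max)` observed bounds to clamp to; default the
#'   range of `series` itself
#' @param outputYears years to return; default every year with a full
#'   window of history
#' @return named vector (or matrix) of window-averaged, clamped values
#' @export
windowAverageSic <- function(series, window = 40, bounds = NULL,
                             outputYears = NULL) {
  if (is.matrix(series)) {
    rows <- lapply(seq_len(nrow(series)), function(i)
      windowAverageSic(series[i, ], window, bounds, outputYears))
    out <- do.call(rbind, rows)
    rownames(out) <- rownames(series)
    return(out)
  }
  if (is.null(names(series))) stop("series must be named by year")
  yrs <- as.integer(names(series))
  if (any(diff(yrs) != 1L)) stop("series years must be consecutive")
  if (is.null(bounds)) bounds <- range(series)
  if (is.null(outputYears)) outputYears <- yrs[yrs >= yrs[1] + window]
  if (!length(outputYears))
    stop("insufficient history: need ", window,
         " years before the first output year")
  if (any(outputYears - window < yrs[1]))
    stop("insufficient history: need ", window,
         " years before the first output year")
  out <- vapply(outputYears, function(y) {
    mean(series[match((y - window):(y - 1L), yrs)])
  }, 0)
  out <- pmin(pmax(out, bounds[1]), bounds[2])
  names(out) <- outputYears
  out
}

# JAGS specification of the hierarchical nest-count state-space model.
.adelieModelString <- "
model {
  for (i in 1:Ncol) {
    lz[i, 1] ~ dnorm(0, 1.0E-4)
    for (t in 2:Tlen[i]) {
      lz[i, t] ~ dnorm(lz[i, t - 1] + mu_r[i], precProc[i])
    }
    mu_r[i] ~ dnorm(b0c + b1c * sicc[i] + b2c * sicc[i] * sicc[i],
                    precR)
    sigma_i[i] ~ dnorm(gamma, precTau) T(0,)
    precProc[i] <- 1 / (sigma_i[i] * sigma_i[i] + 1.0E-12)
  }
  for (k in 1:Nobs) {
    y[k] ~ dnorm(lz[col[k], tix[k]], 1 / (s[k] * s[k] + 1.0E-12))
  }
  # sampled on the centred-SIC scale (sicc = sic - sicCenter) for
  # mixing; mapped back to the raw-scale quadratic coefficients
  b0c ~ dnorm(0, 0.01)
  b1c ~ dnorm(0, 0.01)
  b2c ~ dnorm(0, 0.01)
  beta2 <- b2c
  beta1 <- b1c - 2 * sicCenter * b2c
  beta0 <- b0c - b1c * sicCenter + b2c * sicCenter * sicCenter
  sigma_r ~ dnorm(0, 1) T(0,)
  gamma ~ dnorm(0, 1) T(0,)
  tau ~ dnorm(0, 1) T(0,)
  precR <- 1 / (sigma_r * sigma_r + 1.0E-12)
  precTau <- 1 / (tau * tau + 1.0E-12)
}
"

#' Fit the hierarchical Adelie nest-count model
#'
#' Bayesian fit of the state-space model: true logged abundance evolves
#' as `lz_{i,t} ~ N(lz_{i,t-1} + mu_ri, sigma_i^2)`; colony mean growth
#' is quadratic in long-term SIC, `mu_ri ~ N(b0 + b1 SIC + b2 SIC^2,
#' sigma_r^2)`; per-colony process sds are shrunk through a truncated
#' normal `sigma_i ~ N+(gamma, tau^2)`; observed logged counts carry
#' known observation sds, `y ~ N(lz, s^2)`. Weakly informative priors:
#' `N(0, 10^2)` on the betas, half-normal(1) on the scale parameters.
#' Sampling is by Gibbs/Metropolis via JAGS; the potential scale
#' reduction factor (PSRF) of the top-level parameters is reported, with
#' convergence declared below 1.05.
#'
#' Colonies with fewer than `minCounts` observations (default 10) are
#' dropped before fitting, mirroring the use of long-running colonies
#' only.
#'
#' @param data a [NestCounts-class]
#' @param minCounts minimum counts per included colony
#' @param nChains number of MCMC chains (default 4)
#' @param nAdapt,nBurn,nIter adaptation, burn-in and kept iterations
#' @param thin thinning interval
#' @param seed RNG seed (chains are seeded seed, seed+1, ...)
#' @param quiet suppress JAGS progress output
#' @return list with `draws` (matrix of posterior draws of beta0,
#'   beta1, beta2, sigma_r, gamma, tau), `sigmaI` and `muR` (posterior
#'   means of the per-colony process sds and mean growth rates),
#'   `psrf` (named PSRF values), `converged`, `colonies` (ids used),
#'   and `flags` (character diagnostics, e.g. weak identification with
#'   a single colony)
#' @export
fitAdelieModel <- function(data, minCounts = 10, nChains = 4,
                           nAdapt = 500, nBurn = 1000, nIter = 2000,
                           thin = 1, seed = 1, quiet = TRUE) {
  stopifnot(is(data, "NestCounts"))
  counts <- data@counts
  if (any(!is.finite(counts$y))) stop("non-finite logged counts in data")
  nPer <- table(counts$colony_id)
  keep <- names(nPer)[nPer >= minCounts]
  if (!length(keep))
    stop("no colony has at least ", minCounts, " counts")
  counts <- counts[counts$colony_id %in% keep, ]
  ids <- sort(unique(counts$colony_id))
  flags <- character()
  if (length(ids) < 2)
    flags <- c(flags,
               "single colony: beta2 (and beta1) weakly identified")
  sic <- data@sicMean[ids]
  if (stats::sd(sic) == 0 && length(ids) > 1)
    flags <- c(flags, "no SIC variation across colonies: betas confounded")
  # per-colony time index from first to last observed year
  y0 <- tapply(counts$year, counts$colony_id, min)[ids]
  y1 <- tapply(counts$year, counts$colony_id, max)[ids]
  Tlen <- as.integer(y1 - y0 + 1L)
  colIx <- match(counts$colony_id, ids)
  tix <- counts$year - as.integer(y0[colIx]) + 1L
  sicCenter <- mean(sic)
  dataList <- list(
    Ncol = length(ids), Nobs = nrow(counts), Tlen = Tlen,
    sicc = as.numeric(sic) - sicCenter, sicCenter = sicCenter,
    y = counts$y, s = counts$s,
    col = colIx, tix = tix
  )
  inits <- lapply(seq_len(nChains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch - 1L)
  })
  run <- function() {
    jm <- rjags::jags.model(textConnection(.adelieModelString),
                            data = dataList, inits = inits,
                            n.chains = nChains, n.adapt = nAdapt,
                            quiet = quiet)
    update(jm, nBurn, progress.bar = "none")
    rjags::coda.samples(jm,
                        c("beta0", "beta1", "beta2", "sigma_r",
                          "gamma", "tau", "sigma_i", "mu_r"),
                        n.iter = nIter, thin = thin,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()
  top <- c("beta0", "beta1", "beta2", "sigma_r", "gamma", "tau")
  psrf <- rep(NA_real_, length(top))
  names(psrf) <- top
  if (nChains > 1) {
    gd <- try(coda::gelman.diag(samp[, top, drop = FALSE],
                                multivariate = FALSE,
                                autoburnin = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) psrf <- gd$psrf[top, 1]
  }
  draws <- as.matrix(samp)
  sigmaICols <- grep("^sigma_i(\\[|$)", colnames(draws))
  sigmaI <- colMeans(draws[, sigmaICols, drop = FALSE])
  names(sigmaI) <- ids
  muRCols <- grep("^mu_r(\\[|$)", colnames(draws))
  muR <- colMeans(draws[, muRCols, drop = FALSE])
  names(muR) <- ids
  list(draws = draws[, top, drop = FALSE],
       sigmaI = sigmaI,
       muR = muR,
       psrf = psrf,
       converged = all(is.na(psrf) | psrf < 1.05),
       colonies = ids,
       flags = flags)
}

#' Project Adelie colony growth rates from posterior draws
#'
#' For each parameter draw, the colony-year mean growth
#' `mu_{r,i,t}` is sampled around the quadratic SIC curve with sd
#' `sigma_r`, and the realised annual growth
#' `r_{i,t} ~ N(mu_{r,i,t}, gamma^2)` adds spatio-temporal process
#' variance. With `sigma_r = gamma = 0` the result is the deterministic
#' quadratic in SIC.
#'
#' @param fit result of [fitAdelieModel()], or a matrix/data.frame of
#'   draws with columns beta0, beta1, beta2, sigma_r, gamma
#' @param sicProjection matrix colonies x years of window-averaged,
#'   bias-corrected SIC (fraction)
#' @param nDraws number of growth series per colony (default 100);
#'   parameter draws are sampled with replacement from the posterior
#' @param seed RNG seed
#' @return array `[colony, year, draw]` of annual growth rates, with
#'   dimnames from `sicProjection`
#' @export
projectGrowthAdelie <- function(fit, sicProjection, nDraws = 100,
                                seed = 1) {
  draws <- if (is.list(fit) && !is.data.frame(fit)) fit$draws else fit
  draws <- as.matrix(draws)
  need <- c("beta0", "beta1", "beta2", "sigma_r", "gamma")
  stopifnot(all(need %in% colnames(draws)), is.matrix(sicProjection))
  nc <- nrow(sicProjection)
  ny <- ncol(sicProjection)
  out <- array(NA_real_, dim = c(nc, ny, nDraws),
               dimnames = list(rownames(sicProjection),
                               colnames(sicProjection), NULL))
  .withSeed(seed, {
    pick <- sample.int(nrow(draws), nDraws, replace = TRUE)
    for (d in seq_len(nDraws)) {
      p <- draws[pick[d], ]
      muCurve <- p["beta0"] + p["beta1"] * sicProjection +
        p["beta2"] * sicProjection^2
      mu <- muCurve + stats::rnorm(nc * ny, 0, p["sigma_r"])
      out[, , d] <- mu + stats::rnorm(nc * ny, 0, p["gamma"])
    }
  })
  out
}

#' Intrinsic growth from stage-abundance trajectories
#'
#' The stage-structured pathway: given per-colony stage-abundance
#' vectors over time, the intrinsic growth rate is the log ratio of
#' consecutive stage totals, `r_t = log(sum w(t+1) / sum w(t))`. Stage
#' trajectories are supplied by the user or a generator; the
#' stage-projection matrix itself is outside this package's scope.
#'
#' @param stageSeries matrix stages x time for one colony, or a list of
#'   such matrices (one per colony)
#' @return numeric vector of growth rates (length time-1), or a matrix
#'   colonies x (time-1) for a list input
#' @export
growthFromStageSeries <- function(stageSeries) {
  if (is.list(stageSeries)) {
    return(do.call(rbind, lapply(stageSeries, growthFromStageSeries)))
  }
  stopifnot(is.matrix(stageSeries))
  totals <- colSums(stageSeries)
  if (any(totals <= 0))
    stop("undefined growth: stage totals must stay positive")
  log(totals[-1] / totals[-length(totals)])
}

#' Inter-colony distance-decay dispersal weights
#'
#' Row-stochastic settlement weights: emigrants from colony c settle in
#' colony c' with probability proportional to `exp(-k d_{cc'})` over
#' great-circle distances. Random settlement may return an emigrant to
#' its origin (`includeSelf = TRUE`, the default, since departure is
#' informed but settlement is not); `includeSelf = FALSE` forces all
#' emigrants to other colonies.
#'
#' @param lat,lon colony coordinates, degrees
#' @param calibration `c(distance_km, fraction)` decay calibration, as
#'   in [accessibilityKernel()]
#' @param includeSelf keep the origin colony as a settlement target
#' @return matrix of settlement weights, rows summing to 1
#' @export
dispersalWeights <- function(lat, lon, calibration = EPP_CALIBRATION,
                             includeSelf = TRUE) {
  n <- length(lat)
  if (n < 2) stop("need at least two colonies for dispersal")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- .greatCircleKm(lat, lon, lat[i], lon[i])
    W[i, ] <- accessibilityKernel(d, calibration)
  }
  if (!includeSelf) diag(W) <- 0
  W / rowSums(W)
}

#' Project the metapopulation
#'
#' Each projection year composes a motionless reproduction phase --
#' every colony multiplied by `exp(r_{i,t})` -- with a conservative
#' dispersal phase: a fraction `emigration` of each colony's
#' post-reproduction abundance is redistributed to the other colonies
#' with distance-decay settlement weights. Total abundance is conserved
#' exactly by the dispersal phase. The optional informed-departure mode
#' scales each colony's departure rate up as its local growth falls
#' (`e_i = e * 2 / (1 + exp(5 r_{i,t}))`, capped at 1), approximating
#' informed departure with random distance-decayed settlement.
#'
#' @param n0 named numeric, initial abundance per colony
#' @param growth matrix colonies x years of growth rates, or array
#'   `[colony, year, draw]`
#' @param colonies data.frame(lat, lon) in `n0` order (needed when
#'   `emigration > 0`)
#' @param emigration fraction emigrating per year, in \[0, 1\]
#'   (Adelie default 0.035, the highest observed rate)
#' @param calibration distance-decay calibration for settlement
#' @param informedDeparture logical, see above (default off)
#' @return array `[colony, year+1, draw]` of abundances including the
#'   initial year
#' @export
projectMetapopulation <- function(n0, growth, colonies = NULL,
                                  emigration = 0.035,
                                  calibration = APP_CALIBRATION,
                                  informedDeparture = FALSE) {
  if (emigration < 0 || emigration > 1)
    stop("emigration rate must lie in [0, 1]")
  if (length(dim(growth)) == 2)
    growth <- array(growth, dim = c(dim(growth), 1),
                    dimnames = c(dimnames(growth), list(NULL)))
  nc <- dim(growth)[1]
  ny <- dim(growth)[2]
  nd <- dim(growth)[3]
  stopifnot(length(n0) == nc)
  W <- NULL
  if (emigration > 0) {
    if (is.null(colonies))
      stop("colony coordinates are required when emigration > 0")
    W <- dispersalWeights(colonies$lat, colonies$lon, calibration)
  }
  out <- array(NA_real_, dim = c(nc, ny + 1, nd),
               dimnames = list(names(n0),
                               NULL, NULL))
  for (d in seq_len(nd)) {
    n <- as.numeric(n0)
    out[, 1, d] <- n
    for (t in seq_len(ny)) {
      n <- n * exp(growth[, t, d])               # reproduction phase
      if (emigration > 0) {                       # dispersal phase
        e <- if (informedDeparture)
          pmin(emigration * 2 / (1 + exp(5 * growth[, t, d])), 1)
        else rep(emigration, nc)
        moved <- e * n
        n <- n - moved + as.numeric(crossprod(W, moved))
      }
      out[, t + 1, d] <- n
    }
  }
  out
}

#' Decadal pooled summary
#'
#' Pools all member x year samples in the five years centred on a
#' decade (e.g. 2000 pools 1998-2002) and returns the mean, population
#' sd, and sample count (members x 5; 250 for a 50-member ensemble).
#'
#' @param values matrix members x years with year column names, or any
#'   array whose last dimension is named by year
#' @param decade central year of the decade
#' @param halfWidth years on each side (default 2, i.e. 5 years pooled)
#' @return list(mean, sd, n)
#' @export
decadalAverage <- function(values, decade, halfWidth = 2) {
  yrs <- (decade - halfWidth):(decade + halfWidth)
  dn <- dimnames(values)
  yearNames <- dn[[length(dim(values))]]
  if (is.null(yearNames)) stop("values must have year names on the last dimension")
  sel <- match(as.character(yrs), yearNames)
  if (any(is.na(sel)))
    stop("missing years for decade ", decade, ": ",
         paste(yrs[is.na(sel)], collapse = ", "))
  idx <- slice.index(values, length(dim(values))) %in% sel
  x <- values[idx]
  list(mean = mean(x),
       sd = sqrt(mean((x - mean(x))^2)),
       n = length(x))
}

#' Colony health categories
#'
#' Classifies each colony by its decline from a baseline decade:
#' quasi-extinct (QEX) for declines over 90%, endangered (END) over
#' 50%, vulnerable (VUL) over 30%, otherwise not threatened (NTH,
#' covering growth or decline of at most 30%).
#'
#' @param n abundance per colony in the assessment decade
#' @param baseline abundance per colony in the baseline decade (> 0)
#' @return character vector of categories ("NTH", "VUL", "END", "QEX")
#' @export
colonyHealth <- function(n, baseline) {
  stopifnot(length(n) == length(baseline))
  if (any(baseline <= 0)) stop("baseline abundances must be positive")
  d <- 1 - n / baseline
  out <- ifelse(d > 0.9, "QEX",
                ifelse(d > 0.5, "END",
                       ifelse(d > 0.3, "VUL", "NTH")))
  names(out) <- names(n)
  out
}

#' Colony-catchment sea-ice concentration
#'
#' Mean SIC over grid cells within a great-circle radius of each colony
#' for the given months (default March-June, the post-breeding season),
#' per year. Used to attach a SIC series to each colony when fitting or
#' projecting.
#'
#' @param sic a [GriddedField-class] of SIC (fraction)
#' @param colonies data.frame with lat, lon (and colony_id)
#' @param grid the [Grid-class] the field lives on
#' @param radiusKm catchment radius, default 500
#' @param months months to average, default 3:6
#' @param member ensemble member index or "mean"
#' @return matrix colonies x years of catchment-mean SIC, with colony
#'   ids as row names and years as column names
#' @export
colonyCatchmentSic <- function(sic, colonies, grid, radiusKm = 500,
                               months = 3:6, member = "mean") {
  stopifnot(is(sic, "GriddedField"), is(grid, "Grid"))
  d <- dim(sic@data)
  arr <- if (identical(member, "mean"))
    apply(sic@data, c(2, 3, 4), mean, na.rm = TRUE)
  else array(sic@data[member, , , ], dim = d[2:4])
  nlat <- d[3]
  nlon <- d[4]
  latM <- matrix(latCenters(grid), nlat, nlon)
  lonM <- matrix(lonCenters(grid), nlat, nlon, byrow = TRUE)
  yrs <- sort(unique(fieldYears(sic)))
  out <- matrix(NA_real_, nrow(colonies), length(yrs),
                dimnames = list(colonies$colony_id, yrs))
  sel <- fieldMonths(sic) %in% months
  for (c in seq_len(nrow(colonies))) {
    dKm <- matrix(.greatCircleKm(latM, lonM, colonies$lat[c],
                                 colonies$lon[c]), nlat, nlon)
    inside <- dKm <= radiusKm & !landMask(grid)
    if (!any(inside)) stop("no ocean cells within the catchment of colony ", c)
    for (yi in seq_along(yrs)) {
      tsel <- which(sel & fieldYears(sic) == yrs[yi])
      if (!length(tsel)) next
      vals <- arr[tsel, , , drop = FALSE]
      cellMean <- apply(vals, c(2, 3), mean, na.rm = TRUE)
      out[c, yi] <- mean(cellMean[inside], na.rm = TRUE)
    }
  }
  out
}
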