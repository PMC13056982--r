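# The AEV index: max-scaling and summation of the five layers,
# regional rescaling, percentile bins, and the polynya / protected-area
# summary statistics.

#' Scale layers by their hemispheric maxima and sum
#'
#' Each layer is divided by its maximum over the whole domain; the
#' scaled layers are summed per cell. Inside the seasonal sea-ice zone,
#' a missing layer value (e.g. SST outside the krill range, bottom
#' temperature above the habitability threshold) contributes 0 to the
#' sum at that cell; cells outside the zone stay missing. A layer with
#' no positive values contributes 0 everywhere (warned).
#'
#' @param stack a [LayerStack-class]
#' @return list with `aevSum` (matrix) and `scaledLayers` (named list)
#' @export
scaleAndSum <- function(stack) {
  stopifnot(is(stack, "LayerStack"))
  zone <- stack@zoneMask
  scaled <- list()
  aevSum <- matrix(0, nrow(zone), ncol(zone))
  for (k in names(stack@layers)) {
    lay <- stack@layers[[k]]
    mx <- suppressWarnings(max(lay, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) {
      warning("layer ", k, " has no positive values; it contributes 0")
      sc <- matrix(0, nrow(zone), ncol(zone))
    } else {
      sc <- lay / mx
    }
    scInZone <- sc
    scInZone[is.na(scInZone) & zone] <- 0
    scaled[[k]] <- sc
    aevSum <- aevSum + scInZone
  }
  aevSum[!zone] <- NA_real_
  list(aevSum = aevSum, scaledLayers = scaled)
}

#' Regional (or hemispheric) AEV index
#'
#' Rescales the summed field by the maximum summed value in each
#' region (regional mode) or over the union of all regions
#' (hemispheric mode), giving values from 0 to 1 with 1 at the
#' region's most valuable cell(s). Cells outside every region are
#' missing. Regions whose sums are all zero are returned all-missing
#' with a warning.
#'
#' @param summed output of [scaleAndSum()] (or a bare `aevSum` matrix,
#'   in which case `scaledLayers` are stored empty)
#' @param regions a [RegionSet-class]
#' @param mode "regional" (default) or "hemispheric"
#' @return an [AevResult-class] (bins not yet assigned; see
#'   [binPercentiles()])
#' @export
regionalIndex <- function(summed, regions, mode = c("regional",
                                                    "hemispheric")) {
  mode <- match.arg(mode)
  if (is.matrix(summed)) summed <- list(aevSum = summed,
                                        scaledLayers = list())
  aevSum <- summed$aevSum
  stopifnot(is(regions, "RegionSet"),
            all(dim(aevSum) == regions@gridDim))
  aev <- matrix(NA_real_, nrow(aevSum), ncol(aevSum))
  regNames <- setdiff(regionNames(regions), "Hemi")
  if (mode == "hemispheric") {
    hemi <- regionMask(regions, "Hemi")
    mx <- suppressWarnings(max(aevSum[hemi], na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) {
      warning("hemispheric sums are all zero or missing")
    } else {
      aev[hemi] <- aevSum[hemi] / mx
    }
  } else {
    for (rn in regNames) {
      m <- regionMask(regions, rn)
      vals <- aevSum[m]
      mx <- suppressWarnings(max(vals, na.rm = TRUE))
      if (!is.finite(mx) || mx <= 0) {
        warning("region ", rn, " has all-zero or missing sums; left missing")
        next
      }
      aev[m] <- aevSum[m] / mx
    }
  }
  new("AevResult", aev = aev, aevSum = aevSum,
      bins = matrix(NA_character_, nrow(aev), ncol(aev)),
      scaledLayers = summed$scaledLayers, regions = regions,
      mode = mode, cutoffs = c(5, 10, 25))
}

# Assign bins to a value vector under the strict-quantile tie rule.
.assignBins <- function(v, cutoffs) {
  q <- stats::quantile(v, 1 - cutoffs / 100, names = FALSE, type = 7)
  out <- rep("other", length(v))
  out[v > q[3]] <- "high"
  out[v > q[2]] <- "very_high"
  out[v > q[1]] <- "exceptional"
  out
}

#' Percentile bins of the AEV index
#'
#' Per region, cells are ranked by index value and binned: top 5% ->
#' exceptional, next 5% -> very_high, next 15% -> high, rest -> other
#' (default cutoffs 5/10/25). Quantiles use linear interpolation of
#' order statistics; cells strictly above a cutoff enter the higher
#' bin, so exact ties at a cutoff fall to the lower bin. Counts are
#' unweighted over grid cells (`areaWeighted = TRUE` ranks by
#' area-weighted cumulative fraction instead).
#'
#' @param result an [AevResult-class]
#' @param cutoffs increasing top-percentile cutoffs, default c(5, 10, 25)
#' @param grid a [Grid-class]; only needed for `areaWeighted = TRUE`
#' @param areaWeighted use area-weighted percentiles
#' @return the [AevResult-class] with bins filled in
#' @export
binPercentiles <- function(result, cutoffs = c(5, 10, 25), grid = NULL,
                           areaWeighted = FALSE) {
  stopifnot(is(result, "AevResult"), length(cutoffs) == 3,
            all(diff(cutoffs) > 0))
  bins <- matrix(NA_character_, nrow(result@aev), ncol(result@aev))
  regNames <- if (result@mode == "hemispheric") "Hemi"
  else setdiff(regionNames(result@regions), "Hemi")
  for (rn in regNames) {
    m <- regionMask(result@regions, rn) & !is.na(result@aev)
    idx <- which(m)
    if (length(idx) < 4) {
      warning("region ", rn, " has fewer than 4 scored cells; skipped")
      next
    }
    v <- result@aev[idx]
    if (areaWeighted) {
      stopifnot(is(grid, "Grid"))
      w <- cellArea(grid)[idx]
      ord <- order(v)
      cw <- cumsum(w[ord]) / sum(w)
      b <- rep("other", length(v))
      b[ord][cw > 1 - cutoffs[3] / 100] <- "high"
      b[ord][cw > 1 - cutoffs[2] / 100] <- "very_high"
      b[ord][cw > 1 - cutoffs[1] / 100] <- "exceptional"
      bins[idx] <- b
    } else {
      bins[idx] <- .assignBins(v, cutoffs)
    }
  }
  result@bins <- bins
  result@cutoffs <- cutoffs
  validObject(result)
  result
}

#' Symmetric percent difference
#'
#' `100 * (in - out) / (0.5 * (in + out))`; positive when the inside
#' mean exceeds the outside mean.
#'
#' @param meanIn,meanOut the two means
#' @return percent
#' @export
percentDifference <- function(meanIn, meanOut) {
  denom <- 0.5 * (meanIn + meanOut)
  if (any(denom == 0)) stop("zero denominator in percent difference")
  100 * (meanIn - meanOut) / denom
}

#' Regional polynya statistics of the AEV index
#'
#' Per region (plus "Hemi"): area-weighted mean and sd of the index
#' inside and outside the typical-polynya mask, their symmetric percent
#' difference, the percent of regional area inside polynyas, and the
#' percent of each bin's area inside polynyas. Regions with no polynya
#' cells get missing inside statistics (warned).
#'
#' @param result a binned [AevResult-class]
#' @param polynya logical typical-polynya mask (or a
#'   [PolynyaMap-class])
#' @param grid a [Grid-class]
#' @return data.frame, one row per region
#' @export
polynyaRegionStats <- function(result, polynya, grid) {
  if (is(polynya, "PolynyaMap")) polynya <- typicalMask(polynya)
  stopifnot(is(result, "AevResult"), is(grid, "Grid"),
            all(dim(polynya) == dim(result@aev)))
  area <- cellArea(grid)
  binNames <- c("exceptional", "very_high", "high", "other")
  rows <- lapply(regionNames(result@regions), function(rn) {
    m <- regionMask(result@regions, rn) & !is.na(result@aev)
    inP <- m & polynya
    outP <- m & !polynya
    row <- data.frame(region = rn)
    if (any(inP)) {
      si <- .weightedStats(result@aev[inP], area[inP])
      row$meanInside <- si$mean
      row$sdInside <- si$sd
    } else {
      warning("region ", rn, " has no polynya cells; inside stats missing")
      row$meanInside <- NA_real_
      row$sdInside <- NA_real_
    }
    so <- if (any(outP)) .weightedStats(result@aev[outP], area[outP])
    else list(mean = NA_real_, sd = NA_real_)
    row$meanOutside <- so$mean
    row$sdOutside <- so$sd
    row$pctDifference <- if (any(inP) && any(outP))
      percentDifference(row$meanInside, row$meanOutside) else NA_real_
    row$pctAreaInside <- 100 * sum(area[inP]) / sum(area[m])
    for (b in binNames) {
      bm <- m & !is.na(result@bins) & result@bins == b
      row[[paste0("pct_", b, "_inside")]] <-
        if (any(bm)) 100 * sum(area[bm & polynya]) / sum(area[bm])
        else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Protected-area overlap of the AEV bins
#'
#' Per region: percent of regional area, and of each bin's area, inside
#' the protected-area mask (area-weighted).
#'
#' @param result a binned [AevResult-class]
#' @param mpaMask logical protected-area mask
#' @param grid a [Grid-class]
#' @return data.frame, one row per region
#' @export
mpaOverlap <- function(result, mpaMask, grid) {
  stopifnot(is(result, "AevResult"), is(grid, "Grid"),
            all(dim(mpaMask) == dim(result@aev)))
  area <- cellArea(grid)
  binNames <- c("exceptional", "very_high", "high", "other")
  rows <- lapply(regionNames(result@regions), function(rn) {
    m <- regionMask(result@regions, rn) & !is.na(result@aev)
    row <- data.frame(region = rn)
    row$pctAreaInside <- if (any(m))
      100 * sum(area[m & mpaMask]) / sum(area[m]) else NA_real_
    for (b in binNames) {
      bm <- m & !is.na(result@bins) & result@bins == b
      row[[paste0("pct_", b, "_inside")]] <-
        if (any(bm)) 100 * sum(area[bm & mpaMask]) / sum(area[bm])
        else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Layer contributions to the AEV index
#'
#' Per cell, the percent contribution of each max-scaled layer to the
#' summed index (contributions sum to 100% wherever the sum is
#' positive). For each supplied mask, the area-weighted average
#' contribution of every layer; plus the per-cell dominant layer,
#' flagged ambiguous when the top contribution is less than 1.1 times
#' the second.
#'
#' @param result an [AevResult-class] with scaled layers
#' @param masks named list of logical masks to average over
#' @param grid a [Grid-class]
#' @return list: `contributions` (named list of matrices, percent),
#'   `table` (data.frame mask x layer), `dominant` (character matrix),
#'   `ambiguous` (logical matrix)
#' @export
layerContributions <- function(result, masks = list(), grid) {
  stopifnot(is(result, "AevResult"), length(result@scaledLayers) > 0,
            is(grid, "Grid"))
  zone <- !is.na(result@aevSum)
  denom <- result@aevSum
  denom[denom == 0] <- NA_real_                      # zero-sum cells missing
  contrib <- lapply(result@scaledLayers, function(sc) {
    sc[is.na(sc) & zone] <- 0
    100 * sc / denom
  })
  nms <- names(contrib)
  area <- cellArea(grid)
  tab <- NULL
  if (length(masks)) {
    rows <- lapply(names(masks), function(mn) {
      m <- masks[[mn]] & !is.na(denom)
      row <- data.frame(mask = mn)
      for (k in nms)
        row[[k]] <- if (any(m))
          .weightedStats(contrib[[k]][m], area[m])$mean else NA_real_
      row
    })
    tab <- do.call(rbind, rows)
  }
  nlat <- nrow(denom)
  nlon <- ncol(denom)
  stackArr <- array(unlist(contrib), dim = c(nlat, nlon, length(nms)))
  dominant <- matrix(NA_character_, nlat, nlon)
  ambiguous <- matrix(NA, nlat, nlon)
  scored <- which(!is.na(denom))
  for (i in scored) {
    v <- stackArr[arrayInd(i, c(nlat, nlon))[1],
                  arrayInd(i, c(nlat, nlon))[2], ]
    top2 <- sort(v, decreasing = TRUE)[1:2]
    dominant[i] <- nms[which.max(v)]
    ambiguous[i] <- top2[1] < 1.1 * top2[2]
  }
  list(contributions = contrib, table = tab,
       dominant = dominant, ambiguous = ambiguous)
}
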