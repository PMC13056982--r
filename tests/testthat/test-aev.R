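oneRegion <- function(nlat, nlon, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  new("RegionSet", masks = list(R = mask, Hemi = mask),
      gridDim = as.integer(c(nlat, nlon)))
}

test_that("max-scaling and summation follow the index definition", {
  g <- toyGrid(c(-78, -76), lonStep = 120, latStep = 2)  # 1 x 3 cells
  vals <- list(NPP = matrix(c(1, 2, 4), 1),
               KGP = matrix(c(-0.1, 0.2, 0.1), 1),
               DFP = matrix(c(0, 3, 6), 1),
               EPP = matrix(c(10, 0, 5), 1),
               APP = matrix(c(2, 2, 2), 1))
  st <- toyStack(g, vals)
  got <- scaleAndSum(st)
  expect_equal(as.vector(got$aevSum), c(1.75, 3, 4))
  # constant positive layers sum to the layer count
  cst <- toyStack(g, lapply(vals, function(x) matrix(2, 1, 3)))
  expect_equal(unique(as.vector(scaleAndSum(cst)$aevSum)), 5)
  # an all-zero layer contributes nothing (and warns)
  z <- vals
  z$APP <- matrix(0, 1, 3)
  expect_warning(gz <- scaleAndSum(toyStack(g, z)), "APP")
  expect_equal(as.vector(gz$aevSum), c(1.75, 3, 4) - 1)
  # in-zone missing values count as zero, not missing
  m <- vals
  m$DFP[1, 2] <- NA
  gm <- scaleAndSum(toyStack(g, m))
  expect_equal(as.vector(gm$aevSum), c(1.75, 3 - 0.5, 4))
})

test_that("regional rescaling puts the regional maximum at 1", {
  sums <- matrix(c(2.5, 1.25, 0.5, 1.0), 2, 2)
  rs <- oneRegion(2, 2)
  res <- regionalIndex(list(aevSum = sums, scaledLayers = list()), rs)
  expect_equal(max(aevValues(res)), 1)
  expect_equal(aevValues(res)[1, 1], 1)
  expect_equal(aevValues(res)[2, 1], 0.5)
  # idempotence: rescaling its own output is the identity
  res2 <- regionalIndex(aevValues(res), rs)
  expect_equal(aevValues(res2), aevValues(res))
})

test_that("regional scaling never falls below hemispheric scaling", {
  set.seed(3)
  nlat <- 4; nlon <- 12
  sums <- matrix(runif(nlat * nlon, 0.1, 3), nlat, nlon)
  half1 <- matrix(rep(c(TRUE, FALSE), each = nlon / 2), nlat, nlon,
                  byrow = TRUE)
  rs <- new("RegionSet",
            masks = list(A = half1, B = !half1,
                         Hemi = half1 | !half1),
            gridDim = as.integer(c(nlat, nlon)))
  reg <- regionalIndex(sums, rs, "regional")
  hemi <- regionalIndex(sums, rs, "hemispheric")
  expect_true(all(aevValues(reg) >= aevValues(hemi) - 1e-12, na.rm = TRUE))
})

test_that("percentile bins split 5/5/15/75 with the strict tie rule", {
  set.seed(1)
  v <- sample(seq(0.01, 1, length.out = 100))
  rs <- oneRegion(10, 10)
  res <- regionalIndex(matrix(v, 10, 10), rs)
  res <- binPercentiles(res)
  tab <- table(aevBins(res))
  expect_equal(as.vector(tab[c("exceptional", "very_high", "high",
                               "other")]), c(5, 5, 15, 75))
  # all-equal values: nothing strictly above any cutoff
  resEq <- binPercentiles(regionalIndex(matrix(1, 10, 10), rs))
  expect_true(all(aevBins(resEq) == "other"))
  # 20 distinct values: 1/1/3/15
  res20 <- binPercentiles(regionalIndex(matrix(sample(1:20) / 20, 4, 5),
                                        oneRegion(4, 5)))
  tab20 <- table(aevBins(res20))
  expect_equal(as.vector(tab20[c("exceptional", "very_high", "high",
                                 "other")]), c(1, 1, 3, 15))
  # bins nest as cutoffs widen
  resWide <- binPercentiles(regionalIndex(matrix(v, 10, 10), rs),
                            cutoffs = c(10, 20, 50))
  high1 <- aevBins(res) %in% c("exceptional", "very_high", "high")
  high2 <- aevBins(resWide) %in% c("exceptional", "very_high", "high")
  expect_true(all(high2[high1]))
})

test_that("scale invariance: rescaling any input layer changes nothing", {
  g <- toyGrid(c(-78, -70), lonStep = 45, latStep = 2)   # 4 x 8
  set.seed(8)
  mk <- function() matrix(runif(32, 0, 5), 4, 8)
  vals <- list(NPP = mk(), KGP = mk(), DFP = mk(), EPP = mk(),
               APP = mk())
  rs <- oneRegion(4, 8)
  base <- binPercentiles(regionalIndex(scaleAndSum(toyStack(g, vals)),
                                       rs))
  for (k in names(vals)) {
    v2 <- vals
    v2[[k]] <- v2[[k]] * 37.5
    alt <- binPercentiles(regionalIndex(scaleAndSum(toyStack(g, v2)),
                                        rs))
    expect_equal(aevValues(alt), aevValues(base), tolerance = 1e-12)
    expect_identical(aevBins(alt), aevBins(base))
  }
})

test_that("percent difference matches its printed formula", {
  expect_equal(percentDifference(0.3, 0.3), 0)
  expect_equal(percentDifference(3, 1), 100)
  expect_error(percentDifference(1, -1), "zero")
})

test_that("polynya statistics on a hand-checkable 4-cell region", {
  g <- toyGrid(c(-78, -76), lonStep = 90, latStep = 2)   # 1 x 4, equal areas
  v <- matrix(c(0.2, 0.4, 0.8, 1.0), 1)
  rs <- oneRegion(1, 4)
  res <- binPercentiles(regionalIndex(v, rs))
  poly <- matrix(c(FALSE, FALSE, FALSE, TRUE), 1)
  tab <- polynyaRegionStats(res, poly, g)
  r <- tab[tab$region == "R", ]
  expect_equal(r$meanInside, 1.0)
  expect_equal(r$sdInside, 0)
  expect_equal(r$meanOutside, mean(c(0.2, 0.4, 0.8)), tolerance = 1e-12)
  expect_equal(r$pctDifference,
               100 * (1 - r$meanOutside) / (0.5 * (1 + r$meanOutside)))
  expect_equal(r$pctAreaInside, 25)
  expect_equal(r$pct_exceptional_inside, 100)  # the 1.0 cell is exceptional
  # empty polynya mask: inside missing, outside = whole region
  w <- testthat::capture_warnings(
    tab0 <- polynyaRegionStats(res, matrix(FALSE, 1, 4), g))
  expect_true(length(w) > 0 && all(grepl("no polynya", w)))
  r0 <- tab0[tab0$region == "R", ]
  expect_true(is.na(r0$meanInside))
  whole <- areaWeightedMean(v, matrix(TRUE, 1, 4), g)
  expect_equal(r0$meanOutside, whole$mean)
  expect_equal(r0$sdOutside, whole$sd)
  # bin areas partition the region
  binAreas <- vapply(c("exceptional", "very_high", "high", "other"),
                     function(b) sum(cellArea(g)[aevBins(res) == b]), 0)
  expect_equal(sum(binAreas), sum(cellArea(g)))
})

test_that("protected-area overlap percentages behave at the extremes", {
  g <- toyGrid(c(-78, -76), lonStep = 9, latStep = 2)    # 1 x 40
  v <- matrix(seq(0.025, 1, by = 0.025), 1)              # 40 distinct
  rs <- oneRegion(1, 40)
  res <- binPercentiles(regionalIndex(v, rs))
  full <- mpaOverlap(res, matrix(TRUE, 1, 40), g)
  expect_true(all(full[full$region == "R",
                       grep("pct_", names(full))] == 100))
  none <- mpaOverlap(res, matrix(FALSE, 1, 40), g)
  expect_true(all(none[none$region == "R",
                       grep("pct_", names(none))] == 0))
  # exceptional = top 2 cells; protect exactly one of them -> 50%
  expect_equal(sum(aevBins(res) == "exceptional"), 2L)
  mpa <- matrix(FALSE, 1, 40)
  mpa[1, 40] <- TRUE
  half <- mpaOverlap(res, mpa, g)
  expect_equal(half[half$region == "R", "pct_exceptional_inside"], 50)
})

test_that("layer contributions sum to 100 and flag ambiguous dominance", {
  g <- toyGrid(c(-78, -76), lonStep = 180, latStep = 2)  # 1 x 2
  rs <- oneRegion(1, 2)
  scaled <- list(NPP = matrix(c(0.30, 0.50), 1),
                 KGP = matrix(c(0.28, 0.20), 1),
                 DFP = matrix(c(0.21, 0.10), 1),
                 EPP = matrix(c(0.21, 0.20), 1),
                 APP = matrix(c(0.00, 0.00), 1))
  sums <- Reduce(`+`, scaled)
  res <- regionalIndex(list(aevSum = sums, scaledLayers = scaled), rs)
  lc <- layerContributions(res, masks = list(all = matrix(TRUE, 1, 2)),
                           grid = g)
  perCell <- Reduce(`+`, lc$contributions)
  expect_equal(as.vector(perCell), c(100, 100), tolerance = 1e-10)
  expect_equal(lc$dominant[1, 1], "NPP")
  expect_true(lc$ambiguous[1, 1])        # 30 < 1.1 * 28
  expect_equal(lc$dominant[1, 2], "NPP")
  expect_false(lc$ambiguous[1, 2])       # 50 >= 1.1 * 20
  # a single nonzero layer dominates with 100%, unambiguously
  solo <- list(NPP = matrix(0, 1, 2), KGP = matrix(0, 1, 2),
               DFP = matrix(0, 1, 2), EPP = matrix(c(0.4, 0.9), 1),
               APP = matrix(0, 1, 2))
  resS <- regionalIndex(list(aevSum = Reduce(`+`, solo),
                             scaledLayers = solo), rs)
  lcS <- layerContributions(resS, grid = g)
  expect_equal(as.vector(lcS$contributions$EPP), c(100, 100))
  expect_equal(lcS$dominant[1, 1], "EPP")
  expect_false(lcS$ambiguous[1, 1])
})

test_that("summary tables match an independent cell-by-cell oracle", {
  set.seed(12)
  nlat <- 6; nlon <- 6
  g <- makeGrid(c(-78, -66), lonStep = 60, latStep = 2)
  sums <- matrix(runif(nlat * nlon, 0, 2), nlat, nlon)
  left <- matrix(rep(c(TRUE, FALSE), each = 3), nlat, nlon, byrow = TRUE)
  rs <- new("RegionSet", masks = list(L = left, Rt = !left,
                                      Hemi = left | !left),
            gridDim = as.integer(c(nlat, nlon)))
  res <- binPercentiles(regionalIndex(sums, rs))
  poly <- matrix(runif(nlat * nlon) < 0.3, nlat, nlon)
  mpa <- matrix(runif(nlat * nlon) < 0.4, nlat, nlon)
  tab <- polynyaRegionStats(res, poly, g)
  mtab <- mpaOverlap(res, mpa, g)
  area <- cellArea(g)
  aev <- aevValues(res)
  bins <- aevBins(res)
  for (rn in c("L", "Rt", "Hemi")) {
    m <- regionMask(rs, rn)
    # oracle: direct loops over cells
    wIn <- 0; sIn <- 0; wOut <- 0; sOut <- 0
    for (i in 1:nlat) for (j in 1:nlon) {
      if (!m[i, j]) next
      if (poly[i, j]) { wIn <- wIn + area[i, j]
        sIn <- sIn + area[i, j] * aev[i, j] }
      else { wOut <- wOut + area[i, j]
        sOut <- sOut + area[i, j] * aev[i, j] }
    }
    row <- tab[tab$region == rn, ]
    if (wIn > 0) expect_equal(row$meanInside, sIn / wIn, tolerance = 1e-12)
    expect_equal(row$meanOutside, sOut / wOut, tolerance = 1e-12)
    expect_equal(row$pctAreaInside, 100 * wIn / (wIn + wOut),
                 tolerance = 1e-12)
    for (b in c("exceptional", "very_high", "high", "other")) {
      bm <- m & bins == b
      if (!any(bm)) next
      expect_equal(tab[tab$region == rn, paste0("pct_", b, "_inside")],
                   100 * sum(area[bm & poly]) / sum(area[bm]),
                   tolerance = 1e-12)
      expect_equal(mtab[mtab$region == rn, paste0("pct_", b, "_inside")],
                   100 * sum(area[bm & mpa]) / sum(area[bm]),
                   tolerance = 1e-12)
    }
  }
})
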