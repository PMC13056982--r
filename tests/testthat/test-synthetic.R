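smallGrid <- function() {
  g <- makeGrid(c(-78, -50), lonStep = 10, latStep = 2)
  landMask(g) <- syntheticLandMask(g)
  g
}

test_that("environment generator is deterministic and member-consistent", {
  g <- smallGrid()
  cfg0 <- scenarioConfig(years = 2000:2001, nMembers = 2,
                         iceDeclineRate = 0,
                         noiseSd = c(SIC = 0, SIT = 0, SST = 0, TBOT = 0,
                                     CHL = 0, NPP = 0, DFP_raw = 0),
                         seed = 9)
  env <- generateEnvironment(g, cfg0)
  # no noise, no decline: members identical
  for (f in names(env))
    expect_identical(fieldData(env[[f]])[1, , , ],
                     fieldData(env[[f]])[2, , , ])

  cfg1 <- scenarioConfig(years = 2000:2001, nMembers = 2, seed = 4)
  a <- generateEnvironment(g, cfg1)
  b <- generateEnvironment(g, cfg1)
  for (f in names(a))
    expect_identical(fieldData(a[[f]]), fieldData(b[[f]]))
  c2 <- generateEnvironment(g, scenarioConfig(years = 2000:2001,
                                              nMembers = 2, seed = 5))
  expect_false(identical(fieldData(a$SIC), fieldData(c2$SIC)))
})

test_that("generated fields satisfy the physical-range and phase invariants", {
  g <- smallGrid()
  env <- generateEnvironment(g, scenarioConfig(years = 2000:2002,
                                               nMembers = 3, seed = 2))
  sic <- fieldData(env$SIC)
  sit <- fieldData(env$SIT)
  expect_true(all(sic >= 0 & sic <= 1, na.rm = TRUE))
  expect_true(all(sit >= 0, na.rm = TRUE))
  # ensemble-mean September SIC exceeds February SIC wherever there is ice
  mo <- fieldMonths(env$SIC)
  sep <- apply(sic[, mo == 9, , , drop = FALSE], 3:4, mean, na.rm = TRUE)
  feb <- apply(sic[, mo == 2, , , drop = FALSE], 3:4, mean, na.rm = TRUE)
  iced <- !is.na(sep) & sep > 0.05
  expect_true(all(sep[iced] > feb[iced]))
})

test_that("polynya pockets open the ice and amplify the bloom", {
  g <- smallGrid()
  poly <- data.frame(lat = -71, lon = 95, radiusKm = 200, openness = 0.5)
  cfg <- scenarioConfig(years = 2000, nMembers = 1, iceDeclineRate = 0,
                        polynyas = poly, bloomAmplification = 2,
                        noiseSd = c(SIC = 0, SIT = 0, SST = 0, TBOT = 0,
                                    CHL = 0, NPP = 0, DFP_raw = 0),
                        seed = 1)
  env <- generateEnvironment(g, cfg)
  sep <- which(fieldMonths(env$SIC) == 9)[1]
  iLat <- which.min(abs(latCenters(g) - -71))
  jIn <- which.min(abs(lonCenters(g) - 95))
  sicRow <- fieldData(env$SIC)[1, sep, iLat, ]
  ambient <- sicRow[which.min(abs(lonCenters(g) - 255))]  # same lat, far away
  expect_equal(sicRow[jIn], 0.5 * ambient, tolerance = 1e-12)
  # polynya cells: less ice, more chlorophyll than the zonal mean (summer)
  janIdx <- which(fieldMonths(env$CHL) == 1)[1]
  chlRow <- fieldData(env$CHL)[1, janIdx, iLat, ]
  ocean <- !landMask(g)[iLat, ]
  expect_gt(chlRow[jIn], mean(chlRow[ocean & seq_along(chlRow) != jIn]))
  sitRow <- fieldData(env$SIT)[1, sep, iLat, ]
  expect_lt(sitRow[jIn], mean(sitRow[ocean & seq_along(sitRow) != jIn]))
})

test_that("colony generator places coastal colonies reproducibly", {
  g <- smallGrid()
  col <- generateColonies(g, 66, seed = 3)
  expect_equal(nrow(col), 66L)
  expect_identical(col, generateColonies(g, 66, seed = 3))
  # every colony on an ocean cell adjacent to land
  land <- landMask(g)
  for (k in seq_len(nrow(col))) {
    i <- match(col$lat[k], latCenters(g))
    j <- match(col$lon[k], lonCenters(g))
    expect_false(land[i, j])
    nb <- c(if (i > 1) land[i - 1, j], if (i < nrow(land)) land[i + 1, j],
            land[i, ifelse(j == 1, ncol(land), j - 1)],
            land[i, ifelse(j == ncol(land), 1, j + 1)])
    expect_true(any(nb))
  }
  fixed <- generateColonies(g, 10, abundanceRange = c(100, 100), seed = 1)
  expect_true(all(fixed$abundance == 100))
  gOcean <- makeGrid(c(-78, -50), 10, 2)    # all ocean, no coast
  expect_error(generateColonies(gOcean, 5), "coastal")
})

test_that("nest-count generator reduces to exact exponential growth", {
  sic <- c(a = 0.4, b = 0.6)
  truth0 <- list(beta0 = 0.02, beta1 = 0, beta2 = 0,
                 sigmaR = 0, gamma = 0, tau = 0)
  nc <- generateNestCounts(truth0, sic, 2000:2009, obsErrorSd = 0,
                           seed = 1)
  cts <- nestCounts(nc)
  for (id in c("a", "b")) {
    y <- cts$y[cts$colony_id == id]
    expect_equal(diff(y), rep(0.02, 9), tolerance = 1e-12)
  }
  # beta1 = beta2 = 0: growth independent of SIC
  slopes <- tapply(cts$y, cts$colony_id, function(y) mean(diff(y)))
  expect_equal(unname(diff(slopes)), 0, tolerance = 1e-12)
  expect_error(
    generateNestCounts(list(beta0 = 0, beta1 = 0, beta2 = 0,
                            sigmaR = -1, gamma = 0, tau = 0),
                       sic, 2000:2005),
    "non-negative")
})
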