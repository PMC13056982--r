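test_that("bias correction matches hand arithmetic and the affine property", {
  # identity when model stats equal observed stats
  yrs <- 1979:2018
  obs <- stats::setNames(sin(yrs / 3) * 0.1 + 0.5, yrs)
  expect_equal(biasCorrect(obs, obs, yrs), obs)
  # hand example: theta_m=0.6, delta_m=0.2, theta_o=0.5, delta_o=0.1
  model <- stats::setNames(c(0.4, 0.8, 0.8, 0.4), 2001:2004)  # mean .6
  obs2 <- stats::setNames(c(0.4, 0.6, 0.6, 0.4), 2001:2004)   # mean .5
  dm <- stats::sd(model)
  do <- stats::sd(obs2)
  got <- biasCorrect(model, obs2, 2001:2004)
  expect_equal(unname(got["2002"]), (do / dm) * (0.8 - 0.6) + 0.5)
  # with delta ratio exactly 0.5 this is 0.6
  expect_equal(unname(got["2002"]), 0.6)
  expect_error(biasCorrect(stats::setNames(rep(1, 4), 2001:2004), obs2,
                           2001:2004), "degenerate")
})

test_that("bias correction equalises calibration-window moments per colony", {
  set.seed(5)
  yrs <- 1979:2018
  n <- 25
  model <- matrix(runif(n * length(yrs), 0.2, 0.9), n,
                  dimnames = list(NULL, yrs))
  obs <- matrix(runif(n * length(yrs), 0.3, 0.8), n,
                dimnames = list(NULL, yrs))
  corr <- biasCorrect(model, obs, yrs)
  for (i in seq_len(n)) {
    expect_equal(mean(corr[i, ]), mean(obs[i, ]), tolerance = 1e-10)
    expect_equal(stats::sd(corr[i, ]), stats::sd(obs[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("trailing window average lags, clamps, and needs history", {
  yrs <- 1900:2000
  cst <- stats::setNames(rep(0.4, length(yrs)), yrs)
  expect_equal(unname(windowAverageSic(cst, 40)["1960"]), 0.4)
  ramp <- stats::setNames(seq_along(yrs) * 0.001, yrs)
  out <- windowAverageSic(ramp, 40, bounds = c(-Inf, Inf))
  # value at 1960: mean of 1920..1959 entries (indices 21..60)
  expect_equal(unname(out["1960"]), mean(ramp[21:60]))
  clamped <- windowAverageSic(ramp, 40, bounds = c(0, 0.035))
  expect_true(all(clamped <= 0.035))
  expect_error(windowAverageSic(cst[1:30], 40), "insufficient|history")
})

test_that("stage-series growth is the log ratio of totals", {
  w <- matrix(c(60, 40, 66, 44), 2)   # totals 100 -> 110
  expect_equal(growthFromStageSeries(w), c(log(1.1)),
               ignore_attr = TRUE)
  cst <- matrix(c(60, 40, 60, 40, 60, 40), 2)
  expect_equal(unname(growthFromStageSeries(cst)), c(0, 0))
  bad <- matrix(c(1, 1, 0, 0), 2)
  expect_error(growthFromStageSeries(bad), "positive")
})

test_that("growth projection reduces to the quadratic when noise is off", {
  draws <- matrix(c(0, 1, 0, 0, 0), 1,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2",
                                          "sigma_r", "gamma")))
  sic <- matrix(0.3, 2, 3, dimnames = list(c("a", "b"), 2001:2003))
  r <- projectGrowthAdelie(draws, sic, nDraws = 5, seed = 1)
  expect_true(all(r == 0.3))
  # reproducible under the same seed
  draws2 <- matrix(c(-0.1, 0.6, -0.55, 0.05, 0.05), 1,
                   dimnames = dimnames(draws))
  r1 <- projectGrowthAdelie(draws2, sic, nDraws = 5, seed = 9)
  r2 <- projectGrowthAdelie(draws2, sic, nDraws = 5, seed = 9)
  expect_identical(r1, r2)
})

test_that("metapopulation dispersal conserves abundance and r=0 is static", {
  set.seed(2)
  nC <- 8
  cols <- data.frame(lat = runif(nC, -75, -65), lon = runif(nC, 0, 360))
  n0 <- stats::setNames(runif(nC, 1e3, 1e5), paste0("c", 1:nC))
  # r = 0 everywhere, positive emigration: total constant for 100 years
  g0 <- matrix(0, nC, 100)
  out <- projectMetapopulation(n0, g0, cols, emigration = 0.035)
  totals <- colSums(out[, , 1])
  expect_equal(totals, rep(sum(n0), 101), tolerance = 1e-10)
  # e = 0: independent exponential updates
  gr <- matrix(rnorm(nC * 10, 0, 0.1), nC, 10)
  ind <- projectMetapopulation(n0, gr, emigration = 0)
  expect_equal(ind[, 11, 1], n0 * exp(rowSums(gr)), tolerance = 1e-12)
  # dispersal phase conserves even with growth
  wet <- projectMetapopulation(n0, gr, cols, emigration = 0.2)
  stepTotal <- sum(wet[, 5, 1] * exp(gr[, 5]))
  expect_equal(sum(wet[, 6, 1]), stepTotal, tolerance = 1e-10)
  expect_error(projectMetapopulation(n0, gr, cols, emigration = 1.5),
               "emigration")
})

test_that("two coincident colonies exchange half the emigration rate", {
  cols <- data.frame(lat = c(-70, -70), lon = c(10, 10))
  n0 <- c(a = 1000, b = 1000)
  g <- matrix(0, 2, 1)
  out <- projectMetapopulation(n0, g, cols, emigration = 0.035)
  # equal settlement weights: each colony sends e/2 = 1.75% to the other
  expect_equal(unname(out[1, 2, 1]), 1000)   # symmetric -> unchanged
  W <- dispersalWeights(cols$lat, cols$lon, APP_CALIBRATION)
  expect_equal(W, matrix(0.5, 2, 2))
  asym <- projectMetapopulation(c(a = 1000, b = 0), g, cols,
                                emigration = 0.035)
  expect_equal(unname(asym[2, 2, 1]), 1000 * 0.035 / 2)
})

test_that("decadal pooling counts members x 5 years", {
  vals <- matrix(seq_len(10), 2, 5, dimnames = list(NULL, 1998:2002))
  got <- decadalAverage(vals, 2000)
  expect_equal(got$n, 10L)
  expect_equal(got$mean, 5.5)
  cst <- matrix(7, 4, 5, dimnames = list(NULL, 1998:2002))
  expect_equal(decadalAverage(cst, 2000)$sd, 0)
  expect_error(decadalAverage(vals, 2010), "missing years")
})

test_that("colony health thresholds partition decline fractions", {
  base <- rep(100, 6)
  n <- c(5, 9.9, 40, 60, 71, 120)
  got <- colonyHealth(n, base)
  expect_equal(unname(got), c("QEX", "QEX", "END", "VUL", "NTH", "NTH"))
  # monotone in decline: every colony exactly one label
  d <- seq(0, 1.2, by = 0.01)
  lab <- colonyHealth(100 * (1 - d), rep(100, length(d)))
  ord <- c(NTH = 1, VUL = 2, END = 3, QEX = 4)
  expect_true(all(diff(ord[lab]) >= 0))
  expect_error(colonyHealth(10, 0), "positive")
})

test_that("the state-space fit pins mean growth when noise vanishes", {
  truth0 <- list(beta0 = 0.05, beta1 = -0.1, beta2 = 0,
                 sigmaR = 0, gamma = 0, tau = 0)
  sic <- c(a = 0.2, b = 0.8)
  nc <- generateNestCounts(truth0, sic, 2001:2012, obsErrorSd = 1e-4,
                           seed = 2)
  slopeTruth <- truth0$beta0 + truth0$beta1 * sic
  fit <- fitAdelieModel(nc, minCounts = 10, nChains = 2, nAdapt = 200,
                        nBurn = 300, nIter = 500, seed = 1)
  expect_equal(unname(fit$muR[c("a", "b")]), unname(slopeTruth),
               tolerance = 1e-3)
  expect_true(length(fit$flags) == 0)
})

test_that("a single colony fits but is flagged weakly identified", {
  truth0 <- list(beta0 = 0.02, beta1 = 0, beta2 = 0,
                 sigmaR = 0.01, gamma = 0.02, tau = 0.005)
  nc <- generateNestCounts(truth0, c(only = 0.5), 2001:2015,
                           obsErrorSd = 0.05, seed = 3)
  fit <- fitAdelieModel(nc, nChains = 2, nAdapt = 200, nBurn = 200,
                        nIter = 400, seed = 1)
  expect_true(any(grepl("weakly identified", fit$flags)))
  expect_error(fitAdelieModel(nc, minCounts = 20), "at least")
})

test_that("colony catchment SIC averages cells within the radius", {
  g <- makeGrid(c(-78, -60), lonStep = 10, latStep = 2)
  nlat <- length(latCenters(g)); nlon <- length(lonCenters(g))
  yrs <- rep(2000L, 12); mos <- 1:12
  arr <- array(NA_real_, c(1, 12, nlat, nlon))
  for (t in 1:12) arr[1, t, , ] <- outer(latCenters(g) / -100, rep(1, nlon))
  sic <- new("GriddedField", name = "SIC", units = "1", data = arr,
             years = yrs, months = mos)
  col <- data.frame(colony_id = "x", lat = -71, lon = 95)
  got <- colonyCatchmentSic(sic, col, g, radiusKm = 300, months = 3:6)
  # catchment at 300 km on a 10-degree grid: only the colony's own cell row
  expect_equal(dim(got), c(1L, 1L))
  expect_true(abs(got[1, 1] - 0.71) < 0.02)
})
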