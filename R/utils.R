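# Internal geometry and statistics helpers.

.EARTH_RADIUS_KM <- 6371

# Spherical cell area (km^2) for cell-centre latitudes and steps in degrees.
.sphericalCellArea <- function(latCenters, latStep, lonStep) {
  dlat <- latStep * pi / 180
  dlon <- lonStep * pi / 180
  .EARTH_RADIUS_KM^2 * cos(latCenters * pi / 180) * dlat * dlon
}

# Great-circle distance (km) between points (lat1, lon1) and (lat2, lon2),
# degrees; vectorised over the first set. Spherical Earth, R = 6371 km.
.greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  wrap <- function(x) ((as.vector(x) + 180) %% 360) - 180
  geosphere::distCosine(cbind(wrap(lon1), as.vector(lat1)),
                        cbind(wrap(lon2), as.vector(lat2)),
                        r = .EARTH_RADIUS_KM)
}

# Shortest angular separation between two longitudes, degrees in [0, 180].
.lonSeparation <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Weighted mean / population sd / count over non-missing values.
.weightedStats <- function(x, w) {
  keep <- !is.na(x)
  x <- x[keep]
  w <- w[keep]
  if (!length(x)) stop("empty selection: no non-missing cells under the mask")
  W <- sum(w)
  m <- sum(w * x) / W
  s <- sqrt(sum(w * (x - m)^2) / W)
  list(mean = m, sd = s, n = length(x))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce to 4-d [member, time, lat, lon]; matrices become [1, 1, lat, lon].
.as4d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1, 1, dim(x)))
  else if (length(dim(x)) == 3) array(x, dim = c(1, dim(x)))
  else x
}
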