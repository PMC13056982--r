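# Grid construction, region masks and area-weighted statistics.

#' Construct a regular circumpolar grid
#'
#' Builds a regular latitude/longitude grid south of 50 degrees S with
#' spherical cell areas (Earth radius 6371 km) and an all-ocean default
#' land mask. Longitude always spans the full circle \[0, 360).
#'
#' @param latRange length-2 numeric, cell-edge latitude range within
#'   \[-90, -50\] degrees north (e.g. `c(-78, -60)`)
#' @param lonStep,latStep grid spacing in degrees; must divide the ranges
#'   evenly
#' @return a [Grid-class]
#' @examples
#' g <- makeGrid(c(-78, -60), lonStep = 2, latStep = 2)
#' dim(cellArea(g))
#' @export
makeGrid <- function(latRange = c(-78, -50), lonStep = 1, latStep = 1) {
  if (latStep <= 0 || lonStep <= 0)
    stop("latStep and lonStep must be positive")
  latRange <- sort(as.numeric(latRange))
  if (latRange[1] < -90 || latRange[2] > -50)
    stop("latRange must lie within [-90, -50]")
  nlat <- (latRange[2] - latRange[1]) / latStep
  nlon <- 360 / lonStep
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9)
    stop("steps must divide the latitude range and 360 degrees evenly")
  nlat <- as.integer(round(nlat))
  nlon <- as.integer(round(nlon))
  lat <- latRange[1] + (seq_len(nlat) - 0.5) * latStep
  lon <- (seq_len(nlon) - 0.5) * lonStep
  area <- matrix(.sphericalCellArea(lat, latStep, lonStep),
                 nrow = nlat, ncol = nlon)
  new("Grid", latCenters = lat, lonCenters = lon,
      latStep = latStep, lonStep = lonStep, cellArea = area,
      landMask = matrix(FALSE, nlat, nlon))
}

#' Default management-region longitude sectors
#'
#' Longitude sectors (degrees east, `[start, end)` with wrap when
#' `start > end`) approximating the five CCAMLR-style planning regions:
#' Weddell Sea (60W-30E), East Antarctic (30E-150E), Ross Sea
#' (150E-140W), Amundsen Sea (140W-90W) and Antarctic Peninsula
#' (90W-60W). Shipped as an editable list so boundaries can be adjusted
#' per analysis.
#'
#' @return named list of two-column sector matrices
#' @export
defaultRegionBoundaries <- function() {
  list(
    WS = list(c(300, 30)),
    EA = list(c(30, 150)),
    RS = list(c(150, 220)),
    AS = list(c(220, 270)),
    AP = list(c(270, 300))
  )
}

# Is longitude x inside sector [start, end), wrap-aware?
.inSector <- function(x, start, end) {
  if (start <= end) x >= start & x < end else x >= start | x < end
}

#' Build region masks from longitude sectors
#'
#' Assigns every ocean cell south of 60 degrees S to at most one of the
#' named regions by its longitude sector; overlapping sectors are an
#' error. A "Hemi" mask (the union of all regions) is added.
#'
#' @param grid a [Grid-class]
#' @param boundaries named list of sectors as from
#'   [defaultRegionBoundaries()]; each sector is `c(start, end)` degrees
#'   east, wrap-aware
#' @param southOf latitude cutoff, default -60
#' @return a [RegionSet-class]
#' @export
regionMasks <- function(grid, boundaries = defaultRegionBoundaries(),
                        southOf = -60) {
  stopifnot(is(grid, "Grid"))
  lat <- latCenters(grid)
  lon <- lonCenters(grid)
  nlat <- length(lat)
  nlon <- length(lon)
  eligible <- outer(lat < southOf, rep(TRUE, nlon)) & !landMask(grid)
  cover <- matrix(0L, nlat, nlon)
  masks <- list()
  for (rn in names(boundaries)) {
    inLon <- rep(FALSE, nlon)
    for (sec in boundaries[[rn]])
      inLon <- inLon | .inSector(lon, sec[1] %% 360, sec[2] %% 360)
    m <- eligible & matrix(inLon, nlat, nlon, byrow = TRUE)
    cover <- cover + matrix(as.integer(inLon), nlat, nlon, byrow = TRUE)
    masks[[rn]] <- m
  }
  if (any(cover > 1))
    stop("overlapping region sectors in boundary specification")
  masks[["Hemi"]] <- Reduce(`|`, masks)
  new("RegionSet", masks = masks, gridDim = c(nlat, nlon))
}

#' Area-weighted mean, standard deviation and count
#'
#' Statistics of a field over the cells selected by `mask`, weighted by
#' cell area. Missing values are excluded from both the statistic and
#' the weights. The standard deviation uses the weighted population
#' formula (divide by total weight, no dof correction).
#'
#' @param field numeric matrix (nlat x nlon), or a [GriddedField-class]
#'   with singleton member/time dimensions
#' @param mask logical matrix selecting cells
#' @param grid a [Grid-class] providing cell areas
#' @return list with elements `mean`, `sd`, `n`
#' @examples
#' g <- makeGrid(c(-78, -60), 10, 2)
#' f <- matrix(1, 9, 36)
#' areaWeightedMean(f, !landMask(g), g)$mean
#' @export
areaWeightedMean <- function(field, mask, grid) {
  if (is(field, "GriddedField")) {
    d <- dim(field@data)
    if (d[1] != 1 || d[2] != 1)
      stop("pass a single member/time slice, or a matrix")
    field <- matrix(field@data[1, 1, , ], d[3], d[4])
  }
  stopifnot(is(grid, "Grid"), all(dim(field) == dim(cellArea(grid))),
            all(dim(mask) == dim(field)))
  if (!any(mask)) stop("empty selection: mask selects no cells")
  .weightedStats(field[mask], cellArea(grid)[mask])
}
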