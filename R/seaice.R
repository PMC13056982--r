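# Seasonal sea-ice zone, polynya detection by thresholded connected
# components, and typical-polynya frequency maps.
#
# A polynya is a contiguous pocket of cells below the threshold (SIC or
# SIT) enclosed by land and/or above-threshold ice. Components are
# longitude-wrap aware. The below-threshold component that touches the
# northernmost ocean row of the domain is the open ocean and is never a
# polynya; neither is anything connected to it.

#' Seasonal sea-ice zone
#'
#' Ocean cells whose multi-year September-mean sea-ice concentration is
#' at least the threshold (default 15%). Members are pooled into the
#' mean.
#'
#' @param sic a [GriddedField-class] of SIC as fraction
#' @param years years to average over (default: all years present)
#' @param threshold fraction, default 0.15
#' @param land logical land mask; land cells are excluded
#' @return logical matrix, `TRUE` = in the seasonal sea-ice zone
#' @export
seasonalIceZone <- function(sic, years = unique(fieldYears(sic)),
                            threshold = 0.15, land = NULL) {
  stopifnot(is(sic, "GriddedField"))
  sel <- which(fieldMonths(sic) == 9L & fieldYears(sic) %in% years)
  if (!length(sel)) stop("no September time steps in the requested years")
  d <- dim(sic@data)
  sept <- sic@data[, sel, , , drop = FALSE]
  mean2 <- apply(sept, c(3, 4), mean, na.rm = TRUE)
  zone <- !is.na(mean2) & mean2 >= threshold
  if (!is.null(land)) zone <- zone & !land
  zone
}

# Linear-index neighbours of (r, c) with longitude (column) wrap.
.neighborIdx <- function(r, c, nr, nc, connectivity) {
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  rr <- r + dr
  cc <- ((c - 1L + dc) %% nc) + 1L
  keep <- rr >= 1L & rr <= nr
  (cc[keep] - 1L) * nr + rr[keep]
}

# Label connected below-threshold components (0 = background).
.labelComponents <- function(below, connectivity = 4L) {
  nr <- nrow(below)
  nc <- ncol(below)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(below)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    stack <- start
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cell - 1L) %% nr) + 1L
      c <- ((cell - 1L) %/% nr) + 1L
      for (k in .neighborIdx(r, c, nr, nc, connectivity)) {
        if (below[k] && labels[k] == 0L) {
          labels[k] <- cur
          stack <- c(stack, k)
        }
      }
    }
  }
  labels
}

#' Detect polynyas in one field snapshot
#'
#' Cells strictly below the threshold are partitioned into connected
#' components (4- or 8-neighbourhood, wrap-aware in longitude).
#' Components touching the northernmost ocean row of the domain belong
#' to the open ocean and are discarded; the remaining components -- each
#' enclosed by land and/or above-threshold cells -- are polynyas,
#' labelled 1..K.
#'
#' @param field numeric matrix (nlat x nlon) of SIC (fraction) or SIT
#'   (m) at one time step; rows ordered south to north
#' @param threshold positive threshold (0.85 for SIC, 0.4 m for SIT)
#' @param land logical land mask
#' @param connectivity 4 (default) or 8
#' @param variable label stored with the result ("SIC" or "SIT")
#' @return a [PolynyaMap-class] with a single time step
#' @export
detectPolynyas <- function(field, threshold, land,
                           connectivity = 4L, variable = "SIT") {
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(4L, 8L), threshold > 0,
            is.matrix(field), all(dim(field) == dim(land)))
  if (all(land)) stop("all-land field: nothing to detect")
  below <- !land & !is.na(field) & field < threshold
  labels <- .labelComponents(below, connectivity)
  # open ocean: the component(s) touching the northernmost ocean row
  oceanRows <- which(apply(!land, 1, any))
  northRow <- max(oceanRows)
  openIds <- setdiff(unique(labels[northRow, ]), 0L)
  labels[labels %in% openIds] <- 0L
  # renumber 1..K
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids)) labels[] <- match(labels, c(0L, ids)) - 1L
  lab3 <- array(labels, dim = c(1L, nrow(field), ncol(field)))
  freq <- (labels > 0) * 1
  new("PolynyaMap", labels = lab3, frequency = freq,
      typicalMask = freq > 0.10, threshold = threshold,
      variable = variable, connectivity = connectivity, cutoff = 0.10)
}

#' Polynya label maps for every time step of a field
#'
#' Runs [detectPolynyas()] on each time step (of one ensemble member or
#' of the ensemble mean) and attaches the frequency map and
#' typical-polynya mask via [polynyaFrequency()].
#'
#' @param field a [GriddedField-class] (SIC fraction or SIT metres)
#' @param threshold threshold value (default 0.4, the SIT threshold for
#'   model fields; use 0.85 for satellite-style SIC)
#' @param land logical land mask
#' @param connectivity 4 or 8
#' @param member ensemble member index, or "mean" for the ensemble mean
#' @param cutoff typical-polynya frequency cutoff (strict), default 0.10
#' @return a [PolynyaMap-class]
#' @export
polynyaSeries <- function(field, threshold = 0.4, land,
                          connectivity = 4L, member = "mean",
                          cutoff = 0.10) {
  stopifnot(is(field, "GriddedField"))
  d <- dim(field@data)
  arr <- if (identical(member, "mean"))
    apply(field@data, c(2, 3, 4), mean, na.rm = TRUE)
  else array(field@data[member, , , ], dim = d[2:4])
  labs <- array(0L, dim = d[2:4])
  for (t in seq_len(d[2])) {
    pm <- detectPolynyas(matrix(arr[t, , ], d[3], d[4]), threshold, land,
                         connectivity, variable = field@name)
    labs[t, , ] <- pm@labels[1, , ]
  }
  polynyaFrequency(labs, cutoff = cutoff, threshold = threshold,
                   variable = field@name, connectivity = connectivity)
}

#' Typical-polynya frequency map
#'
#' Per-cell fraction of time steps with a nonzero polynya label; cells
#' labelled in strictly more than `cutoff` of steps form the typical
#' polynya mask.
#'
#' @param labels integer array `[time, lat, lon]` of polynya labels, or
#'   a [PolynyaMap-class]
#' @param cutoff frequency cutoff (strict inequality), default 0.10
#' @param threshold,variable,connectivity metadata carried into the
#'   result
#' @return a [PolynyaMap-class]
#' @export
polynyaFrequency <- function(labels, cutoff = 0.10, threshold = NA_real_,
                             variable = "SIT", connectivity = 4L) {
  if (is(labels, "PolynyaMap")) {
    threshold <- labels@threshold
    variable <- labels@variable
    connectivity <- labels@connectivity
    labels <- labels@labels
  }
  stopifnot(length(dim(labels)) == 3, dim(labels)[1] >= 1)
  freq <- apply(labels > 0, c(2, 3), mean)
  new("PolynyaMap", labels = labels, frequency = freq,
      typicalMask = freq > cutoff, threshold = threshold,
      variable = variable, connectivity = as.integer(connectivity),
      cutoff = cutoff)
}
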