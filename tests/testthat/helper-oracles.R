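# Independent oracles, kept deliberately different in algorithm from
# the package implementation.

# Connected-component labelling by iterative minimum-label propagation
# (longitude columns wrap). Returns 0 for background cells.
oracleLabel <- function(below, connectivity = 4L) {
  nr <- nrow(below)
  nc <- ncol(below)
  ids <- matrix(0L, nr, nc)
  ids[below] <- seq_len(sum(below))
  offsets <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!below[r, c]) next
      best <- ids[r, c]
      for (o in offsets) {
        rr <- r + o[1]
        cc <- ((c - 1 + o[2]) %% nc) + 1
        if (rr >= 1 && rr <= nr && below[rr, cc])
          best <- min(best, ids[rr, cc])
      }
      if (best < ids[r, c]) {
        ids[r, c] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ids
}

# Full polynya rule: components of below-threshold cells, minus every
# component touching the northernmost ocean row. Returns the list of
# components as sorted cell-index vectors (order-free representation).
oraclePolynyaComponents <- function(field, threshold, land,
                                    connectivity = 4L) {
  below <- !land & !is.na(field) & field < threshold
  ids <- oracleLabel(below, connectivity)
  northRow <- max(which(apply(!land, 1, any)))
  openIds <- setdiff(unique(ids[northRow, ]), 0L)
  keep <- setdiff(unique(ids[ids > 0]), openIds)
  comps <- lapply(keep, function(k) sort(which(ids == k)))
  comps[order(vapply(comps, `[`, 0L, 1))]
}

# Component list from a label matrix (for comparing partitions up to
# renumbering).
componentsFromLabels <- function(labels) {
  keep <- setdiff(unique(labels[labels > 0]), 0L)
  comps <- lapply(keep, function(k) sort(which(labels == k)))
  comps[order(vapply(comps, `[`, 0L, 1))]
}

# Small all-ocean grid with one land row carved out near the coast.
toyGrid <- function(latRange = c(-78, -66), lonStep = 30, latStep = 2) {
  makeGrid(latRange, lonStep, latStep)
}

# A layer stack with prescribed values on a fully in-zone toy grid.
toyStack <- function(grid, values) {
  zone <- matrix(TRUE, length(latCenters(grid)), length(lonCenters(grid)))
  layerStack(values$NPP, values$KGP, values$DFP, values$EPP, values$APP,
             zone)
}
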