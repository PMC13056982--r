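# Accessor generics, methods and show() methods for the S4 containers.

#' @rdname Grid-class
#' @param object,x an object
#' @export
setGeneric("latCenters", function(x) standardGeneric("latCenters"))
#' @rdname Grid-class
#' @export
setGeneric("lonCenters", function(x) standardGeneric("lonCenters"))
#' @rdname Grid-class
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))
#' @rdname Grid-class
#' @export
setGeneric("landMask", function(x) standardGeneric("landMask"))
#' @rdname Grid-class
#' @param value replacement value
#' @export
setGeneric("landMask<-", function(x, value) standardGeneric("landMask<-"))

#' @rdname Grid-class
#' @export
setMethod("latCenters", "Grid", function(x) x@latCenters)
#' @rdname Grid-class
#' @export
setMethod("lonCenters", "Grid", function(x) x@lonCenters)
#' @rdname Grid-class
#' @export
setMethod("cellArea", "Grid", function(x) x@cellArea)
#' @rdname Grid-class
#' @export
setMethod("landMask", "Grid", function(x) x@landMask)
#' @rdname Grid-class
#' @export
setReplaceMethod("landMask", "Grid", function(x, value) {
  stopifnot(is.logical(value), all(dim(value) == dim(x@landMask)))
  x@landMask <- value
  validObject(x)
  x
})

setMethod("show", "Grid", function(object) {
  cat(sprintf("Grid: %d lat x %d lon cells (%g x %g deg), lat %g..%g\n",
              length(object@latCenters), length(object@lonCenters),
              object@latStep, object@lonStep,
              min(object@latCenters), max(object@latCenters)))
  cat(sprintf("  land cells: %d; total ocean area %.3g km^2\n",
              sum(object@landMask),
              sum(object@cellArea[!object@landMask])))
})

#' @rdname GriddedField-class
#' @param x,object an object
#' @export
setGeneric("fieldData", function(x) standardGeneric("fieldData"))
#' @rdname GriddedField-class
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))
#' @rdname GriddedField-class
#' @export
setGeneric("fieldYears", function(x) standardGeneric("fieldYears"))
#' @rdname GriddedField-class
#' @export
setGeneric("fieldMonths", function(x) standardGeneric("fieldMonths"))

#' @rdname GriddedField-class
#' @export
setMethod("fieldData", "GriddedField", function(x) x@data)
#' @rdname GriddedField-class
#' @export
setMethod("fieldUnits", "GriddedField", function(x) x@units)
#' @rdname GriddedField-class
#' @export
setMethod("fieldYears", "GriddedField", function(x) x@years)
#' @rdname GriddedField-class
#' @export
setMethod("fieldMonths", "GriddedField", function(x) x@months)

setMethod("show", "GriddedField", function(object) {
  d <- dim(object@data)
  cat(sprintf("GriddedField '%s' [%s]: %d member(s) x %d time x %d lat x %d lon\n",
              object@name, object@units, d[1], d[2], d[3], d[4]))
  if (d[2]) cat(sprintf("  time %d-%02d .. %d-%02d\n",
                        object@years[1], object@months[1],
                        object@years[d[2]], object@months[d[2]]))
})

#' @rdname RegionSet-class
#' @param x,object an object
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname RegionSet-class
#' @param name region name
#' @export
setGeneric("regionMask", function(x, name) standardGeneric("regionMask"))

#' @rdname RegionSet-class
#' @export
setMethod("regionNames", "RegionSet", function(x) names(x@masks))
#' @rdname RegionSet-class
#' @export
setMethod("regionMask", "RegionSet", function(x, name) {
  if (!name %in% names(x@masks)) stop("unknown region: ", name)
  x@masks[[name]]
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet:",
      paste(sprintf("%s (%d cells)", names(object@masks),
                    vapply(object@masks, sum, 0L)), collapse = ", "), "\n")
})

#' @rdname PolynyaMap-class
#' @param x,object an object
#' @export
setGeneric("typicalMask", function(x) standardGeneric("typicalMask"))
#' @rdname PolynyaMap-class
#' @export
setGeneric("frequencyField", function(x) standardGeneric("frequencyField"))
#' @rdname PolynyaMap-class
#' @export
setGeneric("labelField", function(x) standardGeneric("labelField"))

#' @rdname PolynyaMap-class
#' @export
setMethod("typicalMask", "PolynyaMap", function(x) x@typicalMask)
#' @rdname PolynyaMap-class
#' @export
setMethod("frequencyField", "PolynyaMap", function(x) x@frequency)
#' @rdname PolynyaMap-class
#' @export
setMethod("labelField", "PolynyaMap", function(x) x@labels)

setMethod("show", "PolynyaMap", function(object) {
  cat(sprintf(
    "PolynyaMap: %d step(s), %s < %g, %d-connectivity; %d typical cells (freq > %g)\n",
    dim(object@labels)[1], object@variable, object@threshold,
    object@connectivity, sum(object@typicalMask), object@cutoff))
})

#' @rdname LayerStack-class
#' @param x,object an object
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname LayerStack-class
#' @param name layer name (NPP, KGP, DFP, EPP or APP)
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname LayerStack-class
#' @export
setGeneric("zoneMask", function(x) standardGeneric("zoneMask"))

#' @rdname LayerStack-class
#' @export
setMethod("layerNames", "LayerStack", function(x) names(x@layers))
#' @rdname LayerStack-class
#' @export
setMethod("getLayer", "LayerStack", function(x, name) {
  if (!name %in% names(x@layers)) stop("unknown layer: ", name)
  x@layers[[name]]
})
#' @rdname LayerStack-class
#' @export
setMethod("zoneMask", "LayerStack", function(x) x@zoneMask)

setMethod("show", "LayerStack", function(object) {
  cat("LayerStack:", paste(names(object@layers), collapse = ", "),
      sprintf("on %d in-zone cells\n", sum(object@zoneMask)))
})

#' @rdname AevResult-class
#' @param x,object an object
#' @export
setGeneric("aevValues", function(x) standardGeneric("aevValues"))
#' @rdname AevResult-class
#' @export
setGeneric("aevBins", function(x) standardGeneric("aevBins"))
#' @rdname AevResult-class
#' @export
setGeneric("scaledLayers", function(x) standardGeneric("scaledLayers"))
#' @rdname AevResult-class
#' @export
setGeneric("aevRegions", function(x) standardGeneric("aevRegions"))

#' @rdname AevResult-class
#' @export
setMethod("aevValues", "AevResult", function(x) x@aev)
#' @rdname AevResult-class
#' @export
setMethod("aevBins", "AevResult", function(x) x@bins)
#' @rdname AevResult-class
#' @export
setMethod("scaledLayers", "AevResult", function(x) x@scaledLayers)
#' @rdname AevResult-class
#' @export
setMethod("aevRegions", "AevResult", function(x) x@regions)

setMethod("show", "AevResult", function(object) {
  cat(sprintf("AevResult (%s scaling): %d scored cells, bins: %s\n",
              object@mode, sum(!is.na(object@aev)),
              paste(names(table(object@bins)), table(object@bins),
                    sep = "=", collapse = ", ")))
})

#' @rdname NestCounts-class
#' @param x,object an object
#' @export
setGeneric("nestCounts", function(x) standardGeneric("nestCounts"))
#' @rdname NestCounts-class
#' @export
setGeneric("sicMeans", function(x) standardGeneric("sicMeans"))

#' @rdname NestCounts-class
#' @export
setMethod("nestCounts", "NestCounts", function(x) x@counts)
#' @rdname NestCounts-class
#' @export
setMethod("sicMeans", "NestCounts", function(x) x@sicMean)

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: years %d..%d, %d member(s), warming %g degC/decade,\n",
    min(object@years), max(object@years), object@nMembers,
    object@warmingRate))
  cat(sprintf("  ice decline %g/decade, %d polynya pocket(s), bloom x%g, seed %d\n",
              object@iceDeclineRate, nrow(object@polynyas),
              object@bloomAmplification, object@seed))
})
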