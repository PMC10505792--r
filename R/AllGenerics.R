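#' Accessors for micropattern classes
#'
#' Small accessor generics: `pixelSize` (micrometers per pixel),
#' `channelNames`, `getChannel` (one channel as a matrix), `nucleusCount`,
#' `trueFractions` (analytic marker fractions of a
#' [NeuruloidGeometry-class]), `regionCenter` / `regionArea` (colony center
#' in micrometers / area in square micrometers), and `isNormalized`.
#'
#' @param x an object.
#' @param name channel name.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("nucleusCount", function(x) standardGeneric("nucleusCount"))

#' @rdname accessors
#' @export
setGeneric("trueFractions", function(x) standardGeneric("trueFractions"))

#' @rdname accessors
#' @export
setGeneric("regionCenter", function(x) standardGeneric("regionCenter"))

#' @rdname accessors
#' @export
setGeneric("regionArea", function(x) standardGeneric("regionArea"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) names(x@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel '", name, "' (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

#' @rdname accessors
#' @export
setMethod("nucleusCount", "ColonyLayout", function(x) nrow(x@nucleusCenters))

#' @rdname accessors
#' @export
setMethod("trueFractions", "NeuruloidGeometry", function(x) {
  R2 <- x@dapiRadius^2
  c(PAX6 = x@pax6Radius^2 / R2,
    NCAD = x@ncadRadius^2 / R2,
    SOX10 = (x@sox10Outer^2 - x@sox10Inner^2) / R2)
})

#' @rdname accessors
#' @export
setMethod("regionCenter", "ColonyRegion", function(x) x@centerUm)

#' @rdname accessors
#' @export
setMethod("regionArea", "ColonyRegion", function(x) x@areaUm2)

#' @rdname accessors
#' @export
setMethod("isNormalized", "RadialProfile", function(x) x@normalized)

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("MultiChannelImage:", d[1], "x", d[2], "px at",
      object@pixelSize, "um/px\n  channels:",
      paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "ColonyLayout", function(object) {
  cat("ColonyLayout:", nrow(object@nucleusCenters), "nuclei in a",
      object@colonyRadius, "um disc (min separation",
      object@minSeparation, "um)",
      if (object@shortfall) "[shortfall]" else "", "\n")
})

setMethod("show", "PhenotypeParams", function(object) {
  cat(sprintf(
    "PhenotypeParams '%s': pEdge=%.2f pCenter=%.2f band=%g um patchiness=%g um\n",
    object@name, object@pEdge, object@pCenter, object@edgeBandWidth,
    object@patchiness))
})

setMethod("show", "NeuruloidGeometry", function(object) {
  f <- trueFractions(object)
  cat(sprintf(
    "NeuruloidGeometry: DAPI %g um | PAX6 %.3f  NCAD %.3f  SOX10 %.3f (true fractions)\n",
    object@dapiRadius, f["PAX6"], f["NCAD"], f["SOX10"]))
})

setMethod("show", "ColonyRegion", function(object) {
  cat(sprintf(
    "ColonyRegion [%s]: center (%.1f, %.1f) um, area %.0f um^2, %s%s\n",
    object@sourceId, object@centerUm[1], object@centerUm[2], object@areaUm2,
    if (object@accepted) "accepted" else "rejected",
    if (nzchar(object@rejectReason)) paste0(" (", object@rejectReason, ")") else ""))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf(
    "RadialProfile [%s]: %d bins of %g um, %d nuclei%s%s\n",
    object@colonyId, length(object@binMeans),
    diff(object@binEdges[1:2]), sum(object@binCounts),
    if (object@overflow > 0L) sprintf(" (+%d beyond max radius)", object@overflow) else "",
    if (object@normalized) ", normalized" else ""))
})

setMethod("show", "GroupComparison", function(object) {
  a <- object@anova
  cat(sprintf("GroupComparison (%s): F(%d, %d) = %.4g, p = %.4g\n",
              object@method, a$dfBetween, a$dfWithin, a$F, a$p))
  if (nzchar(object@control)) cat("  control:", object@control, "\n")
  print(object@comparisons, row.names = FALSE, digits = 4)
})
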