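#' @import methods
#' @importFrom stats rnorm runif rpois median sd pnorm pt qchisq dchisq aov
#'   ptukey quantile uniroot kmeans setNames complete.cases
#' @importFrom utils write.csv read.csv head
#' @useDynLib micropattern, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Multi-channel fluorescence image
#'
#' A named set of single-channel 2-D pixel grids sharing one geometry, plus
#' the physical pixel size. Channels are plain numeric matrices indexed
#' `[row, column]`; the package-wide coordinate convention maps column `c`,
#' row `r` (1-based) to micrometer coordinates
#' `x = (c - 0.5) * pixelSize`, `y = (r - 0.5) * pixelSize`,
#' i.e. 0-based pixel indices with the origin at the top-left corner,
#' x along columns and y along rows.
#'
#' @slot channels named list of numeric matrices, all with identical
#'   dimensions. Intensities are in arbitrary units (a.u.).
#' @slot pixelSize numeric(1), micrometers per pixel.
#'
#' @seealso [MultiChannelImage()] for the constructor,
#'   [readMultiChannelTIFF()] / [writeMultiChannelTIFF()] for disk IO.
#' @export
setClass("MultiChannelImage",
  representation(channels = "list", pixelSize = "numeric"),
  validity = function(object) {
    ch <- object@channels
    if (length(ch) == 0L) return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
      return("channels must have unique non-empty names")
    if (!all(vapply(ch, function(m) is.matrix(m) && is.numeric(m), logical(1))))
      return("every channel must be a numeric matrix")
    d <- dim(ch[[1]])
    if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1))))
      return("all channels must share the same dimensions")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  }
)

#' Geometry of one synthetic micropattern colony
#'
#' Nucleus center positions and radii (micrometers) inside a circular colony.
#' All centers lie within `colonyRadius` of `colonyCenter` and no two centers
#' are closer than `minSeparation` (a hard non-overlap guarantee used by
#' count-recovery tests).
#'
#' @slot nucleusCenters n x 2 matrix of (x, y) positions in micrometers.
#' @slot nucleusRadii numeric(n), nucleus radii in micrometers.
#' @slot colonyCenter numeric(2), colony center (x, y) in micrometers.
#' @slot colonyRadius numeric(1), colony radius in micrometers.
#' @slot minSeparation numeric(1), guaranteed minimum center-center distance.
#' @slot shortfall logical(1), TRUE when the sampler could not reach the
#'   requested nucleus count (the achieved count is `nrow(nucleusCenters)`).
#' @export
setClass("ColonyLayout",
  representation(nucleusCenters = "matrix", nucleusRadii = "numeric",
                 colonyCenter = "numeric", colonyRadius = "numeric",
                 minSeparation = "numeric", shortfall = "logical"),
  validity = function(object) {
    p <- object@nucleusCenters
    if (ncol(p) != 2L) return("nucleusCenters must be an n x 2 matrix")
    if (length(object@nucleusRadii) != nrow(p))
      return("one radius per nucleus required")
    d <- sqrt((p[, 1] - object@colonyCenter[1])^2 +
              (p[, 2] - object@colonyCenter[2])^2)
    if (any(d > object@colonyRadius + 1e-9))
      return("all nucleus centers must lie inside the colony disc")
    TRUE
  }
)

#' Phenotype preset for the synthetic activin A assay
#'
#' Parameters controlling where nuclei respond (SMAD2/3 nuclear
#' translocation) and how the response is rendered. The four named presets
#' mirror the assay phenotypes: `WT` responds only in an edge band, `HET`
#' adds patchy interior activation, `HD` and `KO` respond uniformly.
#'
#' @slot name phenotype label.
#' @slot pEdge probability that a nucleus in the edge band is activated.
#' @slot pCenter probability that an interior nucleus is activated.
#' @slot edgeBandWidth width of the responsive edge band, micrometers.
#' @slot patchiness correlation length (micrometers) of interior activation
#'   clusters; 0 means spatially independent labels.
#' @slot intensityOn,intensityOff mean nuclear marker intensity (a.u.) of
#'   activated / non-activated nuclei.
#' @slot dapiIntensity mean nuclear DAPI intensity (a.u.).
#' @slot background,backgroundSd additive Gaussian background (mean, sd) in
#'   a.u. applied to every channel.
#' @slot poissonNoise logical, add Poisson shot noise.
#' @slot blurSigma Gaussian blur sigma in micrometers applied to rendered
#'   channels (optical softening).
#' @export
setClass("PhenotypeParams",
  representation(name = "character", pEdge = "numeric", pCenter = "numeric",
                 edgeBandWidth = "numeric", patchiness = "numeric",
                 intensityOn = "numeric", intensityOff = "numeric",
                 dapiIntensity = "numeric", background = "numeric",
                 backgroundSd = "numeric", poissonNoise = "logical",
                 blurSigma = "numeric"),
  validity = function(object) {
    if (object@pEdge < 0 || object@pEdge > 1 ||
        object@pCenter < 0 || object@pCenter > 1)
      return("pEdge and pCenter must lie in [0, 1]")
    if (object@intensityOn <= object@intensityOff)
      return("intensityOn must exceed intensityOff")
    if (object@edgeBandWidth < 0) return("edgeBandWidth must be >= 0")
    TRUE
  }
)

#' Concentric ground-truth geometry of a synthetic neuruloid
#'
#' A neuruloid endpoint is modelled as nested concentric domains on a DAPI
#' disc: a central PAX6 neuroectoderm disc containing an N-CAD lumen disc,
#' and a peripheral SOX10 neural-crest annulus. True area fractions are
#' analytic: `(r/R)^2` for a disc marker and `(r2^2 - r1^2)/R^2` for the
#' annulus.
#'
#' @slot dapiRadius,pax6Radius,ncadRadius radii in micrometers.
#' @slot sox10Inner,sox10Outer annulus radii in micrometers.
#' @export
setClass("NeuruloidGeometry",
  representation(dapiRadius = "numeric", pax6Radius = "numeric",
                 ncadRadius = "numeric", sox10Inner = "numeric",
                 sox10Outer = "numeric"),
  validity = function(object) {
    if (!(object@ncadRadius <= object@pax6Radius &&
          object@pax6Radius <= object@dapiRadius &&
          object@sox10Inner <= object@sox10Outer &&
          object@sox10Outer <= object@dapiRadius))
      return("radii must nest: ncad <= pax6 <= dapi and sox10 in [0, dapi]")
    TRUE
  }
)

#' One synthetic sample: image plus ground truth
#'
#' @slot image a [MultiChannelImage-class].
#' @slot truth data.frame of per-nucleus ground truth (columns `label`,
#'   `x_um`, `y_um`, `radius_um`, `activated`) for colony samples, or the
#'   per-marker true fractions for neuruloid samples.
#' @slot layout the generating [ColonyLayout-class] or
#'   [NeuruloidGeometry-class].
#' @slot seed integer seed that reproduces the sample bit-exactly.
#' @slot params the generating parameter object.
#' @export
setClass("SyntheticSample",
  representation(image = "MultiChannelImage", truth = "data.frame",
                 layout = "ANY", seed = "integer", params = "ANY"))

#' A detected micropattern colony
#'
#' @slot mask logical matrix, colony foreground in source-image coordinates.
#' @slot boundary k x 2 matrix, boundary polygon vertices in pixel
#'   coordinates (x = column - 1, y = row - 1, 0-based).
#' @slot centerPx numeric(2), polygon-centroid colony center in pixel coords.
#' @slot centerUm numeric(2), the same center in micrometers.
#' @slot areaUm2 numeric(1), mask area in square micrometers.
#' @slot bbox integer(4): row min/max, col min/max (1-based, inclusive).
#' @slot pixelSize micrometers per pixel of the source image.
#' @slot sourceId identifier of the source image.
#' @slot accepted logical, passed the expected-size filter.
#' @slot rejectReason character, empty when accepted.
#' @export
setClass("ColonyRegion",
  representation(mask = "matrix", boundary = "matrix", centerPx = "numeric",
                 centerUm = "numeric", areaUm2 = "numeric", bbox = "integer",
                 pixelSize = "numeric", sourceId = "character",
                 accepted = "logical", rejectReason = "character"))

#' Binned radial profile of nuclear intensity
#'
#' Mean of per-nucleus intensities by half-open distance bin
#' `[lo, hi)` from the colony center. Empty bins are `NA`, never 0. When
#' `normalized` is TRUE the maximum over non-empty bins is exactly 1.
#'
#' @slot binEdges numeric(b + 1), bin edges in micrometers.
#' @slot binMeans numeric(b), mean intensity per bin (NA when empty).
#' @slot binCounts integer(b), nuclei per bin.
#' @slot overflow integer(1), nuclei beyond the last edge (excluded).
#' @slot normalized logical(1).
#' @slot colonyId character(1).
#' @export
setClass("RadialProfile",
  representation(binEdges = "numeric", binMeans = "numeric",
                 binCounts = "integer", overflow = "integer",
                 normalized = "logical", colonyId = "character"),
  validity = function(object) {
    b <- length(object@binEdges) - 1L
    if (length(object@binMeans) != b || length(object@binCounts) != b)
      return("binMeans/binCounts must have length(binEdges) - 1")
    if (is.unsorted(object@binEdges, strictly = TRUE))
      return("binEdges must be strictly increasing")
    if (any(object@binCounts == 0L & !is.na(object@binMeans)))
      return("empty bins must carry NA, not a value")
    TRUE
  }
)

#' Group comparison result (ANOVA with post-hoc adjustment)
#'
#' @slot method "dunnett" (many-to-one) or "tukey" (all pairs).
#' @slot groups named list of numeric sample vectors (one value per colony,
#'   the statistical unit).
#' @slot control control group label ("" for Tukey).
#' @slot anova list with `F`, `dfBetween`, `dfWithin`, `p`, `msWithin`.
#' @slot comparisons data.frame: comparison, estimate, se, t, p_adj, stars.
#' @export
setClass("GroupComparison",
  representation(method = "character", groups = "list", control = "character",
                 anova = "list", comparisons = "data.frame"))
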