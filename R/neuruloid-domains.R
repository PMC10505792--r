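#' Segment the area occupied by a marker
#'
#' Classical area segmentation of one fluorescence channel: Gaussian
#' smoothing (sigma 2 um), Otsu threshold on the smoothed intensity range,
#' morphological opening (3 um disc), and removal of connected components
#' smaller than `minComponent` square micrometers.
#'
#' @param channel numeric intensity matrix.
#' @param pixelSize micrometers per pixel.
#' @param smoothSigma Gaussian sigma, micrometers.
#' @param openRadius opening disc radius, micrometers.
#' @param minComponent minimum component area, square micrometers.
#' @return logical mask. A constant channel yields an empty mask with a
#'   warning.
#' @export
segmentMarkerArea <- function(channel, pixelSize = 1, smoothSigma = 2,
                              openRadius = 3, minComponent = 100) {
  stopifnot(is.matrix(channel), pixelSize > 0)
  rng <- range(channel)
  if (diff(rng) == 0) {
    warning("constant channel: returning empty mask")
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  sm <- EBImage::gblur(channel, sigma = smoothSigma / pixelSize)
  rngS <- range(sm)
  norm <- (sm - rngS[1]) / diff(rngS)
  mask <- norm > EBImage::otsu(EBImage::Image(norm))
  brushSize <- 2 * max(1L, round(openRadius / pixelSize)) + 1L
  mask <- EBImage::opening(mask, EBImage::makeBrush(brushSize, "disc")) > 0
  labels <- EBImage::bwlabel(mask)
  nlab <- max(labels)
  if (nlab > 0) {
    areas <- tabulate(labels[labels > 0L], nbins = nlab) * pixelSize^2
    small <- which(areas < minComponent)
    if (length(small)) mask[labels %in% small] <- FALSE
  }
  mask
}

#' Marker area fractions over the DAPI area
#'
#' For each marker mask, the fraction of the total DAPI area it occupies:
#' `|marker & dapi| / |dapi|` in the default clip mode (fractions bounded
#' in `[0, 1]`), or `|marker| / |dapi|` in raw mode.
#'
#' @param markerMasks named list of logical masks.
#' @param dapiMask logical mask of the total DAPI (neuruloid) area.
#' @param pixelSize micrometers per pixel.
#' @param mode `"clip"` (intersect markers with DAPI) or `"raw"`.
#' @param colonyId identifier for the output row.
#' @return one-row data.frame: `colony_id`, `<marker>_frac` per marker,
#'   `dapi_area_um2`, `mode`.
#' @examples
#' dapi <- matrix(TRUE, 10, 10)
#' m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
#' domainFractions(list(PAX6 = m), dapi, pixelSize = 1)
#' @export
domainFractions <- function(markerMasks, dapiMask, pixelSize = 1,
                            mode = c("clip", "raw"), colonyId = "colony") {
  mode <- match.arg(mode)
  stopifnot(is.list(markerMasks), length(markerMasks) >= 1)
  for (m in markerMasks)
    if (!identical(dim(m), dim(dapiMask)))
      stop("marker and DAPI masks must have identical shapes")
  nDapi <- sum(dapiMask)
  if (nDapi == 0) stop("empty DAPI mask: no reference area")
  out <- data.frame(colony_id = colonyId)
  for (nm in names(markerMasks)) {
    m <- markerMasks[[nm]]
    n <- if (mode == "clip") sum(m & dapiMask) else sum(m)
    out[[paste0(nm, "_frac")]] <- n / nDapi
  }
  out$dapi_area_um2 <- nDapi * pixelSize^2
  out$mode <- mode
  out
}
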