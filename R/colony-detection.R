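#' Detect micropattern colonies in the DAPI channel
#'
#' Foreground is found by Otsu thresholding of the DAPI channel (applied on
#' the intensity range, so detection is invariant to positive rescaling),
#' followed by morphological closing (5 um disc) and hole filling. Connected
#' components are filtered by an area window
#' `[1 - tau, 1 + tau] * pi * (expectedDiameter/2)^2` (the expected-size
#' filter), and components touching the image border are rejected with
#' reason `"border"`. The colony boundary polygon is the convex hull of the
#' component (micropattern colonies are convex discs; `alpha` is recorded
#' for provenance), and the colony center is the centroid of that polygon.
#'
#' @param dapi a numeric matrix (DAPI channel) or a
#'   [MultiChannelImage-class] containing a `DAPI` channel.
#' @param expectedDiameter expected colony diameter, micrometers.
#' @param pixelSize micrometers per pixel (ignored if `dapi` is a
#'   [MultiChannelImage-class]).
#' @param alpha boundary scale parameter, micrometers; default
#'   `expectedDiameter / 5`.
#' @param tau relative area tolerance of the expected-size window.
#' @param closingRadius radius (um) of the morphological closing disc.
#' @param sourceId identifier stored in each region.
#' @return list of [ColonyRegion-class]; accepted regions have
#'   `@accepted == TRUE`, rejects carry a `@rejectReason`. A blank image
#'   yields an empty list; a constant non-zero (saturated) image is an
#'   error.
#' @examples
#' lay <- generateColonyLayout(60, 40, minSeparation = 9, seed = 1)
#' s <- renderColonyImage(lay, rep(TRUE, 40), phenotypeParams("KO"), seed = 1)
#' regs <- detectColonies(s@image, expectedDiameter = 120)
#' acceptedRegions(regs)
#' @export
detectColonies <- function(dapi, expectedDiameter, pixelSize = 1,
                           alpha = expectedDiameter / 5, tau = 0.35,
                           closingRadius = 5, sourceId = "image") {
  if (is(dapi, "MultiChannelImage")) {
    pixelSize <- dapi@pixelSize
    dapi <- getChannel(dapi, "DAPI")
  }
  stopifnot(is.matrix(dapi), expectedDiameter > 0, pixelSize > 0)
  rng <- range(dapi)
  if (diff(rng) == 0) {
    if (rng[1] == 0) return(list())  # all-background image
    stop("threshold failure: constant (saturated) image")
  }
  norm <- (dapi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  brushSize <- 2 * max(1L, round(closingRadius / pixelSize)) + 1L
  mask <- EBImage::closing(mask, EBImage::makeBrush(brushSize, "disc"))
  mask <- EBImage::fillHull(mask) > 0
  labels <- EBImage::bwlabel(mask)
  nlab <- max(labels)
  if (nlab == 0) return(list())
  expArea <- pi * (expectedDiameter / 2)^2
  regions <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    compMask <- labels == l
    idx <- which(compMask, arr.ind = TRUE)
    areaUm2 <- nrow(idx) * pixelSize^2
    onBorder <- any(idx[, 1] == 1L | idx[, 1] == nrow(dapi) |
                    idx[, 2] == 1L | idx[, 2] == ncol(dapi))
    # convex-hull boundary in 0-based pixel coords (x = col - 1, y = row - 1)
    ptsPx <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    hull <- ptsPx[grDevices::chull(ptsPx), , drop = FALSE]
    ctrPx <- .polygonCentroid(hull)
    reason <- if (onBorder) "border"
      else if (areaUm2 < (1 - tau) * expArea) "too-small"
      else if (areaUm2 > (1 + tau) * expArea) "too-large"
      else ""
    regions[[l]] <- new("ColonyRegion", mask = compMask, boundary = hull,
      centerPx = ctrPx, centerUm = (ctrPx + 0.5) * pixelSize,
      areaUm2 = areaUm2,
      bbox = as.integer(c(min(idx[, 1]), max(idx[, 1]),
                          min(idx[, 2]), max(idx[, 2]))),
      pixelSize = pixelSize, sourceId = sourceId,
      accepted = !nzchar(reason), rejectReason = reason)
  }
  regions
}

#' @rdname detectColonies
#' @param regions list of [ColonyRegion-class] from `detectColonies`.
#' @export
acceptedRegions <- function(regions)
  Filter(function(r) r@accepted, regions)

# centroid of a closed polygon (shoelace); falls back to vertex mean for
# degenerate (zero-area) polygons such as single-pixel components
.polygonCentroid <- function(v) {
  n <- nrow(v)
  if (n < 3) return(colMeans(v))
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Crop one colony out of a multi-channel image
#'
#' Crops all channels to the region's bounding box expanded by `margin`
#' micrometers, clipping at the image border (with a flag when clipped),
#' and re-expresses the region in crop coordinates.
#'
#' @param image a [MultiChannelImage-class] (same geometry the region was
#'   detected in).
#' @param region a [ColonyRegion-class].
#' @param margin extra margin around the bounding box, micrometers.
#' @return list with `image` (the cropped [MultiChannelImage-class]),
#'   `region` (the [ColonyRegion-class] in crop coordinates) and `clipped`
#'   (TRUE when the requested margin ran past the image border).
#' @export
extractColony <- function(image, region, margin = 0) {
  stopifnot(is(image, "MultiChannelImage"), is(region, "ColonyRegion"))
  d <- dim(image@channels[[1]])
  if (!identical(dim(region@mask), d))
    stop("region does not match image dimensions")
  mpx <- round(margin / image@pixelSize)
  want <- c(region@bbox[1] - mpx, region@bbox[2] + mpx,
            region@bbox[3] - mpx, region@bbox[4] + mpx)
  got <- c(max(1, want[1]), min(d[1], want[2]),
           max(1, want[3]), min(d[2], want[4]))
  clipped <- !identical(as.integer(want), as.integer(got))
  rows <- got[1]:got[2]; cols <- got[3]:got[4]
  crop <- cropImage(image, rows, cols)
  shift <- c(got[3] - 1L, got[1] - 1L)  # (x, y) pixel shift
  out <- region
  out@mask <- region@mask[rows, cols, drop = FALSE]
  out@boundary <- sweep(region@boundary, 2, shift)
  out@centerPx <- region@centerPx - shift
  out@centerUm <- (out@centerPx + 0.5) * region@pixelSize
  out@bbox <- as.integer(c(region@bbox[1] - got[1] + 1L,
                           region@bbox[2] - got[1] + 1L,
                           region@bbox[3] - got[3] + 1L,
                           region@bbox[4] - got[3] + 1L))
  list(image = crop, region = out, clipped = clipped)
}
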