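#' Segment nuclei in a DAPI image by distance-transform watershed
#'
#' Otsu threshold on the DAPI channel (relative, so invariant to positive
#' rescaling), hole filling, then marker-controlled splitting of touching
#' nuclei by watershed on the Euclidean distance transform of the
#' foreground mask. Background pixels are labelled 0.
#'
#' @param dapi numeric matrix or [MultiChannelImage-class] with a `DAPI`
#'   channel.
#' @param pixelSize micrometers per pixel (taken from the image object when
#'   one is supplied).
#' @param tolerance watershed merge tolerance in distance units (pixels of
#'   the distance map); minima shallower than this are merged, which sets
#'   the effective minimum peak separation.
#' @param ext neighbourhood radius (px) used by the watershed peak search.
#' @return integer label matrix (0 = background). A blank image yields an
#'   all-zero labelling with a warning.
#' @examples
#' lay <- generateColonyLayout(40, 15, minSeparation = 10, seed = 2)
#' s <- renderColonyImage(lay, rep(FALSE, 15), phenotypeParams("WT"), seed = 1)
#' labels <- segmentNuclei(getChannel(s@image, "DAPI"), pixelSize = 1)
#' max(labels)
#' @export
segmentNuclei <- function(dapi, pixelSize = 1, tolerance = 0.3, ext = 1) {
  if (is(dapi, "MultiChannelImage")) {
    pixelSize <- dapi@pixelSize
    dapi <- getChannel(dapi, "DAPI")
  }
  stopifnot(is.matrix(dapi), pixelSize > 0)
  rng <- range(dapi)
  if (diff(rng) == 0) {
    warning("zero foreground: constant DAPI image")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  norm <- (dapi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- EBImage::fillHull(norm > thr) > 0
  if (!any(mask)) {
    warning("zero foreground after thresholding")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  storage.mode(labels) <- "integer"
  matrix(labels, nrow(dapi), ncol(dapi))
}

#' Filter segmented nuclei by area
#'
#' Drops labels whose area falls outside `[minArea, maxArea]` (square
#' micrometers) — debris below, mitotic figures and merged objects above.
#' Remaining labels are renumbered consecutively.
#'
#' @param labels integer label matrix from [segmentNuclei()].
#' @param minArea,maxArea area window in square micrometers.
#' @param pixelSize micrometers per pixel.
#' @return list with `labels` (filtered, renumbered label matrix) and
#'   `removed` (data.frame: label, area_um2, reason `"too-small"` /
#'   `"too-large"`).
#' @export
filterNuclei <- function(labels, minArea = 30, maxArea = 300, pixelSize = 1) {
  stopifnot(minArea < maxArea)
  nlab <- max(labels)
  if (nlab == 0)
    return(list(labels = labels,
                removed = data.frame(label = integer(), area_um2 = numeric(),
                                     reason = character())))
  areas <- tabulate(labels[labels > 0L], nbins = nlab) * pixelSize^2
  bad <- which(areas < minArea | areas > maxArea)
  removed <- data.frame(
    label = bad, area_um2 = areas[bad],
    reason = ifelse(areas[bad] < minArea, "too-small", "too-large"))
  keep <- setdiff(seq_len(nlab), bad)
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  list(labels = out, removed = removed)
}

#' Measure per-nucleus properties
#'
#' For every label: centroid (micrometers, in the image's coordinate
#' convention), area, distance from centroid to the colony center, and the
#' median and mean intensity over the nucleus mask in each measurement
#' channel. The median uses the lower-median convention for even pixel
#' counts so reported values are always attained in the image.
#'
#' @param labels integer label matrix.
#' @param channels named list of intensity matrices (same shape as
#'   `labels`), or a [MultiChannelImage-class] whose non-DAPI channels are
#'   measured.
#' @param colonyCenter colony center (x, y) in micrometers.
#' @param pixelSize micrometers per pixel.
#' @param colonyId identifier stored in the records.
#' @return data.frame with columns `colony_id`, `label`, `x_um`, `y_um`,
#'   `area_um2`, `distance_um`, and `median_<channel>` / `mean_<channel>`
#'   per measurement channel.
#' @export
measureNuclei <- function(labels, channels, colonyCenter, pixelSize = 1,
                          colonyId = "colony") {
  if (is(channels, "MultiChannelImage")) {
    pixelSize <- channels@pixelSize
    channels <- channels@channels[setdiff(names(channels@channels), "DAPI")]
  }
  if (is.matrix(channels)) channels <- list(intensity = channels)
  nlab <- max(labels)
  for (ch in channels)
    if (!identical(dim(ch), dim(labels)))
      stop("channel and label matrices must have identical shapes")
  if (nlab == 0)
    return(data.frame(colony_id = character(), label = integer(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), distance_um = numeric()))
  pos <- which(labels > 0L)
  lab <- labels[pos]
  npixAll <- tabulate(lab, nbins = nlab)
  present <- which(npixAll > 0L)  # watershed/filter labels are consecutive,
  npix <- npixAll[present]        # but do not rely on it
  rowIdx <- (pos - 1L) %% nrow(labels) + 1L
  colIdx <- (pos - 1L) %/% nrow(labels) + 1L
  xUm <- (rowsum(colIdx - 0.5, lab)[, 1] / npix) * pixelSize
  yUm <- (rowsum(rowIdx - 0.5, lab)[, 1] / npix) * pixelSize
  out <- data.frame(colony_id = colonyId, label = present,
                    x_um = xUm, y_um = yUm,
                    area_um2 = npix * pixelSize^2,
                    distance_um = sqrt((xUm - colonyCenter[1])^2 +
                                       (yUm - colonyCenter[2])^2))
  ord <- order(lab)
  labSorted <- lab[ord]
  for (nm in names(channels)) {
    vals <- channels[[nm]][pos][ord]
    byLab <- split(vals, labSorted)
    out[[paste0("median_", nm)]] <-
      vapply(byLab, .lowerMedian, numeric(1), USE.NAMES = FALSE)
    out[[paste0("mean_", nm)]] <- rowsum(vals, labSorted)[, 1] / npix
  }
  out
}

# lower median: for even n, the smaller of the two middle order statistics
.lowerMedian <- function(x) sort(x)[floor((length(x) + 1) / 2)]
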