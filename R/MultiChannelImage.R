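#' Construct a MultiChannelImage
#'
#' @param channels named list of numeric matrices with identical dimensions.
#' @param pixelSize micrometers per pixel.
#' @return a [MultiChannelImage-class].
#' @examples
#' img <- MultiChannelImage(list(DAPI = matrix(0, 8, 8)), pixelSize = 1)
#' channelNames(img)
#' @export
MultiChannelImage <- function(channels, pixelSize) {
  new("MultiChannelImage", channels = channels, pixelSize = as.numeric(pixelSize))
}

#' Crop every channel of an image
#'
#' @param x a [MultiChannelImage-class].
#' @param rows,cols integer index vectors (1-based, contiguous).
#' @return the cropped [MultiChannelImage-class].
#' @keywords internal
cropImage <- function(x, rows, cols) {
  MultiChannelImage(lapply(x@channels, function(m) m[rows, cols, drop = FALSE]),
                    pixelSize = x@pixelSize)
}

# pixel-center coordinate vectors (um) for a channel matrix
.pixelCoords <- function(dim2, pixelSize) {
  list(y = (seq_len(dim2[1]) - 0.5) * pixelSize,
       x = (seq_len(dim2[2]) - 0.5) * pixelSize)
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' One 32-bit float page per channel. `tiff::writeTIFF` stores samples in
#' `[0, 1]`, so intensities are divided by an `intensityScale` recorded in a
#' JSON sidecar (`<file>.json`) together with channel names and pixel size;
#' `readMultiChannelTIFF` undoes the scaling. The sidecar is authoritative
#' for channel identity.
#'
#' @param x a [MultiChannelImage-class].
#' @param path TIFF file path.
#' @param intensityScale divisor applied before writing; chosen automatically
#'   (next power of two above the max intensity) when `NULL`.
#' @return `writeMultiChannelTIFF` returns `path` invisibly;
#'   `readMultiChannelTIFF` returns a [MultiChannelImage-class].
#' @export
writeMultiChannelTIFF <- function(x, path, intensityScale = NULL) {
  stopifnot(is(x, "MultiChannelImage"))
  mx <- max(vapply(x@channels, max, numeric(1)), 0)
  offset <- min(vapply(x@channels, min, numeric(1)), 0)  # noise can dip below 0
  if (is.null(intensityScale))
    intensityScale <- 2^ceiling(log2(max(mx - offset, 1) + 1))
  pages <- lapply(x@channels,
                  function(m) pmin(pmax((m - offset) / intensityScale, 0), 1))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L)
  meta <- list(channels = names(x@channels), pixel_size_um = x@pixelSize,
               intensity_scale = intensityScale, intensity_offset = offset)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMultiChannelTIFF
#' @param channelNames channel names for the pages; defaults to the sidecar's.
#' @param pixelSize micrometers per pixel; defaults to the sidecar's.
#' @export
readMultiChannelTIFF <- function(path, channelNames = NULL, pixelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  offset <- if (!is.null(meta$intensity_offset)) meta$intensity_offset else 0
  if (is.null(channelNames))
    channelNames <- if (!is.null(meta$channels))
      unlist(meta$channels) else paste0("ch", seq_along(pages))
  if (is.null(pixelSize))
    pixelSize <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else 1
  if (length(channelNames) != length(pages))
    stop("channel map names ", length(channelNames), " channels but TIFF has ",
         length(pages), " pages")
  ch <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale + offset
  })
  names(ch) <- channelNames
  MultiChannelImage(ch, pixelSize = pixelSize)
}

#' Write a synthetic sample to disk
#'
#' Writes the multi-page TIFF (+ JSON sidecar), a per-nucleus ground-truth
#' CSV (`<stem>_truth.csv`) and a JSON parameter record including the seed
#' (`<stem>_params.json`).
#'
#' @param sample a [SyntheticSample-class].
#' @param dir output directory (created if missing).
#' @param stem file stem, e.g. `"colony_WT_001"`.
#' @return named character vector of the written paths, invisibly.
#' @export
writeSyntheticSample <- function(sample, dir, stem) {
  stopifnot(is(sample, "SyntheticSample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tif"))
  writeMultiChannelTIFF(sample@image, tif)
  truthCsv <- file.path(dir, paste0(stem, "_truth.csv"))
  write.csv(sample@truth, truthCsv, row.names = FALSE)
  paramsJson <- file.path(dir, paste0(stem, "_params.json"))
  jsonlite::write_json(
    list(seed = sample@seed, params = .describeParams(sample@params)),
    paramsJson, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tif, truth = truthCsv, params = paramsJson))
}

.describeParams <- function(p) {
  if (is(p, "PhenotypeParams"))
    list(type = "phenotype", name = p@name, p_edge = p@pEdge,
         p_center = p@pCenter, edge_band_width_um = p@edgeBandWidth,
         patchiness_um = p@patchiness, intensity_on = p@intensityOn,
         intensity_off = p@intensityOff, background = p@background,
         background_sd = p@backgroundSd, poisson = p@poissonNoise,
         blur_sigma_um = p@blurSigma)
  else if (is(p, "NeuruloidGeometry"))
    list(type = "neuruloid", dapi_radius_um = p@dapiRadius,
         pax6_radius_um = p@pax6Radius, ncad_radius_um = p@ncadRadius,
         sox10_inner_um = p@sox10Inner, sox10_outer_um = p@sox10Outer)
  else as.list(p)
}
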