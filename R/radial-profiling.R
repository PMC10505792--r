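#' Radial profile of nuclear intensity
#'
#' Bins nuclei by distance to the colony center into half-open intervals
#' `[lo, hi)` of width `binWidth` up to `maxRadius`, and averages the
#' per-nucleus intensities (median nuclear intensity by default) within
#' each bin. Nuclei at or beyond `maxRadius` are counted in an overflow
#' tally and excluded from all bin means. Empty bins are `NA`.
#'
#' @param records nucleus table from [measureNuclei()] (or
#'   [simulateNucleusRecords()]).
#' @param binWidth bin width, micrometers.
#' @param maxRadius profile extent, micrometers.
#' @param intensity name of the intensity column to profile.
#' @param colonyId profile identifier; defaults to the records' colony id.
#' @return a [RadialProfile-class].
#' @examples
#' rec <- data.frame(colony_id = "c", distance_um = c(5, 12, 18),
#'                   median_SMAD23 = c(2, 4, 8))
#' radialProfile(rec, binWidth = 10, maxRadius = 30)
#' @export
radialProfile <- function(records, binWidth = 10, maxRadius = 250,
                          intensity = "median_SMAD23", colonyId = NULL) {
  stopifnot(binWidth > 0, maxRadius > 0)
  if (nrow(records) == 0) stop("no nucleus records to profile")
  if (!intensity %in% names(records))
    stop("no intensity column '", intensity, "' in records")
  if (is.null(colonyId))
    colonyId <- as.character(records$colony_id[1])
  edges <- seq(0, maxRadius, by = binWidth)
  if (edges[length(edges)] < maxRadius) edges <- c(edges, maxRadius)
  nb <- length(edges) - 1L
  d <- records$distance_um
  v <- records[[intensity]]
  over <- sum(d >= edges[nb + 1L])
  inb <- d < edges[nb + 1L]
  bin <- findInterval(d[inb], edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = nb)
  means <- rep(NA_real_, nb)
  if (any(inb)) {
    s <- rowsum(v[inb], bin)
    means[as.integer(rownames(s))] <- s[, 1] / counts[counts > 0]
  }
  new("RadialProfile", binEdges = edges, binMeans = means,
      binCounts = as.integer(counts), overflow = as.integer(over),
      normalized = FALSE, colonyId = colonyId)
}

#' Normalize a radial profile to its maximum
#'
#' Divides every bin mean by the maximum over non-empty bins, so the
#' maximum of the normalized profile is exactly 1. Idempotent.
#'
#' @param profile a [RadialProfile-class].
#' @return the normalized [RadialProfile-class].
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "RadialProfile"))
  m <- profile@binMeans
  if (all(is.na(m))) stop("cannot normalize a profile with no non-empty bins")
  mx <- max(m, na.rm = TRUE)
  if (mx <= 0) stop("cannot normalize: maximum bin mean is not positive")
  profile@binMeans <- m / mx
  profile@normalized <- TRUE
  profile
}

#' Center/edge band summary of nuclear intensity
#'
#' Mean of the per-nucleus intensities whose distance falls inside the
#' half-open center and edge bands (defaults 10-25 um and 175-225 um).
#' These are the per-colony scatter values used for group statistics.
#' Bands with no nuclei yield `NA`.
#'
#' @inheritParams radialProfile
#' @param centerBand,edgeBand `(lo, hi)` in micrometers; must not overlap.
#' @return one-row data.frame: `colony_id`, `center_mean`, `edge_mean`,
#'   `n_center`, `n_edge`.
#' @export
bandSummary <- function(records, centerBand = c(10, 25),
                        edgeBand = c(175, 225), intensity = "median_SMAD23") {
  stopifnot(length(centerBand) == 2, length(edgeBand) == 2,
            centerBand[1] < centerBand[2], edgeBand[1] < edgeBand[2])
  if (max(centerBand[1], edgeBand[1]) < min(centerBand[2], edgeBand[2]))
    stop("center and edge bands must not overlap")
  d <- records$distance_um
  v <- records[[intensity]]
  inC <- d >= centerBand[1] & d < centerBand[2]
  inE <- d >= edgeBand[1] & d < edgeBand[2]
  data.frame(colony_id = as.character(records$colony_id[1]),
             center_mean = if (any(inC)) mean(v[inC]) else NA_real_,
             edge_mean = if (any(inE)) mean(v[inE]) else NA_real_,
             n_center = sum(inC), n_edge = sum(inE))
}

#' Aggregate radial profiles across colonies
#'
#' Per-bin mean and sample standard deviation across colonies, ignoring
#' missing (empty) bins, plus the number of contributing colonies per bin.
#' All profiles must share one bin grid.
#'
#' @param profiles list of [RadialProfile-class] with identical `binEdges`.
#' @return data.frame: `bin_lo`, `bin_hi`, `mean`, `sd`, `n`.
#' @export
aggregateProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  edges <- profiles[[1]]@binEdges
  for (p in profiles)
    if (!isTRUE(all.equal(p@binEdges, edges)))
      stop("profiles must share the same bin grid")
  m <- do.call(rbind, lapply(profiles, function(p) p@binMeans))
  n <- colSums(!is.na(m))
  mu <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sdv <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2) sd(col) else if (length(col) == 1) 0 else NA_real_
  })
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             mean = mu, sd = sdv, n = n)
}
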