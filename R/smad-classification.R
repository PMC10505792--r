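#' Classify nuclei as SMAD2/3-positive
#'
#' A nucleus is positive when its intensity is strictly above the threshold
#' (ties are negative). The per-colony positive fraction is
#' `100 * positives / total` over the retained (size-filtered) nuclei.
#' Classification uses the mean nuclear intensity by default; set
#' `intensity` to a `median_` column to classify on medians.
#'
#' @param records nucleus table from [measureNuclei()].
#' @param threshold intensity threshold, a.u.
#' @param intensity intensity column used for the calls.
#' @return list with `calls` (data.frame: label, intensity, threshold,
#'   positive) and `fraction` (percent positive).
#' @examples
#' rec <- data.frame(colony_id = "c", label = 1:4,
#'                   mean_SMAD23 = c(1, 2, 8, 9))
#' classifyPositive(rec, threshold = 5)$fraction
#' @export
classifyPositive <- function(records, threshold, intensity = "mean_SMAD23") {
  if (nrow(records) == 0) stop("no nucleus records to classify")
  stopifnot(is.finite(threshold))
  v <- records[[intensity]]
  if (is.null(v)) stop("no intensity column '", intensity, "' in records")
  pos <- v > threshold
  list(calls = data.frame(label = records$label, intensity = v,
                          threshold = threshold, positive = pos),
       fraction = 100 * sum(pos) / length(pos))
}

#' Suggest a reproducible SMAD2/3 positivity threshold
#'
#' Replaces manual thresholding with two auditable estimators on the pooled
#' nucleus intensities of control colonies: `"otsu"` (Otsu's criterion on a
#' 256-bin histogram of the pooled intensities) or `"bimodal-midpoint"`
#' (midpoint of the two k-means cluster centers, deterministically
#' initialized at the pooled min and max). When the two cluster centers are
#' closer than 5\% of the intensity range the distribution is effectively
#' unimodal and the result carries `degenerate = TRUE`.
#'
#' @param records nucleus table (pooled over one or more colonies).
#' @param mode `"otsu"` or `"bimodal-midpoint"`.
#' @param intensity intensity column.
#' @return list with `threshold`, `mode`, `degenerate`.
#' @export
suggestThreshold <- function(records, mode = c("otsu", "bimodal-midpoint"),
                             intensity = "mean_SMAD23") {
  mode <- match.arg(mode)
  v <- records[[intensity]]
  if (is.null(v) || length(v) == 0) stop("no intensities to threshold")
  rng <- range(v)
  if (diff(rng) == 0)
    return(list(threshold = rng[1], mode = mode, degenerate = TRUE))
  if (mode == "otsu") {
    thr <- .otsu1d(v)
    centers <- c(mean(v[v <= thr]), mean(v[v > thr]))
  } else {
    km <- kmeans(v, centers = matrix(rng, ncol = 1))
    centers <- sort(km$centers[, 1])
    thr <- mean(centers)
  }
  degenerate <- diff(sort(centers)) < 0.05 * diff(rng)
  if (degenerate)
    warning("intensity distribution looks unimodal; threshold is unreliable")
  list(threshold = unname(thr), mode = mode, degenerate = degenerate)
}

# Otsu's between-class variance maximizer on a 256-bin histogram
.otsu1d <- function(v, nbins = 256L) {
  rng <- range(v)
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * nbins) + 1L, nbins),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nbins]
  between <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
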