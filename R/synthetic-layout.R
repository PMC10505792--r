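#' Generate nucleus positions for one micropattern colony
#'
#' Places `targetCount` nucleus centers inside a circular colony with a hard
#' minimum pairwise separation, by Poisson-disc sampling (Bridson's
#' annulus dart-throwing plus a random-sequential densification pass) and
#' random subsampling down to the target. Nucleus radii are drawn uniformly
#' from `radiusRange`. The separation guarantee is what makes nucleus-count
#' recovery assertable downstream.
#'
#' If the target is geometrically infeasible (hexagonal-packing bound) the
#' function stops with an error naming the maximum feasible count. If the
#' sampler falls short of a feasible target, the achieved layout is returned
#' with `shortfall = TRUE`.
#'
#' @param colonyRadius colony radius in micrometers (default 250, the 500 um
#'   circular micropattern).
#' @param targetCount requested number of nuclei.
#' @param minSeparation minimum center-center distance in micrometers.
#' @param seed integer seed; identical inputs reproduce the layout exactly.
#' @param radiusRange nucleus radius range in micrometers.
#' @param colonyCenter colony center (x, y) in micrometers.
#' @return a [ColonyLayout-class].
#' @examples
#' lay <- generateColonyLayout(250, 400, minSeparation = 10, seed = 1)
#' nucleusCount(lay)
#' @export
generateColonyLayout <- function(colonyRadius, targetCount, minSeparation,
                                 seed, radiusRange = c(3.5, 4.5),
                                 colonyCenter = c(0, 0)) {
  stopifnot(colonyRadius > 0, targetCount >= 1, minSeparation > 0)
  # hexagonal packing bound on centers inside the disc (generous upper bound)
  hexMax <- floor(pi * (colonyRadius + minSeparation / 2)^2 /
                  (sqrt(3) / 2 * minSeparation^2))
  if (targetCount > hexMax)
    stop("infeasible packing: at most ~", hexMax, " nuclei fit in a ",
         colonyRadius, " um disc at ", minSeparation, " um separation")
  set.seed(seed)
  pts <- .poissonDiscDisc(colonyRadius, minSeparation)
  shortfall <- nrow(pts) < targetCount
  if (!shortfall) {
    keep <- sample.int(nrow(pts), targetCount)
    pts <- pts[keep, , drop = FALSE]
  } else if (nrow(pts) < 0.5 * targetCount) {
    stop("infeasible packing: sampler placed ", nrow(pts),
         " nuclei; maximum feasible at this separation is about ", nrow(pts))
  }
  radii <- runif(nrow(pts), radiusRange[1], radiusRange[2])
  # keep whole nuclei inside the disc margin used for rendering
  pts <- sweep(pts, 2, colonyCenter, "+")
  new("ColonyLayout", nucleusCenters = pts, nucleusRadii = radii,
      colonyCenter = as.numeric(colonyCenter),
      colonyRadius = as.numeric(colonyRadius),
      minSeparation = as.numeric(minSeparation), shortfall = shortfall)
}

#' Phenotype presets for the synthetic activin A assay
#'
#' Returns the [PhenotypeParams-class] preset for a phenotype. `WT` responds
#' to apical activin A only in a 50 um edge band (edge restriction); `HET`
#' keeps the responsive edge but adds patchy interior activation
#' (`pCenter = 0.4`, 40 um patches); `HD` and `KO` have lost edge
#' restriction and respond everywhere. Intensities are arbitrary units.
#'
#' @param phenotype one of `"WT"`, `"HET"`, `"HD"`, `"KO"`.
#' @param ... named overrides of any [PhenotypeParams-class] slot.
#' @return a [PhenotypeParams-class].
#' @examples
#' phenotypeParams("WT")
#' phenotypeParams("HET", pCenter = 0.5)
#' @export
phenotypeParams <- function(phenotype = c("WT", "HET", "HD", "KO"), ...) {
  phenotype <- match.arg(phenotype)
  base <- list(name = phenotype, pEdge = 1, pCenter = 0, edgeBandWidth = 50,
               patchiness = 0, intensityOn = 200, intensityOff = 20,
               dapiIntensity = 150, background = 10, backgroundSd = 4,
               poissonNoise = FALSE, blurSigma = 0.8)
  base <- switch(phenotype,
    WT  = base,
    HET = modifyList(base, list(pCenter = 0.4, patchiness = 40)),
    HD  = modifyList(base, list(pCenter = 1)),
    KO  = modifyList(base, list(pCenter = 1)))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown PhenotypeParams field(s): ",
                        paste(bad, collapse = ", "))
  base <- modifyList(base, over)
  do.call(new, c(list("PhenotypeParams"), base))
}

#' Assign SMAD2/3 activation labels to a colony layout
#'
#' Nuclei whose distance to the colony center is at least
#' `colonyRadius - edgeBandWidth` belong to the edge band and are activated
#' independently with probability `pEdge`. Interior nuclei are activated
#' with probability `pCenter`; when `patchiness > 0` interior labels are
#' spatially clustered: a white-noise field on a grid over the colony is
#' Gaussian-smoothed with sigma `patchiness` micrometers, evaluated at the
#' nucleus positions, and thresholded at the empirical `pCenter` quantile of
#' the interior values, so the realized interior fraction equals `pCenter`
#' (up to rounding) while labels form patches of the requested scale.
#'
#' @param layout a [ColonyLayout-class].
#' @param pheno a [PhenotypeParams-class].
#' @param seed integer seed.
#' @return logical vector, one activation flag per nucleus.
#' @export
assignActivation <- function(layout, pheno, seed) {
  stopifnot(is(layout, "ColonyLayout"), is(pheno, "PhenotypeParams"))
  set.seed(seed)
  p <- layout@nucleusCenters
  d <- sqrt((p[, 1] - layout@colonyCenter[1])^2 +
            (p[, 2] - layout@colonyCenter[2])^2)
  edge <- d >= layout@colonyRadius - pheno@edgeBandWidth
  act <- logical(nrow(p))
  act[edge] <- runif(sum(edge)) < pheno@pEdge
  nInt <- sum(!edge)
  if (nInt > 0) {
    if (pheno@pCenter <= 0) {
      act[!edge] <- FALSE
    } else if (pheno@pCenter >= 1) {
      act[!edge] <- TRUE
    } else if (pheno@patchiness <= 0) {
      act[!edge] <- runif(nInt) < pheno@pCenter
    } else {
      f <- .smoothFieldAt(p[!edge, , drop = FALSE], layout@colonyCenter,
                          layout@colonyRadius, pheno@patchiness)
      thr <- quantile(f, pheno@pCenter, type = 1)
      act[!edge] <- f <= thr
    }
  }
  act
}

# Gaussian-smoothed white-noise field sampled at points (n x 2, um).
# Grid step is patchiness/4; smoothing via EBImage::gblur on the grid.
.smoothFieldAt <- function(pts, center, radius, patchiness) {
  step <- max(patchiness / 4, 1)
  half <- radius + 2 * patchiness
  g <- seq(-half, half, by = step)
  n <- length(g)
  field <- matrix(rnorm(n * n), n, n)
  sm <- EBImage::gblur(field, sigma = patchiness / step)
  # bilinear interpolation at nucleus positions
  fx <- (pts[, 1] - center[1] + half) / step + 1
  fy <- (pts[, 2] - center[2] + half) / step + 1
  i0 <- pmin(pmax(floor(fy), 1), n - 1); j0 <- pmin(pmax(floor(fx), 1), n - 1)
  wy <- fy - i0; wx <- fx - j0
  sm[cbind(i0, j0)] * (1 - wy) * (1 - wx) +
    sm[cbind(i0 + 1, j0)] * wy * (1 - wx) +
    sm[cbind(i0, j0 + 1)] * (1 - wy) * wx +
    sm[cbind(i0 + 1, j0 + 1)] * wy * wx
}

#' Idealized per-nucleus measurement records from ground truth
#'
#' Produces the nucleus table that [measureNuclei()] would output, directly
#' from a layout and its activation labels, bypassing rendering and
#' segmentation: each nucleus gets intensity
#' `background + intensityOn/Off + N(0, measSd)`. This is the generator's
#' idealized measurement model, used for large replicate studies (e.g.
#' power/separation simulations) where re-rendering thousands of images adds
#' nothing to the question being asked.
#'
#' @param layout a [ColonyLayout-class].
#' @param activation logical vector from [assignActivation()].
#' @param pheno a [PhenotypeParams-class].
#' @param seed integer seed for the measurement noise.
#' @param measSd standard deviation (a.u.) of per-nucleus intensity
#'   measurement error.
#' @param colonyId identifier for the records.
#' @return data.frame in the [measureNuclei()] schema.
#' @export
simulateNucleusRecords <- function(layout, activation, pheno, seed,
                                   measSd = 1, colonyId = "sim") {
  stopifnot(length(activation) == nucleusCount(layout))
  set.seed(seed)
  p <- layout@nucleusCenters
  d <- sqrt((p[, 1] - layout@colonyCenter[1])^2 +
            (p[, 2] - layout@colonyCenter[2])^2)
  base <- pheno@background +
    ifelse(activation, pheno@intensityOn, pheno@intensityOff)
  v <- base + rnorm(length(base), 0, measSd)
  data.frame(colony_id = colonyId, label = seq_len(nrow(p)),
             x_um = p[, 1], y_um = p[, 2],
             area_um2 = pi * layout@nucleusRadii^2, distance_um = d,
             median_SMAD23 = v, mean_SMAD23 = v)
}
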