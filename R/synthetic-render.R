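#' Render a synthetic activin-assay colony image
#'
#' Renders a two-channel image (`DAPI`, `SMAD23`) of a colony layout. Every
#' nucleus is a disc of its layout radius: in DAPI at `dapiIntensity`, in
#' SMAD2/3 at `intensityOn` (activated) or `intensityOff` (not activated).
#' Channels are Gaussian-blurred by `blurSigma` (optical softening), then
#' additive Gaussian background (`background`, `backgroundSd`) and optional
#' Poisson shot noise are applied. Ground truth (nucleus positions in image
#' coordinates and activation labels) is attached.
#'
#' @param layout a [ColonyLayout-class].
#' @param activation logical vector from [assignActivation()].
#' @param pheno a [PhenotypeParams-class].
#' @param pixelSize micrometers per pixel.
#' @param seed integer seed; identical inputs give a bit-identical sample.
#' @param margin blank margin around the colony, micrometers.
#' @param maxDim error if either image dimension would exceed this (pixels).
#' @return a [SyntheticSample-class].
#' @examples
#' lay <- generateColonyLayout(60, 30, minSeparation = 10, seed = 1)
#' s <- renderColonyImage(lay, assignActivation(lay, phenotypeParams("WT"), 1),
#'                        phenotypeParams("WT"), pixelSize = 1, seed = 1)
#' s@image
#' @export
renderColonyImage <- function(layout, activation, pheno, pixelSize = 1, seed = 1,
                              margin = 10, maxDim = 4096) {
  stopifnot(is(layout, "ColonyLayout"), is(pheno, "PhenotypeParams"),
            length(activation) == nucleusCount(layout), pixelSize > 0)
  side <- 2 * (layout@colonyRadius + margin)
  n <- ceiling(side / pixelSize)
  if (n > maxDim)
    stop("image would be ", n, " px per side, exceeding the cap of ", maxDim)
  set.seed(seed)
  offset <- c(n, n) * pixelSize / 2 - layout@colonyCenter
  ctr <- sweep(layout@nucleusCenters, 2, offset, "+")
  dapi <- matrix(0, n, n)
  smad <- matrix(0, n, n)
  smadLevel <- ifelse(activation, pheno@intensityOn, pheno@intensityOff)
  for (i in seq_len(nrow(ctr))) {
    sub <- .discIndex(ctr[i, 1], ctr[i, 2], layout@nucleusRadii[i], n, pixelSize)
    if (is.null(sub)) next
    dapi[sub$rows, sub$cols][sub$inside] <-
      pmax(dapi[sub$rows, sub$cols][sub$inside], pheno@dapiIntensity)
    smad[sub$rows, sub$cols][sub$inside] <-
      pmax(smad[sub$rows, sub$cols][sub$inside], smadLevel[i])
  }
  chans <- lapply(list(DAPI = dapi, SMAD23 = smad), .applyNoise,
                  pheno = pheno, pixelSize = pixelSize)
  truth <- data.frame(label = seq_len(nrow(ctr)), x_um = ctr[, 1],
                      y_um = ctr[, 2], radius_um = layout@nucleusRadii,
                      activated = activation)
  shifted <- layout
  shifted@nucleusCenters <- ctr
  shifted@colonyCenter <- layout@colonyCenter + offset
  new("SyntheticSample",
      image = MultiChannelImage(chans, pixelSize = pixelSize),
      truth = truth, layout = shifted, seed = as.integer(seed), params = pheno)
}

# disc footprint of radius r at (cx, cy) um on an n x n grid; NULL if empty
.discIndex <- function(cx, cy, r, n, pixelSize) {
  c0 <- max(1L, floor((cx - r) / pixelSize)); c1 <- min(n, ceiling((cx + r) / pixelSize) + 1L)
  r0 <- max(1L, floor((cy - r) / pixelSize)); r1 <- min(n, ceiling((cy + r) / pixelSize) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  ys <- (rows - 0.5) * pixelSize; xs <- (cols - 0.5) * pixelSize
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  if (!any(inside)) return(NULL)
  list(rows = rows, cols = cols, inside = inside)
}

.applyNoise <- function(m, pheno, pixelSize) {
  if (pheno@blurSigma > 0)
    m <- EBImage::gblur(m, sigma = pheno@blurSigma / pixelSize)
  m <- m + pheno@background
  if (pheno@poissonNoise)
    m <- matrix(rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
  if (pheno@backgroundSd > 0)
    m <- m + matrix(rnorm(length(m), 0, pheno@backgroundSd), nrow(m), ncol(m))
  m
}

#' Construct neuruloid ground-truth geometry
#'
#' @param dapiRadius,pax6Radius,ncadRadius,sox10Inner,sox10Outer radii in
#'   micrometers; must nest (`ncad <= pax6 <= dapi`, annulus within the
#'   disc).
#' @return a [NeuruloidGeometry-class].
#' @examples
#' trueFractions(neuruloidGeometry(250, 125, 60, 180, 240))
#' @export
neuruloidGeometry <- function(dapiRadius, pax6Radius, ncadRadius,
                              sox10Inner, sox10Outer) {
  new("NeuruloidGeometry", dapiRadius = dapiRadius, pax6Radius = pax6Radius,
      ncadRadius = ncadRadius, sox10Inner = sox10Inner,
      sox10Outer = sox10Outer)
}

#' Neuruloid geometry presets by phenotype
#'
#' Endpoint geometries encoding the phenotype direction: relative to `WT`,
#' the `HD`-like presets have an enlarged PAX6 neuroectodermal domain and
#' N-CAD lumen and a contracted SOX10 neural-crest annulus, with `HET`
#' intermediate and `KO` most extreme.
#'
#' @param phenotype one of `"WT"`, `"HET"`, `"HD"`, `"KO"`.
#' @return a [NeuruloidGeometry-class].
#' @export
neuruloidPreset <- function(phenotype = c("WT", "HET", "HD", "KO")) {
  phenotype <- match.arg(phenotype)
  r <- switch(phenotype,
    WT  = c(pax6 = 110, ncad = 55, s1 = 180, s2 = 240),
    HET = c(pax6 = 130, ncad = 70, s1 = 195, s2 = 240),
    HD  = c(pax6 = 150, ncad = 85, s1 = 205, s2 = 240),
    KO  = c(pax6 = 160, ncad = 95, s1 = 215, s2 = 240))
  neuruloidGeometry(250, r["pax6"], r["ncad"], r["s1"], r["s2"])
}

#' Randomly perturb a neuruloid geometry
#'
#' Multiplies each radius by an independent log-normal factor (sd `jitterSd`
#' on the log scale) to emulate colony-to-colony variability, then restores
#' the nesting order by clipping. The DAPI radius is jittered too.
#'
#' @param geom a [NeuruloidGeometry-class].
#' @param jitterSd log-scale standard deviation of the radius factors.
#' @param seed integer seed.
#' @return a perturbed [NeuruloidGeometry-class].
#' @export
jitterNeuruloidGeometry <- function(geom, jitterSd = 0.03, seed = 1) {
  set.seed(seed)
  f <- exp(rnorm(5, 0, jitterSd))
  dapi <- geom@dapiRadius * f[1]
  pax6 <- min(geom@pax6Radius * f[2], dapi)
  ncad <- min(geom@ncadRadius * f[3], pax6)
  s2 <- min(geom@sox10Outer * f[4], dapi)
  s1 <- min(geom@sox10Inner * f[5], s2)
  neuruloidGeometry(dapi, pax6, ncad, s1, s2)
}

#' Render a synthetic neuruloid image
#'
#' Four channels: `DAPI` (full disc), `PAX6` (central disc), `NCAD` (lumen
#' disc, filled) and `SOX10` (peripheral annulus), each at `intensity` over
#' background, blurred and noised like colony renders. The analytic true
#' fractions are recorded in the sample's truth table.
#'
#' @param geom a [NeuruloidGeometry-class].
#' @param pixelSize micrometers per pixel.
#' @param noise list with `background`, `backgroundSd`, `blurSigma`,
#'   `poisson` (same meaning as in [PhenotypeParams-class]).
#' @param seed integer seed.
#' @param intensity foreground level, a.u.
#' @param margin blank margin, micrometers.
#' @param maxDim image-dimension cap in pixels.
#' @return a [SyntheticSample-class] whose truth table has columns
#'   `marker` and `true_fraction`.
#' @export
renderNeuruloidImage <- function(geom, pixelSize = 1,
                                 noise = list(background = 10, backgroundSd = 4,
                                              blurSigma = 0.8, poisson = FALSE),
                                 seed = 1, intensity = 200, margin = 10,
                                 maxDim = 4096) {
  stopifnot(is(geom, "NeuruloidGeometry"), pixelSize > 0)
  validObject(geom)
  side <- 2 * (geom@dapiRadius + margin)
  n <- ceiling(side / pixelSize)
  if (n > maxDim)
    stop("image would be ", n, " px per side, exceeding the cap of ", maxDim)
  set.seed(seed)
  cc <- c(n, n) * pixelSize / 2
  ys <- (seq_len(n) - 0.5) * pixelSize
  xs <- (seq_len(n) - 0.5) * pixelSize
  d2 <- outer((ys - cc[2])^2, (xs - cc[1])^2, "+")
  disc <- function(r) intensity * (d2 <= r^2)
  raw <- list(DAPI = disc(geom@dapiRadius), PAX6 = disc(geom@pax6Radius),
              NCAD = disc(geom@ncadRadius),
              SOX10 = intensity * (d2 <= geom@sox10Outer^2 &
                                   d2 >= geom@sox10Inner^2))
  ph <- new("PhenotypeParams", name = "neuruloid", pEdge = 1, pCenter = 0,
            edgeBandWidth = 0, patchiness = 0, intensityOn = intensity,
            intensityOff = 0.5 * intensity, dapiIntensity = intensity,
            background = noise$background, backgroundSd = noise$backgroundSd,
            poissonNoise = isTRUE(noise$poisson), blurSigma = noise$blurSigma)
  chans <- lapply(raw, .applyNoise, pheno = ph, pixelSize = pixelSize)
  tf <- trueFractions(geom)
  truth <- data.frame(marker = names(tf), true_fraction = as.numeric(tf))
  new("SyntheticSample",
      image = MultiChannelImage(chans, pixelSize = pixelSize),
      truth = truth, layout = geom, seed = as.integer(seed), params = geom)
}
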