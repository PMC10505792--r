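# shared fixture builders; everything is generated in code at test time

# draw filled discs (value `level`) onto an n x m zero matrix;
# centers is a k x 2 matrix of (x, y) in um at `pixelSize` um/px
drawDiscs <- function(nrow, ncol, centers, radii, level = 150, pixelSize = 1) {
  m <- matrix(0, nrow, ncol)
  ys <- (seq_len(nrow) - 0.5) * pixelSize
  xs <- (seq_len(ncol) - 0.5) * pixelSize
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((ys - centers[i, 2])^2, (xs - centers[i, 1])^2, "+")
    m[d2 <= radii[i]^2] <- level
  }
  m
}

# small fast colony sample for pipeline-level unit tests
smallColonySample <- function(phenotype = "WT", targetCount = 180,
                              colonyRadius = 80, seed = 1, ...) {
  ph <- phenotypeParams(phenotype, ...)
  lay <- generateColonyLayout(colonyRadius, targetCount, minSeparation = 8,
                              seed = seed)
  act <- assignActivation(lay, ph, seed = seed + 1)
  smp <- renderColonyImage(lay, act, ph, pixelSize = 1, seed = seed + 2)
  list(sample = smp, layout = lay, activation = act, pheno = ph)
}

# noiseless phenotype: no background, no blur, no read noise
noiselessParams <- function(phenotype = "WT", ...) {
  phenotypeParams(phenotype, background = 0, backgroundSd = 0, blurSigma = 0,
                  ...)
}

measureSample <- function(smp, tolerance = 0.3) {
  labels <- segmentNuclei(getChannel(smp@image, "DAPI"),
                          pixelSize = pixelSize(smp@image),
                          tolerance = tolerance)
  filt <- filterNuclei(labels, pixelSize = pixelSize(smp@image))
  measureNuclei(filt$labels, smp@image,
                colonyCenter = smp@layout@colonyCenter,
                pixelSize = pixelSize(smp@image))
}
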