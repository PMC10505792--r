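test_that("noiseless renders hit the configured intensities", {
  lay <- generateColonyLayout(30, 1, minSeparation = 10, seed = 0)
  ph <- noiselessParams("KO")
  s <- renderColonyImage(lay, TRUE, ph, pixelSize = 1, seed = 1)
  smad <- getChannel(s@image, "SMAD23")
  inside <- smad > 0
  expect_true(any(inside))
  expect_equal(mean(smad[inside]), ph@intensityOn, tolerance = 1e-8)
  dapi <- getChannel(s@image, "DAPI")
  expect_equal(max(dapi), ph@dapiIntensity)
})

test_that("rendering is deterministic given seed and parameters", {
  fx <- smallColonySample("HET", seed = 11)
  s2 <- renderColonyImage(fx$layout, fx$activation, fx$pheno,
                          pixelSize = 1, seed = 13)
  expect_identical(fx$sample@image@channels, s2@image@channels)
  s3 <- renderColonyImage(fx$layout, fx$activation, fx$pheno,
                          pixelSize = 1, seed = 14)
  expect_false(identical(fx$sample@image@channels, s3@image@channels))
})

test_that("DAPI foreground area matches the analytic disc-area sum", {
  lay <- generateColonyLayout(250, 2000, minSeparation = 9, seed = 2)
  ph <- noiselessParams("WT")
  act <- assignActivation(lay, ph, seed = 3)
  s <- renderColonyImage(lay, act, ph, pixelSize = 1, seed = 4)
  fg <- sum(getChannel(s@image, "DAPI") > 0)
  expect_lt(abs(fg / sum(pi * lay@nucleusRadii^2) - 1), 0.10)
})

test_that("truth centroids map to pixel-space centroids within one pixel", {
  fx <- smallColonySample("WT", targetCount = 60, seed = 21,
                          background = 0, backgroundSd = 0, blurSigma = 0)
  rec <- measureSample(fx$sample)
  truth <- fx$sample@truth
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((rec$x_um - truth$x_um[i])^2 + (rec$y_um - truth$y_um[i])^2)
    expect_lt(min(dd), 1)
  }
})

test_that("image dimension cap triggers an error", {
  lay <- generateColonyLayout(30, 1, minSeparation = 10, seed = 0)
  expect_error(renderColonyImage(lay, TRUE, phenotypeParams("WT"),
                                 pixelSize = 0.01, seed = 1, maxDim = 512),
               "cap")
})

test_that("neuruloid geometry encodes analytic truth fractions", {
  expect_equal(unname(trueFractions(neuruloidGeometry(250, 250, 50, 100, 150))["PAX6"]), 1)
  expect_equal(unname(trueFractions(neuruloidGeometry(250, 125, 50, 100, 150))["PAX6"]), 0.25)
  tf <- trueFractions(neuruloidGeometry(250, 125, 50, 180, 240))
  expect_equal(unname(tf["SOX10"]), (240^2 - 180^2) / 250^2)  # 0.4032
  expect_error(neuruloidGeometry(250, 100, 150, 180, 240), "nest")
  expect_error(renderNeuruloidImage(neuruloidGeometry(250, 100, 150, 180, 240)))
})

test_that("jittered neuruloid geometries stay nested and deterministic", {
  base <- neuruloidPreset("HD")
  for (s in 1:20) {
    g <- jitterNeuruloidGeometry(base, jitterSd = 0.1, seed = s)
    expect_true(g@ncadRadius <= g@pax6Radius)
    expect_true(g@pax6Radius <= g@dapiRadius)
    expect_true(g@sox10Inner <= g@sox10Outer)
    expect_true(g@sox10Outer <= g@dapiRadius)
  }
  expect_identical(jitterNeuruloidGeometry(base, 0.05, 3),
                   jitterNeuruloidGeometry(base, 0.05, 3))
})

test_that("TIFF round trip preserves channels, names and pixel size", {
  fx <- smallColonySample("HD", targetCount = 40, colonyRadius = 50, seed = 31)
  dirOut <- withr::local_tempdir()
  writeSyntheticSample(fx$sample, dirOut, "col1")
  expect_true(file.exists(file.path(dirOut, "col1_truth.csv")))
  expect_true(file.exists(file.path(dirOut, "col1_params.json")))
  back <- readMultiChannelTIFF(file.path(dirOut, "col1.tif"))
  expect_identical(channelNames(back), channelNames(fx$sample@image))
  expect_equal(pixelSize(back), 1)
  for (ch in channelNames(back))
    expect_equal(getChannel(back, ch), getChannel(fx$sample@image, ch),
                 tolerance = 1e-5)  # 32-bit float storage
})
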